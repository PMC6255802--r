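#' Sliding windows over contigs
#'
#' Windows start at 0 and advance by `step`; each is truncated at the contig
#' end, and a terminal partial window is emitted iff its length is at least
#' half the window size (so genome tails are neither dropped nor reported as
#' noisy slivers). Coordinates are 0-based half-open.
#'
#' @param contig_lengths Named vector of contig lengths in bp.
#' @param size Window size in bp (default 100 kb).
#' @param step Window increment in bp (default 50 kb); must not exceed
#'   `size`.
#' @return Tibble with `contig`, `start`, `end`.
#' @export
#' @examples
#' make_windows(c(chr1 = 250000))
make_windows <- function(contig_lengths, size = 100000L, step = 50000L) {
  if (is.null(names(contig_lengths)) || any(names(contig_lengths) == "")) {
    abort("contig_lengths must be a named vector")
  }
  if (size <= 0 || step <= 0) abort("size and step must be positive")
  if (step > size) abort("step > size would leave gaps between windows")
  if (any(contig_lengths <= 0)) abort("contig lengths must be positive")
  purrr::map_dfr(names(contig_lengths), function(ctg) {
    len <- as.integer(contig_lengths[[ctg]])
    starts <- seq(0L, max(0L, len - 1L), by = as.integer(step))
    ends <- pmin(starts + as.integer(size), len)
    keep <- (ends - starts) >= size / 2
    if (!any(keep)) { # contig shorter than half a window: single window
      starts <- 0L
      ends <- len
      keep <- TRUE
    }
    tibble(contig = ctg, start = starts[keep], end = ends[keep])
  })
}

#' Windowed selective-sweep scan
#'
#' Computes, for every window, the number of SNPs, pooled heterozygosity per
#' population, windowed Fst (ratio of averages), nucleotide diversity and
#' Tajima's D per population, then genome-wide Z-transforms Hp and Fst over
#' the non-NA windows. Windows with fewer than `min_snps` SNPs get NA
#' statistics and are excluded from the Z-transformation.
#'
#' @param x A QC'd [genotype_dataset()] with exactly two populations.
#' @param windows Tibble from [make_windows()]; if `NULL`, built from
#'   `x$contig_lengths` (or the last SNP per contig) with `size`/`step`.
#' @param size,step Window geometry used when `windows` is `NULL`.
#' @param min_snps Minimum SNPs for a window to receive statistics.
#' @param focal_pop The population in which the sweep is sought (its ZHp
#'   drives outlier calling); the other population is the reference.
#' @param estimator Fst estimator, see [fst_site_components()].
#' @param hp_normalization See [pooled_heterozygosity()].
#' @return Tibble of class `sweep_scan`: one row per window with columns
#'   `contig`, `start`, `end`, `n_snps`, `hp_<focal>`, `hp_<other>`, `fst`,
#'   `pi_*`, `tajd_*` as `hp_focal`/`hp_other` etc., plus `zhp_focal`,
#'   `zhp_other`, `zfst` and `delta_zhp = zhp_other - zhp_focal`.
#' @export
scan_windows <- function(x, windows = NULL, size = 100000L, step = 50000L,
                         min_snps = 10L, focal_pop = "highland",
                         estimator = c("wc", "hudson"),
                         hp_normalization = c("squared", "printed")) {
  estimator <- match.arg(estimator)
  hp_normalization <- match.arg(hp_normalization)
  pops <- unique(x$popmap$population)
  if (length(pops) != 2) abort("scan_windows needs exactly two populations")
  if (!focal_pop %in% pops) {
    abort(paste0("unknown focal population '", focal_pop, "'; available: ",
                 paste(pops, collapse = ", ")))
  }
  other_pop <- setdiff(pops, focal_pop)
  if (is.null(windows)) {
    cl <- x$contig_lengths
    if (is.null(cl)) {
      cl <- tapply(x$variants$pos, x$variants$contig, max)
      cl <- stats::setNames(as.integer(cl), names(cl))
    }
    windows <- make_windows(cl, size = size, step = step)
  }

  acf <- allele_counts(x, focal_pop)
  aco <- allele_counts(x, other_pop)
  comp <- fst_site_components(aco$n_ref, aco$n_alt, acf$n_ref, acf$n_alt,
                              estimator = estimator)
  site <- tibble(
    contig = x$variants$contig, pos0 = x$variants$pos - 1L,
    maj_f = acf$n_maj, min_f = acf$n_min,
    maj_o = aco$n_maj, min_o = aco$n_min,
    n_f = acf$n, n_o = aco$n,
    pi_f = pi_site(acf$n_ref, acf$n_alt),
    pi_o = pi_site(aco$n_ref, aco$n_alt),
    seg_f = acf$n_ref > 0 & acf$n_alt > 0,
    seg_o = aco$n_ref > 0 & aco$n_alt > 0,
    fst_num = comp$num, fst_den = comp$den)

  win_stats <- function(w) {
    s <- site[site$contig == w$contig &
                site$pos0 >= w$start & site$pos0 < w$end, ]
    len <- w$end - w$start
    ns <- nrow(s)
    if (ns < min_snps) {
      return(tibble(n_snps = ns, hp_focal = NA_real_, hp_other = NA_real_,
                    fst = NA_real_, pi_focal = NA_real_, pi_other = NA_real_,
                    tajd_focal = NA_real_, tajd_other = NA_real_))
    }
    tibble(
      n_snps = ns,
      hp_focal = pooled_heterozygosity(sum(s$maj_f), sum(s$min_f),
                                       normalization = hp_normalization),
      hp_other = pooled_heterozygosity(sum(s$maj_o), sum(s$min_o),
                                       normalization = hp_normalization),
      fst = fst_window(tibble(num = s$fst_num, den = s$fst_den)),
      pi_focal = sum(s$pi_f) / len,
      pi_other = sum(s$pi_o) / len,
      tajd_focal = tajd_from_site(s, "f"),
      tajd_other = tajd_from_site(s, "o"))
  }
  rows <- bind_cols(windows,
                    purrr::map_dfr(seq_len(nrow(windows)),
                                   function(i) win_stats(windows[i, ])))

  usable <- sum(!is.na(rows$fst) & !is.na(rows$hp_focal))
  if (usable < 10) {
    abort("fewer than 10 windows with statistics; Z-scores would be meaningless")
  }
  rows <- rows %>%
    mutate(zhp_focal = safe_z(.data$hp_focal),
           zhp_other = safe_z(.data$hp_other),
           zfst = safe_z(.data$fst),
           delta_zhp = .data$zhp_other - .data$zhp_focal)
  attr(rows, "focal_pop") <- focal_pop
  attr(rows, "other_pop") <- other_pop
  class(rows) <- c("sweep_scan", class(rows))
  rows
}

# z-transform keeping NA
safe_z <- function(v) {
  out <- rep(NA_real_, length(v))
  fin <- is.finite(v)
  out[fin] <- zscore(v[fin])
  out
}

# windowed Tajima's D from the precomputed site table; suffix selects pop
tajd_from_site <- function(s, suffix) {
  seg <- s[[paste0("seg_", suffix)]]
  s_obs <- sum(seg)
  if (s_obs == 0) return(NA_real_)
  n <- min(s[[paste0("n_", suffix)]][seg])
  if (n < 3) return(NA_real_)
  k <- tajima_constants(n)
  pi_sum <- sum(s[[paste0("pi_", suffix)]][seg])
  denom <- sqrt(k$e1 * s_obs + k$e2 * s_obs * (s_obs - 1))
  if (denom == 0) return(NA_real_)
  (pi_sum - s_obs / k$a1) / denom
}

#' Flag joint ZFst/ZHp outlier windows
#'
#' A window is an outlier iff its ZFst is at or above the empirical
#' `1 - q` quantile and the focal population's ZHp is at or below the
#' empirical `q` quantile (type-7 linear-interpolation quantiles over
#' non-NA windows) -- i.e. the jointly extreme top-left corner of the
#' ZFst-vs-ZHp plane.
#'
#' @param rows A `sweep_scan` tibble from [scan_windows()].
#' @param q Tail quantile, in (0, 0.5) (default 0.05 = top/bottom 5%).
#' @param hp_condition Which ZHp drives the Hp condition: the focal
#'   population (default), the other population, or the minimum of both.
#' @return `rows` with a logical `outlier` column; the thresholds are
#'   stored in attributes `zfst_threshold` and `zhp_threshold`.
#' @export
call_outliers <- function(rows, q = 0.05,
                          hp_condition = c("focal", "other", "min")) {
  hp_condition <- match.arg(hp_condition)
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 0.5) {
    abort("q must lie strictly between 0 and 0.5")
  }
  zhp <- switch(hp_condition,
                focal = rows$zhp_focal,
                other = rows$zhp_other,
                min = pmin(rows$zhp_focal, rows$zhp_other))
  thr_fst <- quantile(rows$zfst, 1 - q, na.rm = TRUE, type = 7, names = FALSE)
  thr_hp <- quantile(zhp, q, na.rm = TRUE, type = 7, names = FALSE)
  rows$outlier <- !is.na(rows$zfst) & !is.na(zhp) &
    rows$zfst >= thr_fst & zhp <= thr_hp
  attr(rows, "q") <- q
  attr(rows, "zfst_threshold") <- thr_fst
  attr(rows, "zhp_threshold") <- thr_hp
  attr(rows, "hp_condition") <- hp_condition
  rows
}

#' Merge flagged windows into sweep regions
#'
#' Overlapping or book-ended (shared-boundary) outlier windows on the same
#' contig are merged into maximal regions.
#'
#' @param rows Output of [call_outliers()].
#' @return Tibble with `contig`, `start`, `end`, `n_windows` (flagged
#'   windows merged into the region), sorted and non-overlapping.
#' @export
merge_regions <- function(rows) {
  fl <- rows[!is.na(rows$outlier) & rows$outlier, , drop = FALSE]
  if (nrow(fl) == 0) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  n_windows = integer()))
  }
  gr <- GenomicRanges::GRanges(fl$contig,
                               IRanges::IRanges(fl$start + 1L, fl$end))
  red <- GenomicRanges::reduce(gr) # merges overlapping and book-ended
  hits <- GenomicRanges::countOverlaps(red, gr)
  out <- tibble(contig = as.character(GenomicRanges::seqnames(red)),
                start = GenomicRanges::start(red) - 1L,
                end = GenomicRanges::end(red),
                n_windows = as.integer(hits))
  arrange(out, .data$contig, .data$start)
}

#' Total genomic span of sweep regions
#'
#' @param regions Tibble from [merge_regions()].
#' @return Total bp covered.
#' @export
total_region_span <- function(regions) {
  if (nrow(regions) == 0) return(0)
  sum(as.numeric(regions$end - regions$start))
}

#' Genes overlapping sweep regions
#'
#' A gene is counted for a region iff its interval intersects the region by
#' at least 1 bp (half-open region coordinates; gene coordinates 1-based
#' inclusive as in GFF3).
#'
#' @param regions Tibble from [merge_regions()].
#' @param genes Gene-model tibble (e.g. from [place_genes()] or
#'   [read_gff3()]) with `gene_id`, `contig`, `start`, `end`.
#' @return `regions` with a `gene_ids` list-column of overlapping genes.
#' @export
genes_in_regions <- function(regions, genes) {
  if (nrow(regions) == 0) {
    regions$gene_ids <- list()
    return(regions)
  }
  rgr <- GenomicRanges::GRanges(regions$contig,
                                IRanges::IRanges(regions$start + 1L,
                                                 regions$end))
  ggr <- GenomicRanges::GRanges(genes$contig,
                                IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(rgr, ggr)
  ids <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    ids[[i]] <- sort(unique(
      genes$gene_id[S4Vectors::subjectHits(hits)[
        S4Vectors::queryHits(hits) == i]]))
  }
  regions$gene_ids <- ids
  regions
}

#' Deduplicated, sorted candidate gene list
#'
#' The global list of positively-selected-gene (PSG) candidates: every gene
#' overlapping any sweep region.
#'
#' @param regions_with_genes Output of [genes_in_regions()].
#' @return Sorted character vector of gene ids.
#' @export
psg_genes <- function(regions_with_genes) {
  sort(unique(as.character(unlist(regions_with_genes$gene_ids))))
}
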