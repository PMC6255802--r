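#' Construct a genotype dataset
#'
#' The central container of the package: a table of biallelic SNPs together
#' with a sample-by-variant genotype dosage matrix and a sample-to-population
#' map. All window statistics, the outlier scan and the locus diagnostics
#' operate on this object.
#'
#' @param variants Tibble with columns `contig`, `pos` (1-based), `ref`,
#'   `alt` and optionally `mq` (site root-mean-square mapping quality).
#'   Positions must be strictly increasing within each contig.
#' @param genotypes Integer matrix, samples in rows and variants in columns,
#'   values 0 (hom ref), 1 (het), 2 (hom alt) or `NA` (missing call).
#'   Row names are sample ids.
#' @param popmap Tibble with columns `sample` and `population` covering every
#'   row of `genotypes`.
#' @param dp Optional matrix of per-call sequencing depths, same shape as
#'   `genotypes`; used by the depth mask in [apply_qc()].
#' @param contig_lengths Optional named vector of contig lengths (bp).
#'
#' @return An object of class `genotype_dataset`.
#' @export
#' @examples
#' gd <- genotype_dataset(
#'   variants = tibble::tibble(contig = "chr1", pos = c(100L, 200L),
#'                             ref = c("A", "C"), alt = c("T", "G"), mq = 60),
#'   genotypes = matrix(c(0L, 1L, 2L, 1L), nrow = 2,
#'                      dimnames = list(c("s1", "s2"), NULL)),
#'   popmap = tibble::tibble(sample = c("s1", "s2"),
#'                           population = c("lowland", "highland")))
#' gd
genotype_dataset <- function(variants, genotypes, popmap, dp = NULL,
                             contig_lengths = NULL) {
  variants <- as_tibble(variants)
  stopifnot(all(c("contig", "pos", "ref", "alt") %in% names(variants)))
  if (!"mq" %in% names(variants)) variants$mq <- NA_real_
  if (!is.matrix(genotypes)) genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  popmap <- as_tibble(popmap)
  stopifnot(all(c("sample", "population") %in% names(popmap)))
  if (is.null(rownames(genotypes))) {
    stopifnot(nrow(genotypes) == nrow(popmap))
    rownames(genotypes) <- popmap$sample
  }
  if (ncol(genotypes) != nrow(variants)) {
    abort("genotype matrix columns must match the variant table rows")
  }
  missing_pop <- setdiff(rownames(genotypes), popmap$sample)
  if (length(missing_pop) > 0) {
    abort(paste0("sample(s) absent from popmap: ",
                 paste(missing_pop, collapse = ", ")))
  }
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) > 0 && (min(bad) < 0L || max(bad) > 2L)) {
    abort("genotype dosages must be 0, 1, 2 or NA")
  }
  if (nrow(variants) > 1) {
    dup <- unlist(lapply(split(variants$pos, variants$contig), function(p) {
      length(p) > 1 && any(diff(p) <= 0)
    }))
    if (any(dup)) abort("positions must be strictly increasing within contig")
  }
  if (!is.null(dp)) {
    stopifnot(all(dim(dp) == dim(genotypes)))
    storage.mode(dp) <- "integer"
  }
  popmap <- popmap[match(rownames(genotypes), popmap$sample), ]
  structure(
    list(variants = variants, genotypes = genotypes, popmap = popmap,
         dp = dp, contig_lengths = contig_lengths),
    class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("<genotype_dataset>\n")
  cat("  samples:  ", nrow(x$genotypes), " (",
      paste(sprintf("%s=%d", names(table(x$popmap$population)),
                    as.integer(table(x$popmap$population))), collapse = ", "),
      ")\n", sep = "")
  cat("  variants: ", nrow(x$variants), " on ",
      length(unique(x$variants$contig)), " contig(s)\n", sep = "")
  invisible(x)
}

#' @method glance genotype_dataset
#' @export
glance.genotype_dataset <- function(x, ...) {
  tibble(
    n_samples = nrow(x$genotypes),
    n_variants = nrow(x$variants),
    n_contigs = length(unique(x$variants$contig)),
    n_populations = length(unique(x$popmap$population)),
    missing_rate = mean(is.na(x$genotypes)))
}

#' Variant table of a genotype dataset
#'
#' @param x A [genotype_dataset()].
#' @param ... Unused.
#' @return Tibble of variants with per-variant overall alt-allele frequency.
#' @method tidy genotype_dataset
#' @export
tidy.genotype_dataset <- function(x, ...) {
  g <- x$genotypes
  n <- 2L * colSums(!is.na(g))
  af <- ifelse(n > 0, colSums(g, na.rm = TRUE) / n, NA_real_)
  mutate(x$variants, alt_freq = af)
}

#' Samples belonging to a population
#' @param x A [genotype_dataset()].
#' @param population Population label as in the popmap.
#' @return Character vector of sample ids.
#' @export
pop_samples <- function(x, population) {
  s <- x$popmap$sample[x$popmap$population == population]
  if (length(s) == 0) {
    abort(paste0("unknown population '", population, "'; available: ",
                 paste(unique(x$popmap$population), collapse = ", ")))
  }
  s
}

#' Per-site allele counts within one population
#'
#' Counts non-missing REF and ALT allele copies per variant, plus the derived
#' major/minor (nMAJ/nMIN) counts used by pooled heterozygosity. Major-allele
#' ties at frequency 0.5 are broken REF-first.
#'
#' @inheritParams pop_samples
#' @return Tibble with one row per variant: `n_ref`, `n_alt`, `n` (copies),
#'   `n_maj`, `n_min`.
#' @export
allele_counts <- function(x, population) {
  g <- x$genotypes[pop_samples(x, population), , drop = FALSE]
  n <- 2L * colSums(!is.na(g))
  n_alt <- colSums(g, na.rm = TRUE)
  n_ref <- n - n_alt
  tibble(n_ref = as.integer(n_ref), n_alt = as.integer(n_alt),
         n = as.integer(n),
         n_maj = as.integer(pmax(n_ref, n_alt)),
         n_min = as.integer(pmin(n_ref, n_alt)))
}

#' Restrict a dataset to a genomic region
#'
#' @inheritParams pop_samples
#' @param contig Contig name.
#' @param start,end Region bounds, 0-based half-open.
#' @return A [genotype_dataset()] with the variants falling in the region.
#' @export
subset_region <- function(x, contig, start, end) {
  keep <- x$variants$contig == contig &
    (x$variants$pos - 1L) >= start & (x$variants$pos - 1L) < end
  genotype_dataset(x$variants[keep, , drop = FALSE],
                   x$genotypes[, keep, drop = FALSE],
                   x$popmap,
                   dp = if (is.null(x$dp)) NULL else x$dp[, keep, drop = FALSE],
                   contig_lengths = x$contig_lengths)
}

#' Parse a region string
#'
#' Accepts `"contig:start-end"` with 1-based inclusive coordinates (the CLI
#' convention) and returns the 0-based half-open bounds used internally.
#'
#' @param region Region string.
#' @return List with `contig`, `start`, `end` (0-based half-open).
#' @export
parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4) abort("region must look like 'contig:start-end'")
  start1 <- as.integer(m[3])
  end1 <- as.integer(m[4])
  if (start1 < 1 || end1 < start1) abort("invalid region bounds")
  list(contig = m[2], start = start1 - 1L, end = end1)
}
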