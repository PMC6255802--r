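#' Alternate-allele frequency per population
#'
#' @param x A [genotype_dataset()].
#' @param contig,pos Variant coordinates (1-based).
#' @return Tibble with `population`, `n` (non-missing allele copies) and
#'   `alt_freq` (`NA` for a population with all calls missing).
#' @export
allele_freq_by_pop <- function(x, contig, pos) {
  j <- which(x$variants$contig == contig & x$variants$pos == pos)
  if (length(j) == 0) {
    abort(paste0("variant ", contig, ":", pos, " not in dataset"))
  }
  purrr::map_dfr(unique(x$popmap$population), function(p) {
    g <- x$genotypes[pop_samples(x, p), j[1]]
    n <- 2L * sum(!is.na(g))
    tibble(population = p, n = n,
           alt_freq = if (n > 0) sum(g, na.rm = TRUE) / n else NA_real_)
  })
}

#' Genotype-class frequencies per population
#'
#' Fractions of hom-ref (dosage 0), het (1) and hom-alt (2) calls per
#' population at one variant; labels (e.g. wild type vs mutant) are left to
#' the caller, since which allele is ancestral is a downstream decision.
#'
#' @inheritParams allele_freq_by_pop
#' @return Tibble with `population`, `n_called`, `hom_ref`, `het`,
#'   `hom_alt` (fractions summing to 1 per population with any calls).
#' @export
genotype_class_freqs <- function(x, contig, pos) {
  j <- which(x$variants$contig == contig & x$variants$pos == pos)
  if (length(j) == 0) {
    abort(paste0("variant ", contig, ":", pos, " not in dataset"))
  }
  purrr::map_dfr(unique(x$popmap$population), function(p) {
    g <- x$genotypes[pop_samples(x, p), j[1]]
    g <- g[!is.na(g)]
    nc <- length(g)
    tibble(population = p, n_called = nc,
           hom_ref = if (nc) mean(g == 0L) else NA_real_,
           het = if (nc) mean(g == 1L) else NA_real_,
           hom_alt = if (nc) mean(g == 2L) else NA_real_)
  })
}

#' Principal component analysis of a locus
#'
#' PCA of the SNP dosages in a region: missing dosages are mean-imputed per
#' SNP, columns are centered and scaled by `sqrt(2 p (1 - p))` (Patterson
#' scaling, `p` the alt-allele frequency), monomorphic SNPs dropped, and
#' the sample coordinates obtained by eigendecomposition of the resulting
#' matrix. Component signs are canonicalized so that each component's
#' largest-magnitude SNP loading is positive, making outputs reproducible
#' across linear-algebra backends.
#'
#' @param x A [genotype_dataset()].
#' @param contig,start,end Region, 0-based half-open.
#' @param n_components Number of components to return (default 2).
#' @return Object of class `locus_pca`: list with `coords` (tibble:
#'   `sample`, `population`, `PC1`, ...), `varexp` (variance-explained
#'   fractions, non-increasing) and `n_snps`.
#' @export
locus_pca <- function(x, contig, start, end, n_components = 2L) {
  sub <- subset_region(x, contig, start, end)
  g <- sub$genotypes
  if (nrow(g) < 2) abort("locus_pca needs at least 2 samples")
  p <- colMeans(g, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (sum(poly) < 2) abort("locus_pca needs at least 2 polymorphic SNPs")
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  m <- t(t(g) - 2 * p)           # center
  m[is.na(m)] <- 0               # mean imputation after centering
  m <- t(t(m) / sqrt(2 * p * (1 - p)))
  sv <- svd(m)
  k <- min(n_components, length(sv$d))
  # canonical sign: largest-|loading| entry of each component positive
  for (i in seq_len(k)) {
    j <- which.max(abs(sv$v[, i]))
    if (sv$v[j, i] < 0) {
      sv$v[, i] <- -sv$v[, i]
      sv$u[, i] <- -sv$u[, i]
    }
  }
  coords <- as_tibble(stats::setNames(
    as.data.frame(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], nrow = k)),
    paste0("PC", seq_len(k))))
  coords <- bind_cols(tibble(sample = rownames(g)), coords) %>%
    left_join(x$popmap, by = "sample") %>%
    select("sample", "population", dplyr::starts_with("PC"))
  structure(list(coords = coords,
                 varexp = (sv$d^2 / sum(sv$d^2))[seq_len(k)],
                 n_snps = ncol(g)),
            class = "locus_pca")
}

#' @export
print.locus_pca <- function(x, ...) {
  cat("<locus_pca> ", nrow(x$coords), " samples, ", x$n_snps, " SNPs; ",
      "variance explained: ",
      paste(sprintf("%.1f%%", 100 * x$varexp), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @method tidy locus_pca
#' @export
tidy.locus_pca <- function(x, ...) x$coords

#' @method glance locus_pca
#' @export
glance.locus_pca <- function(x, ...) {
  out <- as_tibble(as.list(stats::setNames(
    x$varexp, paste0("varexp_pc", seq_along(x$varexp)))))
  mutate(out, n_snps = x$n_snps)
}

#' Per-locus diagnostic report
#'
#' Assembles the full workup of a candidate locus: per-population alternate
#' allele frequency and genotype-class fractions at a focal variant, mean
#' pairwise r-squared and Tajima's D per population over the region, and a
#' locus-restricted PCA.
#'
#' @param x A [genotype_dataset()].
#' @param region Region string `"contig:start-end"` (1-based inclusive) or
#'   a list from [parse_region()].
#' @param focal_variant Optional `c(contig, pos)` or position of the focal
#'   variant; defaults to the SNP with the largest between-population
#'   frequency difference in the region.
#' @return Object of class `locus_report`: list with `region`,
#'   `focal_variant`, `allele_freq`, `genotype_classes`, `stats` (tibble:
#'   per-population mean r2 and Tajima's D) and `pca`.
#' @export
locus_summary <- function(x, region, focal_variant = NULL) {
  r <- if (is.character(region)) parse_region(region) else region
  sub <- subset_region(x, r$contig, r$start, r$end)
  if (nrow(sub$variants) == 0) abort("no SNPs in region")
  pops <- unique(x$popmap$population)
  if (is.null(focal_variant)) {
    freqs <- vapply(pops, function(p) {
      ac <- allele_counts(sub, p)
      ifelse(ac$n > 0, ac$n_alt / ac$n, NA_real_)
    }, numeric(nrow(sub$variants)))
    freqs <- matrix(freqs, nrow = nrow(sub$variants))
    dif <- abs(freqs[, 1] - freqs[, ncol(freqs)])
    j <- which.max(dif)
    focal_variant <- c(sub$variants$contig[j], sub$variants$pos[j])
  }
  fv_contig <- as.character(focal_variant[1])
  fv_pos <- as.integer(focal_variant[2])
  stats_tbl <- purrr::map_dfr(pops, function(p) {
    tibble(population = p,
           mean_r2 = region_mean_r2(x, p, r$contig, r$start, r$end),
           tajimas_d = tajimas_d(x, p, r$contig, r$start, r$end))
  })
  structure(
    list(region = r,
         focal_variant = tibble(contig = fv_contig, pos = fv_pos),
         allele_freq = allele_freq_by_pop(x, fv_contig, fv_pos),
         genotype_classes = genotype_class_freqs(x, fv_contig, fv_pos),
         stats = stats_tbl,
         pca = locus_pca(x, r$contig, r$start, r$end)),
    class = "locus_report")
}

#' @export
print.locus_report <- function(x, ...) {
  cat(sprintf("<locus_report> %s:%d-%d (focal variant %s:%d)\n",
              x$region$contig, x$region$start + 1L, x$region$end,
              x$focal_variant$contig, x$focal_variant$pos))
  print(x$allele_freq)
  print(x$stats)
  invisible(x)
}

#' @method tidy locus_report
#' @export
tidy.locus_report <- function(x, ...) {
  x$allele_freq %>%
    left_join(x$genotype_classes, by = "population") %>%
    left_join(x$stats, by = "population")
}

#' @method glance locus_report
#' @export
glance.locus_report <- function(x, ...) {
  tibble(contig = x$region$contig, start = x$region$start,
         end = x$region$end, n_snps = x$pca$n_snps,
         varexp_pc1 = x$pca$varexp[1])
}

#' Write a locus report and its PCA coordinates as TSV
#' @param report A [locus_summary()] result.
#' @param path Output path for the per-population table; PCA coordinates go
#'   to `sub("\\.tsv$", "_pca.tsv", path)`.
#' @return `path`, invisibly.
#' @export
write_locus_tsv <- function(report, path) {
  tb <- tidy(report)
  con <- file(path, "w")
  writeLines(sprintf("# region=%s:%d-%d focal=%s:%d",
                     report$region$contig, report$region$start + 1L,
                     report$region$end, report$focal_variant$contig,
                     report$focal_variant$pos), con)
  writeLines(paste0("#", paste(names(tb), collapse = "\t")), con)
  write.table(as.data.frame(tb), con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  close(con)
  pca_path <- sub("\\.tsv$", "_pca.tsv", path)
  pc <- tidy(report$pca)
  con <- file(pca_path, "w")
  writeLines(sprintf("# varexp=%s",
                     paste(sprintf("%.6f", report$pca$varexp),
                           collapse = ",")), con)
  writeLines(paste0("#", paste(names(pc), collapse = "\t")), con)
  write.table(as.data.frame(pc), con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}
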