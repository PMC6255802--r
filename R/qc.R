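#' SNP quality-control thresholds
#'
#' Defaults follow common resequencing practice for individually sequenced
#' population samples: per-call depth within `[3, 50]`, site RMS mapping
#' quality at least 20, minor allele frequency at least 0.05 and missing
#' call fraction at most 0.1. All bounds are inclusive.
#'
#' @param min_dp,max_dp Per-genotype depth bounds; calls outside are masked
#'   to missing.
#' @param min_mq Minimum site RMS mapping quality.
#' @param min_maf Minimum minor allele frequency (computed on non-missing
#'   calls, after depth masking).
#' @param max_missing Maximum fraction of missing calls per site.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_dp = 3, max_dp = 50, min_mq = 20,
                          min_maf = 0.05, max_missing = 0.1) {
  stopifnot(min_maf >= 0, min_maf <= 0.5, max_missing >= 0,
            max_missing <= 1, min_dp <= max_dp)
  structure(list(min_dp = min_dp, max_dp = max_dp, min_mq = min_mq,
                 min_maf = min_maf, max_missing = max_missing),
            class = "qc_thresholds")
}

#' Apply SNP quality control
#'
#' Filters a [genotype_dataset()] in a fixed, documented order:
#' 1. mask genotype calls with depth outside `[min_dp, max_dp]` to missing
#'    (skipped with a warning when no DP matrix is present);
#' 2. drop sites with RMS mapping quality below `min_mq`;
#' 3. drop sites whose missing-call fraction exceeds `max_missing`;
#' 4. drop sites whose minor allele frequency (on the remaining non-missing
#'    calls) is below `min_maf`.
#'
#' Depth masking runs first so that depth problems propagate into the
#' missingness and MAF filters, as they would in practice. To disable a
#' step, pass a vacuous bound (e.g. `min_mq = 0` or `max_missing = 1`).
#'
#' @param x A [genotype_dataset()].
#' @param thresholds A [qc_thresholds()] object.
#' @return List with elements `dataset` (filtered; empty with a warning if
#'   nothing survives) and `report` (one-row tibble reconciling counts:
#'   `sites_in = sites_out + removed_mq + removed_missing + removed_maf`).
#' @export
apply_qc <- function(x, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  g <- x$genotypes
  sites_in <- ncol(g)
  masked_calls <- 0L
  if (!is.null(x$dp)) {
    mask <- !is.na(x$dp) & !is.na(g) &
      (x$dp < thresholds$min_dp | x$dp > thresholds$max_dp)
    masked_calls <- sum(mask)
    g[mask] <- NA_integer_
  } else {
    warn("no per-sample DP available; depth mask skipped")
  }
  mq <- x$variants$mq
  fail_mq <- !is.na(mq) & mq < thresholds$min_mq
  miss_frac <- colMeans(is.na(g))
  fail_miss <- !fail_mq & miss_frac > thresholds$max_missing
  n <- 2 * colSums(!is.na(g))
  n_alt <- colSums(g, na.rm = TRUE)
  maf <- ifelse(n > 0, pmin(n_alt, n - n_alt) / n, 0)
  fail_maf <- !fail_mq & !fail_miss & maf < thresholds$min_maf
  keep <- !fail_mq & !fail_miss & !fail_maf
  report <- tibble(
    sites_in = sites_in,
    masked_calls_dp = as.integer(masked_calls),
    removed_mq = as.integer(sum(fail_mq)),
    removed_missing = as.integer(sum(fail_miss)),
    removed_maf = as.integer(sum(fail_maf)),
    sites_out = as.integer(sum(keep)))
  if (report$sites_out == 0) warn("QC removed all sites; returning empty dataset")
  out <- genotype_dataset(
    x$variants[keep, , drop = FALSE], g[, keep, drop = FALSE], x$popmap,
    dp = if (is.null(x$dp)) NULL else x$dp[, keep, drop = FALSE],
    contig_lengths = x$contig_lengths)
  list(dataset = out, report = report)
}
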