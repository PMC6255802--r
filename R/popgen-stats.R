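#' Pooled heterozygosity from summed major/minor allele counts
#'
#' Window-level expected heterozygosity computed from the window sums of
#' per-site major (`A = sum nMAJ`) and minor (`B = sum nMIN`) allele counts,
#' `Hp = 2AB / (A + B)^2`. Bounded on `[0, 0.5]`, maximal when the summed
#' minor fraction is one half, and depressed in swept windows where most
#' sites are near fixation. `normalization = "printed"` instead returns the
#' count-scale quantity `A * B / (A + B)` (see the methods vignette for why
#' the squared normalization is the default).
#'
#' @param sum_nmaj,sum_nmin Window sums of per-site major/minor allele
#'   counts. Vectorized.
#' @param normalization `"squared"` (default, bounded) or `"printed"`.
#' @return Numeric vector of Hp values; `NA` where both sums are zero.
#' @export
#' @examples
#' pooled_heterozygosity(10, 10) # 0.5
#' pooled_heterozygosity(30, 10) # 0.375
pooled_heterozygosity <- function(sum_nmaj, sum_nmin,
                                  normalization = c("squared", "printed")) {
  normalization <- match.arg(normalization)
  a <- as.numeric(sum_nmaj)
  b <- as.numeric(sum_nmin)
  if (any(a < 0 | b < 0, na.rm = TRUE)) abort("allele count sums must be >= 0")
  tot <- a + b
  out <- if (normalization == "squared") 2 * a * b / tot^2 else a * b / tot
  out[!is.na(tot) & tot == 0] <- NA_real_
  out
}

#' Per-site Fst variance components
#'
#' Computes per-site numerator and denominator components of Fst between two
#' populations from non-missing allele counts. The default is the
#' Weir & Cockerham (1984) variance-components estimator with allele copies
#' as sampling units; `estimator = "hudson"` gives the Hudson (1992)
#' estimator. Windowed Fst is obtained by the ratio of summed components
#' ("ratio of averages"), see [fst_window()].
#'
#' @param n_ref_a,n_alt_a Allele copy counts in population A (vectorized).
#' @param n_ref_b,n_alt_b Allele copy counts in population B.
#' @param estimator `"wc"` (default) or `"hudson"`.
#' @return Tibble with columns `num` and `den`; both `NA` for sites lacking
#'   at least one non-missing allele copy in each population.
#' @export
fst_site_components <- function(n_ref_a, n_alt_a, n_ref_b, n_alt_b,
                                estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  n1 <- as.numeric(n_ref_a + n_alt_a)
  n2 <- as.numeric(n_ref_b + n_alt_b)
  p1 <- ifelse(n1 > 0, n_alt_a / n1, NA_real_)
  p2 <- ifelse(n2 > 0, n_alt_b / n2, NA_real_)
  ok <- n1 > 0 & n2 > 0
  if (estimator == "wc") {
    # Weir & Cockerham (1984) with r = 2 samples of allele copies
    r <- 2
    nbar <- (n1 + n2) / r
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2)
    num <- a
    den <- a + b
    # a single copy per population leaves the correction undefined
    ok <- ok & (nbar > 1)
  } else {
    num <- (p1 - p2)^2 -
      ifelse(n1 > 1, p1 * (1 - p1) / (n1 - 1), NA_real_) -
      ifelse(n2 > 1, p2 * (1 - p2) / (n2 - 1), NA_real_)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    ok <- ok & n1 > 1 & n2 > 1
  }
  num[!ok] <- NA_real_
  den[!ok] <- NA_real_
  tibble(num = num, den = den)
}

#' Windowed Fst from per-site components
#'
#' Ratio of summed numerators to summed denominators over the sites of a
#' window. Negative values are reported as computed, not clipped.
#'
#' @param components Tibble from [fst_site_components()] (rows = sites).
#' @return Single Fst value; `NA` for an empty window or zero denominator.
#' @export
fst_window <- function(components) {
  num <- sum(components$num, na.rm = TRUE)
  den <- sum(components$den, na.rm = TRUE)
  if (nrow(components) == 0 || all(is.na(components$den)) || den == 0) {
    return(NA_real_)
  }
  num / den
}

#' Nucleotide diversity in a window
#'
#' Unbiased per-site heterozygosity `2 n_ref n_alt / (n (n - 1))` summed over
#' SNPs and divided by the window length in bp; the monomorphic remainder of
#' the window is assumed invariant. `n` is the per-site count of non-missing
#' allele copies.
#'
#' @param x A [genotype_dataset()].
#' @param population Population label.
#' @param contig,start,end Window, 0-based half-open.
#' @return Per-bp nucleotide diversity.
#' @export
nucleotide_diversity <- function(x, population, contig, start, end) {
  len <- end - start
  if (len <= 0) abort("window length must be positive")
  sub <- subset_region(x, contig, start, end)
  ac <- allele_counts(sub, population)
  sum(pi_site(ac$n_ref, ac$n_alt)) / len
}

# per-site unbiased pairwise-difference probability
pi_site <- function(n_ref, n_alt) {
  n <- n_ref + n_alt
  ifelse(n >= 2, 2 * n_ref * n_alt / (n * (n - 1)), 0)
}

# Tajima's D constants for n sequences
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D in a window
#'
#' Standard normalized difference between the mean pairwise diversity and
#' Watterson's estimator over the segregating sites of a window. Under
#' missingness the sample size entering the constants is the minimum
#' per-site number of non-missing allele copies in the window (a documented
#' conservative simplification).
#'
#' @inheritParams nucleotide_diversity
#' @return Tajima's D; `NA` when there are no segregating sites or fewer
#'   than 3 allele copies.
#' @export
tajimas_d <- function(x, population, contig, start, end) {
  sub <- subset_region(x, contig, start, end)
  ac <- allele_counts(sub, population)
  tajimas_d_counts(ac$n_ref, ac$n_alt)
}

# core computation from per-site allele counts
tajimas_d_counts <- function(n_ref, n_alt) {
  seg <- n_ref > 0 & n_alt > 0
  s_obs <- sum(seg)
  if (s_obs == 0) return(NA_real_)
  n <- min(n_ref[seg] + n_alt[seg])
  if (n < 3) return(NA_real_)
  k <- tajima_constants(n)
  pi_sum <- sum(pi_site(n_ref[seg], n_alt[seg]))
  denom <- sqrt(k$e1 * s_obs + k$e2 * s_obs * (s_obs - 1))
  if (denom == 0) return(NA_real_)
  (pi_sum - s_obs / k$a1) / denom
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of two genotype dosage vectors over the
#' samples non-missing at both sites (Rogers-Huff style, unphased).
#'
#' @param gi,gj Integer dosage vectors (0/1/2, `NA` = missing).
#' @return r-squared in `[0, 1]`; `NA` if fewer than 2 complete pairs or a
#'   zero-variance column.
#' @export
#' @examples
#' ld_r2(c(0, 0, 1, 1, 2, 2), c(0, 1, 0, 2, 1, 2))
ld_r2 <- function(gi, gj) {
  ok <- !is.na(gi) & !is.na(gj)
  if (sum(ok) < 2) return(NA_real_)
  xi <- gi[ok]
  xj <- gj[ok]
  if (var(xi) == 0 || var(xj) == 0) return(NA_real_)
  cor(xi, xj)^2
}

# all-pairs r2 and distances within one contig for one population's
# dosage matrix; returns tibble(dist, r2) with NA r2 for skipped pairs
pairwise_r2 <- function(g, pos, max_dist = Inf) {
  s <- ncol(g)
  if (s < 2) return(tibble(dist = integer(), r2 = numeric()))
  keep <- apply(g, 2, function(v) {
    v <- v[!is.na(v)]
    length(v) >= 2 && var(v) > 0
  })
  g <- g[, keep, drop = FALSE]
  pos <- pos[keep]
  s <- ncol(g)
  if (s < 2) return(tibble(dist = integer(), r2 = numeric()))
  cc <- suppressWarnings(cor(g, use = "pairwise.complete.obs"))
  iu <- which(upper.tri(cc), arr.ind = TRUE)
  d <- abs(pos[iu[, 2]] - pos[iu[, 1]])
  r2 <- cc[iu]^2
  ok <- d <= max_dist
  tibble(dist = as.integer(d[ok]), r2 = r2[ok])
}

#' LD decay curve
#'
#' Mean pairwise r-squared in physical-distance bins, per population, for
#' all SNP pairs up to `max_dist` apart within each contig (default 500 kb).
#'
#' @param x A [genotype_dataset()].
#' @param population Population label (default: all populations, one curve
#'   each).
#' @param max_dist Maximum pair distance in bp.
#' @param n_bins Number of equal-width distance bins.
#' @return Tibble with `population`, `bin_start`, `bin_end`, `mean_r2`
#'   (`NA` for empty bins) and `n_pairs`.
#' @export
ld_decay <- function(x, population = NULL, max_dist = 500000L, n_bins = 50L) {
  pops <- if (is.null(population)) unique(x$popmap$population) else population
  edges <- seq(0, max_dist, length.out = n_bins + 1)
  purrr::map_dfr(pops, function(p) {
    g_all <- x$genotypes[pop_samples(x, p), , drop = FALSE]
    pr <- purrr::map_dfr(unique(x$variants$contig), function(ctg) {
      j <- which(x$variants$contig == ctg)
      pairwise_r2(g_all[, j, drop = FALSE], x$variants$pos[j], max_dist)
    })
    bin <- cut(pr$dist, breaks = edges, include.lowest = TRUE,
               right = FALSE, labels = FALSE)
    out <- tibble(bin = seq_len(n_bins),
                  bin_start = edges[-length(edges)], bin_end = edges[-1])
    agg <- tibble(bin = bin, r2 = pr$r2) %>%
      filter(!is.na(.data$bin), !is.na(.data$r2)) %>%
      group_by(.data$bin) %>%
      summarise(mean_r2 = mean(.data$r2), n_pairs = dplyr::n(),
                .groups = "drop")
    out %>%
      left_join(agg, by = "bin") %>%
      mutate(n_pairs = ifelse(is.na(.data$n_pairs), 0L, .data$n_pairs),
             population = p) %>%
      select("population", "bin_start", "bin_end", "mean_r2", "n_pairs")
  })
}

#' Mean r-squared over all SNP pairs in a region
#'
#' @inheritParams nucleotide_diversity
#' @return Mean pairwise r-squared; `NA` if fewer than two usable SNPs.
#' @export
region_mean_r2 <- function(x, population, contig, start, end) {
  sub <- subset_region(x, contig, start, end)
  g <- sub$genotypes[pop_samples(sub, population), , drop = FALSE]
  pr <- pairwise_r2(g, sub$variants$pos)
  if (nrow(pr) == 0) return(NA_real_)
  mean(pr$r2, na.rm = TRUE)
}

#' Per-sample homozygosity
#'
#' Fraction of non-missing genotype calls that are homozygous (dosage 0
#' or 2) for each sample.
#'
#' @param x A [genotype_dataset()].
#' @return Tibble with `sample`, `population`, `n_calls`, `homozygosity`
#'   (`NA` for samples with zero non-missing calls).
#' @export
individual_homozygosity <- function(x) {
  g <- x$genotypes
  n_calls <- rowSums(!is.na(g))
  hom <- rowSums(g == 0L | g == 2L, na.rm = TRUE)
  tibble(sample = rownames(g)) %>%
    left_join(x$popmap, by = "sample") %>%
    mutate(n_calls = as.integer(n_calls),
           homozygosity = ifelse(n_calls > 0, hom / n_calls, NA_real_))
}

#' Z-transformation
#'
#' Standardizes a genome-wide statistic to mean 0 and sample standard
#' deviation 1 (ddof = 1) so that empirical tail quantiles define outliers.
#' `NA` entries pass through as `NA` and are excluded from the mean and sd.
#'
#' @param values Numeric vector.
#' @return Standardized vector of the same length.
#' @export
#' @examples
#' zscore(c(1, 2, 3)) # -1 0 1
zscore <- function(values) {
  fin <- is.finite(values)
  if (sum(fin) < 2) abort("zscore needs at least 2 finite values")
  m <- mean(values[fin])
  s <- sd(values[fin])
  if (s == 0) abort("zscore refused: values have zero spread")
  (values - m) / s
}
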