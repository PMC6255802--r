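# Independent brute-force oracles, coded directly from the published
# definitions with explicit loops; deliberately naive and separate from the
# package's vectorized implementations.

# pooled heterozygosity from raw per-site major/minor counts
oracle_hp <- function(nmaj, nmin) {
  A <- 0
  B <- 0
  for (i in seq_along(nmaj)) {
    A <- A + nmaj[i]
    B <- B + nmin[i]
  }
  2 * A * B / (A + B)^2
}

# Weir & Cockerham (1984) theta-hat for one window, r = 2 populations,
# allele copies as sampling units; ratio of averages over sites
oracle_wc_fst <- function(n_ref_a, n_alt_a, n_ref_b, n_alt_b) {
  num <- 0
  den <- 0
  for (i in seq_along(n_ref_a)) {
    n1 <- n_ref_a[i] + n_alt_a[i]
    n2 <- n_ref_b[i] + n_alt_b[i]
    if (n1 == 0 || n2 == 0) next
    if ((n1 + n2) / 2 <= 1) next
    p1 <- n_alt_a[i] / n1
    p2 <- n_alt_b[i] / n2
    r <- 2
    nbar <- (n1 + n2) / r
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    a <- (nbar / nc) *
      (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2)
    num <- num + a
    den <- den + a + b
  }
  if (den == 0) return(NA_real_)
  num / den
}

# mean pairwise difference per bp by exhaustive enumeration of allele
# copies; genotype dosage g splits each diploid into g alt copies and
# (2 - g) ref copies at every site
oracle_pi <- function(geno, len) {
  total <- 0
  for (s in seq_len(ncol(geno))) {
    g <- geno[, s]
    g <- g[!is.na(g)]
    copies <- c(rep(1, sum(g)), rep(0, 2 * length(g) - sum(g)))
    n <- length(copies)
    if (n < 2) next
    diffs <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) diffs <- diffs + as.integer(copies[i] != copies[j])
    }
    total <- total + diffs / choose(n, 2)
  }
  total / len
}

# Tajima's D from a complete (no-missing) dosage matrix
oracle_tajd <- function(geno) {
  n <- 2 * nrow(geno)
  ac <- colSums(geno)
  seg <- ac > 0 & ac < n
  S <- sum(seg)
  if (S == 0 || n < 3) return(NA_real_)
  pi_sum <- 0
  for (s in which(seg)) {
    pi_sum <- pi_sum + 2 * ac[s] * (n - ac[s]) / (n * (n - 1))
  }
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# squared Pearson correlation from first principles
oracle_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  num <- n * sxy - sx * sy
  den <- sqrt(n * sxx - sx^2) * sqrt(n * syy - sy^2)
  (num / den)^2
}

# random small genotype dataset on one contig
random_dataset <- function(n_samples = 8, n_snps = 50, len = 10000L,
                           missing = 0, n_pops = 2) {
  pos <- sort(sample.int(len, n_snps))
  p <- runif(n_snps, 0.05, 0.95)
  g <- sapply(p, function(pp) rbinom(n_samples, 2, pp))
  g <- matrix(as.integer(g), nrow = n_samples)
  if (missing > 0) g[runif(length(g)) < missing] <- NA_integer_
  samples <- sprintf("s%02d", seq_len(n_samples))
  pops <- rep(c("lowland", "highland"), length.out = n_pops)
  popmap <- tibble::tibble(
    sample = samples,
    population = rep_len(rep(pops, each = ceiling(n_samples / n_pops)),
                         n_samples))
  rownames(g) <- samples
  genotype_dataset(
    tibble::tibble(contig = "chr1", pos = pos,
                   ref = sample(c("A", "C", "G", "T"), n_snps, TRUE),
                   alt = "N", mq = 60),
    g, popmap, contig_lengths = c(chr1 = len))
}
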