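test_that("pooled heterozygosity matches closed forms and stays bounded", {
  expect_equal(pooled_heterozygosity(10, 10), 0.5)
  expect_equal(pooled_heterozygosity(20, 0), 0)
  expect_equal(pooled_heterozygosity(30, 10), 0.375)
  expect_true(is.na(pooled_heterozygosity(0, 0)))
  expect_error(pooled_heterozygosity(-1, 3), "count")
  # printed-equation variant is count-scale AB/(A+B)
  expect_equal(pooled_heterozygosity(30, 10, normalization = "printed"),
               30 * 10 / 40)
  # monotone decrease as the minor fraction moves away from 1/2
  tot <- 200
  b <- seq(100, 0, by = -5)
  hp <- pooled_heterozygosity(tot - b, b)
  expect_true(all(diff(hp) < 0))
  expect_true(all(hp >= 0 & hp <= 0.5))
})

test_that("Weir-Cockerham Fst matches fixation and no-differentiation cases", {
  fixed <- fst_site_components(10, 0, 0, 10)
  expect_equal(fst_window(fixed), 1.0)
  same <- fst_site_components(c(12, 6), c(8, 14), c(12, 6), c(8, 14))
  expect_lte(fst_window(same), 1e-12)
  expect_true(is.na(fst_window(fst_site_components(integer(), integer(),
                                                   integer(), integer()))))
})

test_that("per-site and windowed Fst agree with the brute-force oracle", {
  set.seed(42)
  for (i in 1:25) {
    n1 <- sample(4:24, 12, replace = TRUE)
    n2 <- sample(4:24, 12, replace = TRUE)
    a1 <- vapply(n1, function(n) sample(0:n, 1), integer(1))
    a2 <- vapply(n2, function(n) sample(0:n, 1), integer(1))
    comp <- fst_site_components(n1 - a1, a1, n2 - a2, a2)
    expect_equal(fst_window(comp),
                 oracle_wc_fst(n1 - a1, a1, n2 - a2, a2),
                 tolerance = 1e-12)
  }
  # spec-style single-site sanity case against the oracle
  comp <- fst_site_components(12, 8, 3, 17)
  expect_equal(comp$num / comp$den, oracle_wc_fst(12, 8, 3, 17),
               tolerance = 1e-12)
  # windowed ratio-of-averages equals per-site value for a 1-site window
  expect_equal(fst_window(comp), comp$num / comp$den)
})

test_that("Hudson Fst is sane at fixation and under no differentiation", {
  h <- fst_site_components(10, 0, 0, 10, estimator = "hudson")
  expect_equal(fst_window(h), 1.0)
  h2 <- fst_site_components(10, 10, 10, 10, estimator = "hudson")
  expect_lte(fst_window(h2), 1e-12)
})

test_that("nucleotide diversity equals exhaustive pairwise differences", {
  # 1 diploid = 2 haplotypes differing at 3 sites over 100 bp
  gd <- genotype_dataset(
    tibble::tibble(contig = "c", pos = c(10L, 20L, 30L),
                   ref = "A", alt = "T", mq = 60),
    matrix(c(1L, 1L, 1L), nrow = 1, dimnames = list("s1", NULL)),
    tibble::tibble(sample = "s1", population = "p"))
  expect_equal(nucleotide_diversity(gd, "p", "c", 0, 100), 0.03)
  # monomorphic window
  expect_equal(nucleotide_diversity(gd, "p", "c", 40, 140), 0)
  expect_error(nucleotide_diversity(gd, "p", "c", 10, 10), "length")
  set.seed(7)
  for (i in 1:10) {
    ds <- random_dataset(n_samples = 6, n_snps = 20, len = 500L,
                         missing = ifelse(i > 5, 0.1, 0))
    expect_equal(nucleotide_diversity(ds, "lowland", "chr1", 0, 500),
                 oracle_pi(ds$genotypes[pop_samples(ds, "lowland"), ,
                                        drop = FALSE], 500),
                 tolerance = 1e-12)
  }
})

test_that("Tajima's D matches the constants oracle and degenerate rules", {
  set.seed(11)
  for (i in 1:10) {
    ds <- random_dataset(n_samples = sample(3:8, 1), n_snps = 30,
                         len = 1000L, n_pops = 1)
    expect_equal(tajimas_d(ds, "lowland", "chr1", 0, 1000),
                 oracle_tajd(ds$genotypes), tolerance = 1e-10)
  }
  # n = 2 allele copies -> undefined
  one <- genotype_dataset(
    tibble::tibble(contig = "c", pos = 5L, ref = "A", alt = "T", mq = 60),
    matrix(1L, 1, 1, dimnames = list("s1", NULL)),
    tibble::tibble(sample = "s1", population = "p"))
  expect_true(is.na(tajimas_d(one, "p", "c", 0, 10)))
  # no segregating sites -> NA
  mono <- genotype_dataset(
    tibble::tibble(contig = "c", pos = 5L, ref = "A", alt = "T", mq = 60),
    matrix(c(0L, 0L, 0L), 3, 1, dimnames = list(c("a", "b", "d"), NULL)),
    tibble::tibble(sample = c("a", "b", "d"), population = "p"))
  expect_true(is.na(tajimas_d(mono, "p", "c", 0, 10)))
  # harmonic constant for two sequences
  expect_equal(sweepscan:::tajima_constants(2)$a1, 1.0)
})

test_that("r2 matches hand Pearson computation and is relabeling-invariant", {
  x <- c(0, 0, 1, 1, 2, 2)
  y <- c(0, 1, 0, 2, 1, 2)
  expect_equal(ld_r2(x, y), oracle_r2(x, y), tolerance = 1e-12)
  expect_equal(ld_r2(x, x), 1.0)
  expect_equal(ld_r2(x, 2 - x), 1.0)   # allele relabeling
  expect_equal(ld_r2(x, y), ld_r2(y, x))
  expect_true(is.na(ld_r2(c(1, 1, 1), c(0, 1, 2))))  # zero variance
  expect_true(is.na(ld_r2(c(0, NA, NA), c(0, 1, NA))))  # <2 complete pairs
  set.seed(3)
  for (i in 1:20) {
    a <- rbinom(10, 2, 0.5)
    b <- rbinom(10, 2, 0.5)
    if (var(a) == 0 || var(b) == 0) next
    expect_equal(ld_r2(a, b), oracle_r2(a, b), tolerance = 1e-12)
  }
})

test_that("ld_decay bins pairs correctly and reports empty bins as NA", {
  set.seed(5)
  ds <- random_dataset(n_samples = 8, n_snps = 40, len = 5000L)
  curve <- ld_decay(ds, max_dist = 5000L, n_bins = 5L)
  expect_equal(nrow(curve), 10)  # 5 bins x 2 populations
  expect_true(all(curve$mean_r2 >= 0 & curve$mean_r2 <= 1, na.rm = TRUE))
  expect_true(all(is.na(curve$mean_r2[curve$n_pairs == 0])))
  # bins are contiguous
  by_pop <- split(curve, curve$population)
  for (b in by_pop) {
    expect_equal(b$bin_start[-1], b$bin_end[-length(b$bin_end)])
  }
})

test_that("individual homozygosity counts hom calls over non-missing calls", {
  g <- rbind(
    all_hom = c(0L, 2L, 2L, 0L),
    all_het = c(1L, 1L, 1L, 1L),
    mixed = c(0L, 2L, 1L, NA))
  ds <- genotype_dataset(
    tibble::tibble(contig = "c", pos = c(1L, 2L, 3L, 4L), ref = "A",
                   alt = "T", mq = 60),
    g, tibble::tibble(sample = rownames(g), population = "p"))
  h <- individual_homozygosity(ds)
  expect_equal(h$homozygosity, c(1, 0, 2 / 3))
  # spec-style arithmetic: 7 hom of 8 non-missing calls
  g2 <- matrix(c(rep(0L, 5), rep(2L, 2), 1L, NA, NA), nrow = 1,
               dimnames = list("s", NULL))
  ds2 <- genotype_dataset(
    tibble::tibble(contig = "c", pos = 1:10, ref = "A", alt = "T", mq = 60),
    g2, tibble::tibble(sample = "s", population = "p"))
  expect_equal(individual_homozygosity(ds2)$homozygosity, 7 / 8)
})

test_that("zscore standardizes, passes NA through and is scale-equivariant", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  x <- c(2, 4, 4, 4, 5, 5, 7, 9)
  # frozen value from direct computation: (2 - mean(x)) / sd(x), ddof = 1
  expect_equal(zscore(x)[1], -3 / sqrt(32 / 7), tolerance = 1e-12)
  y <- rnorm(50)
  z <- zscore(y)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(zscore(3 * y + 7), z, tolerance = 1e-12)
  expect_equal(zscore(-2 * y + 1), -z, tolerance = 1e-12)
  yna <- c(y, NA)
  expect_true(is.na(zscore(yna)[51]))
  expect_equal(zscore(yna)[1:50], z, tolerance = 1e-12)
  expect_error(zscore(c(1, 1, 1)), "spread")
  expect_error(zscore(c(1, NA)), "finite")
})
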