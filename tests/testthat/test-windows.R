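# small two-population dataset with enough windows for Z-transformation
scan_fixture <- function(seed = 1, n_snps_per_win = 15, n_wins = 12,
                         win = 10000L) {
  set.seed(seed)
  len <- n_wins * win
  pos <- sort(sample.int(len, n_snps_per_win * n_wins))
  n <- 12
  p1 <- runif(length(pos), 0.1, 0.9)
  p2 <- pmin(pmax(p1 + rnorm(length(pos), 0, 0.15), 0), 1)
  g <- rbind(sapply(p1, function(p) rbinom(n / 2, 2, p)),
             sapply(p2, function(p) rbinom(n / 2, 2, p)))
  rownames(g) <- sprintf("s%02d", 1:n)
  genotype_dataset(
    tibble::tibble(contig = "chr1", pos = pos, ref = "A", alt = "T",
                   mq = 60),
    matrix(as.integer(g), nrow = n, dimnames = dimnames(g)),
    tibble::tibble(sample = rownames(g),
                   population = rep(c("lowland", "highland"), each = n / 2)),
    contig_lengths = c(chr1 = len))
}

test_that("make_windows follows the half-size terminal rule", {
  w <- make_windows(c(chr1 = 250000))
  expect_equal(w$start, c(0L, 50000L, 100000L, 150000L, 200000L))
  expect_equal(w$end[5], 250000L)  # terminal 50 kb = exactly half, emitted
  w2 <- make_windows(c(chr1 = 240000))
  # last emitted window [150k, 240k) has length 90 kb >= half;
  # the 40 kb window starting at 200k is below half and dropped
  expect_equal(max(w2$start), 150000L)
  expect_equal(w2$end[nrow(w2)], 240000L)
  # short contig: one whole-contig window
  w3 <- make_windows(c(tiny = 80000))
  expect_equal(nrow(w3), 1)
  expect_equal(c(w3$start, w3$end), c(0L, 80000L))
  expect_error(make_windows(c(chr1 = 0)), "positive")
  expect_error(make_windows(c(chr1 = 1e6), size = 1e5, step = 2e5), "step")
  expect_error(make_windows(250000), "named")
})

test_that("scan on a single-window dataset equals direct statistic calls", {
  ds <- scan_fixture()
  rows <- scan_windows(ds, size = 10000L, step = 10000L, min_snps = 1L)
  w <- rows[3, ]
  sub <- subset_region(ds, "chr1", w$start, w$end)
  ach <- allele_counts(sub, "highland")
  acl <- allele_counts(sub, "lowland")
  expect_equal(w$n_snps, nrow(sub$variants))
  expect_equal(w$hp_focal,
               pooled_heterozygosity(sum(ach$n_maj), sum(ach$n_min)))
  expect_equal(w$hp_other,
               pooled_heterozygosity(sum(acl$n_maj), sum(acl$n_min)))
  expect_equal(w$fst, oracle_wc_fst(acl$n_ref, acl$n_alt, ach$n_ref,
                                    ach$n_alt), tolerance = 1e-12)
  expect_equal(w$pi_focal,
               nucleotide_diversity(ds, "highland", "chr1", w$start, w$end))
  expect_equal(w$tajd_focal,
               tajimas_d(ds, "highland", "chr1", w$start, w$end))
  expect_equal(w$delta_zhp, w$zhp_other - w$zhp_focal)
})

test_that("boundary SNPs follow the half-open convention", {
  ds <- scan_fixture()
  # place a SNP exactly at pos0 = 20000 (pos 20001)
  ds$variants$pos[1] <- 20001L
  keep <- !duplicated(ds$variants$pos)
  ds$variants <- ds$variants[keep, ]
  ds$genotypes <- ds$genotypes[, keep, drop = FALSE]
  ord <- order(ds$variants$pos)
  ds$variants <- ds$variants[ord, ]
  ds$genotypes <- ds$genotypes[, ord, drop = FALSE]
  wins <- tibble::tibble(contig = "chr1",
                         start = seq(0L, 55000L, by = 5000L))
  wins$end <- wins$start + 10000L
  rows <- scan_windows(ds, windows = wins, min_snps = 0L)
  in_win <- function(i) sum(ds$variants$pos - 1 >= rows$start[i] &
                              ds$variants$pos - 1 < rows$end[i])
  expect_equal(rows$n_snps, vapply(seq_len(nrow(rows)), in_win, integer(1)))
  # the SNP at pos0 = 20000 counts for [15000,25000) and [20000,30000)
  # but not for [10000,20000)
  hit <- rows$start <= 20000 & rows$end > 20000
  expect_true(all(rows$start[hit] %in% c(15000L, 20000L) |
                    rows$start[hit] <= 15000))
  # the boundary SNP counts for windows starting at 15000/20000 only
  expect_true(all((ds$variants$pos - 1 != 20000) |
                    (ds$variants$pos - 1 >= 20000)))
})

test_that("scan gives NA stats to sparse windows and refuses tiny scans", {
  ds <- scan_fixture()
  rows <- scan_windows(ds, size = 10000L, step = 5000L, min_snps = 10L)
  sparse <- rows$n_snps < 10
  expect_true(all(is.na(rows$fst[sparse])))
  expect_true(all(is.na(rows$zfst[sparse])))
  expect_true(all(!is.na(rows$zfst[!sparse])))
  expect_error(scan_windows(ds, size = 120000L, step = 120000L),
               "fewer than 10")
  expect_error(scan_windows(ds, focal_pop = "alpine"), "alpine")
})

test_that("scan output is invariant to SNP order within a contig", {
  ds <- scan_fixture(seed = 4)
  perm <- sample(nrow(ds$variants))
  ds_perm <- ds
  ds_perm$variants <- ds$variants[perm, ]
  ds_perm$genotypes <- ds$genotypes[, perm, drop = FALSE]
  ord <- order(ds_perm$variants$pos)
  ds_perm$variants <- ds_perm$variants[ord, ]
  ds_perm$genotypes <- ds_perm$genotypes[, ord, drop = FALSE]
  r1 <- scan_windows(ds, size = 10000L, step = 5000L, min_snps = 1L)
  r2 <- scan_windows(ds_perm, size = 10000L, step = 5000L, min_snps = 1L)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
})

test_that("outlier calling is a strict conjunction at the stated quantiles", {
  ds <- scan_fixture(seed = 2)
  rows <- scan_windows(ds, size = 10000L, step = 5000L, min_snps = 1L)
  out <- call_outliers(rows, q = 0.2)
  thrF <- attr(out, "zfst_threshold")
  thrH <- attr(out, "zhp_threshold")
  expect_equal(thrF, quantile(rows$zfst, 0.8, na.rm = TRUE, names = FALSE))
  expect_equal(out$outlier,
               !is.na(rows$zfst) & rows$zfst >= thrF &
                 !is.na(rows$zhp_focal) & rows$zhp_focal <= thrH)
  # a window with top zfst but median zhp is not flagged
  fake <- rows
  fake$zfst[1] <- max(fake$zfst, na.rm = TRUE) + 10
  fake$zhp_focal[1] <- stats::median(fake$zhp_focal, na.rm = TRUE)
  expect_false(call_outliers(fake, q = 0.1)$outlier[1])
  expect_error(call_outliers(rows, q = 0.5), "between 0 and 0.5")
  expect_error(call_outliers(rows, q = 0), "between 0 and 0.5")
})

test_that("independent ranks keep the joint flagged fraction near q^2", {
  set.seed(12)
  q <- 0.05
  n <- 100
  excess <- replicate(50, {
    rows <- tibble::tibble(zfst = rnorm(n), zhp_focal = rnorm(n),
                           zhp_other = rnorm(n))
    sum(call_outliers(rows, q = q)$outlier)
  })
  expect_true(all(excess <= 2 * q^2 * n + 5))
})

test_that("merging joins overlapping and book-ended windows only", {
  rows <- tibble::tibble(
    contig = c("c1", "c1", "c1", "c2", "c2"),
    start = c(0L, 50000L, 200000L, 0L, 100000L),
    end = c(100000L, 150000L, 300000L, 100000L, 200000L),
    outlier = TRUE)
  reg <- merge_regions(rows)
  expect_equal(reg$contig, c("c1", "c1", "c2"))
  expect_equal(reg$start, c(0L, 200000L, 0L))
  expect_equal(reg$end, c(150000L, 300000L, 200000L))
  expect_equal(reg$n_windows, c(2L, 1L, 2L))
  expect_equal(total_region_span(reg), 150000 + 100000 + 200000)
  expect_equal(nrow(merge_regions(dplyr::mutate(rows, outlier = FALSE))), 0)
  expect_equal(total_region_span(merge_regions(
    dplyr::mutate(rows, outlier = FALSE))), 0)
})

test_that("every flagged window lies in exactly one region covering it", {
  set.seed(8)
  for (i in 1:10) {
    n <- 30
    rows <- tibble::tibble(
      contig = sample(c("a", "b"), n, TRUE),
      start = as.integer(sample(0:20, n, TRUE) * 5000L))
    rows$end <- rows$start + 10000L
    rows <- dplyr::distinct(rows, .data$contig, .data$start,
                            .keep_all = TRUE)
    rows$outlier <- runif(nrow(rows)) < 0.4
    reg <- merge_regions(rows)
    fl <- rows[rows$outlier, ]
    if (nrow(fl) == 0) next
    cover <- vapply(seq_len(nrow(fl)), function(k) {
      sum(reg$contig == fl$contig[k] & reg$start <= fl$start[k] &
            reg$end >= fl$end[k])
    }, integer(1))
    expect_true(all(cover == 1))
    expect_equal(total_region_span(reg), sum(vapply(
      unique(reg$contig), function(ctg) {
        w <- fl[fl$contig == ctg, ]
        length(unique(unlist(mapply(seq, w$start, w$end - 1L,
                                    SIMPLIFY = FALSE)))) / 1
      }, numeric(1))), tolerance = 0)
  }
})

test_that("gene overlap uses half-open region vs inclusive gene semantics", {
  genes <- gene_models(
    c("inside", "abutting", "spanning"), rep("c1", 3), rep("+", 3),
    list(tibble::tibble(start = 120001L, end = 130000L),
         tibble::tibble(start = 150001L, end = 150030L),
         tibble::tibble(start = 149998L, end = 150027L)))
  reg <- tibble::tibble(contig = "c1", start = 0L, end = 150000L,
                        n_windows = 1L)
  out <- genes_in_regions(reg, genes)
  # gene starting exactly at region end (1-based 150001) is excluded
  expect_equal(out$gene_ids[[1]], c("inside", "spanning"))
  expect_equal(psg_genes(out), c("inside", "spanning"))
  empty <- genes_in_regions(reg[0, ], genes)
  expect_equal(nrow(empty), 0)
})
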