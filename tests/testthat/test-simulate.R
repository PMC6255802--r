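# small, fast scenario used throughout
mini_config <- function(...) {
  args <- list(n_anc = 50, n_low = 50, n_high = 50, bottleneck_frac = 1,
               t_split = 50, t_total = 250, mu = 1e-6, rho = 1e-7,
               contig_lengths = c(ctg1 = 30000L), sample_low = 6,
               sample_high = 6, n_genes = 3, seed = 1L)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

test_that("no mutation means no variation; identical seeds replay exactly", {
  s0 <- simulate_two_pop(mini_config(mu = 0))
  expect_equal(nrow(s0$dataset$variants), 0)
  expect_equal(ncol(s0$dataset$genotypes), 0)
  a <- simulate_two_pop(mini_config(seed = 42))
  b <- simulate_two_pop(mini_config(seed = 42))
  expect_identical(a$dataset$genotypes, b$dataset$genotypes)
  expect_identical(a$dataset$variants, b$dataset$variants)
  expect_identical(a$reference, b$reference)
  c <- simulate_two_pop(mini_config(seed = 43))
  expect_false(identical(a$dataset$genotypes, c$dataset$genotypes))
})

test_that("invalid scenarios are rejected", {
  expect_error(mini_config(sample_low = 60), "sample_low")
  expect_error(mini_config(contig_lengths = integer()), "contig")
  expect_error(mini_config(sweep = list(contig = "nope", pos = 10L, s = 0.1)),
               "contig")
  expect_error(mini_config(sweep = list(contig = "ctg1", pos = 40000L,
                                        s = 0.1)), "inside")
  expect_error(mini_config(sweep = list(contig = "ctg1", pos = 100L, s = 0.1,
                                        t_onset = 50)), "t_onset")
})

test_that("genotypes are valid dosages at unique increasing positions", {
  sim <- simulate_two_pop(mini_config(seed = 5))
  g <- sim$dataset$genotypes
  expect_true(all(g %in% 0:2))
  expect_true(all(diff(sim$dataset$variants$pos) > 0))
  # every returned site segregates in the sample
  ac <- colSums(g)
  expect_true(all(ac > 0 & ac < 2 * nrow(g)))
  # population labels and sizes as configured
  expect_equal(sort(unique(sim$dataset$popmap$population)),
               c("highland", "lowland"))
  expect_equal(sum(sim$dataset$popmap$population == "highland"), 6)
  # REF alleles agree with the reference sequence
  v <- sim$dataset$variants
  expect_equal(substring(sim$reference[["ctg1"]], v$pos, v$pos), v$ref)
  expect_true(all(v$ref != v$alt))
})

test_that("segregating sites match the Watterson expectation", {
  # effectively panmictic neutral scenario: tiny split, equal sizes
  n <- 100
  reps <- 20
  s_obs <- vapply(seq_len(reps), function(seed) {
    cfg <- sim_config(n_anc = n, n_low = n, n_high = n, bottleneck_frac = 1,
                      t_split = 10, t_total = 1600, mu = 1e-7,
                      contig_lengths = c(c1 = 200000L),
                      sample_low = 10, sample_high = 10, seed = seed)
    nrow(simulate_two_pop(cfg)$dataset$variants)
  }, numeric(1))
  k <- 2 * 20  # sampled allele copies
  expected <- 4 * n * 1e-7 * 200000 * sum(1 / seq_len(k - 1))
  expect_gt(mean(s_obs), 0.7 * expected)
  expect_lt(mean(s_obs), 1.3 * expected)
})

test_that("neutral diversity matches the 4Nmu equilibrium expectation", {
  reps <- 20
  n <- 100
  pis <- vapply(seq_len(reps), function(seed) {
    cfg <- sim_config(n_anc = n, n_low = n, n_high = n, bottleneck_frac = 1,
                      t_split = 10, t_total = 1600, mu = 1e-7,
                      contig_lengths = c(c1 = 200000L),
                      sample_low = 10, sample_high = 10, seed = 100 + seed)
    sim <- simulate_two_pop(cfg)
    nucleotide_diversity(sim$dataset, "lowland", "c1", 0, 200000)
  }, numeric(1))
  expect_gt(mean(pis), 0.7 * 4 * n * 1e-7)
  expect_lt(mean(pis), 1.3 * 4 * n * 1e-7)
})

test_that("a strong sweep fixes in most replicates and is logged honestly", {
  reps <- 20
  fixed <- vapply(seq_len(reps), function(seed) {
    cfg <- sim_config(n_anc = 100, n_low = 100, n_high = 100,
                      bottleneck_frac = 1, t_split = 400, t_total = 700,
                      mu = 3e-7, contig_lengths = c(c1 = 50000L),
                      sweep = list(contig = "c1", pos = 25000L, s = 0.1,
                                   h = 0.5, t_onset = 0,
                                   target_pop = "highland"),
                      sample_low = 8, sample_high = 8, seed = 200 + seed)
    sim <- simulate_two_pop(cfg)
    expect_equal(nrow(sim$truth), 1)
    expect_true(is.finite(sum(sim$log$reseeds)))
    sim$truth$fixed_in_target
  }, logical(1))
  expect_gte(mean(fixed), 0.8)
})

test_that("missingness injection and depth simulation feed the QC layer", {
  sim <- simulate_two_pop(mini_config(seed = 9, missing_rate = 0.2))
  miss <- mean(is.na(sim$dataset$genotypes))
  expect_gt(miss, 0.1)
  expect_lt(miss, 0.3)
  expect_true(all(sim$dataset$dp >= 1))
  expect_equal(dim(sim$dataset$dp), dim(sim$dataset$genotypes))
})

test_that("place_genes yields in-frame non-overlapping genes, seeded", {
  cfg <- mini_config(seed = 13)
  genes <- place_genes(cfg)
  expect_equal(nrow(genes), 3)
  expect_true(all(genes$cds_len %% 3 == 0))
  expect_true(all(genes$translatable))
  ord <- order(genes$start)
  expect_true(all(genes$start[ord][-1] > genes$end[ord][-3]))
  expect_identical(place_genes(cfg), genes)
  # a sweep gets a gene spanning its position
  cfgs <- mini_config(seed = 13,
                      sweep = list(contig = "ctg1", pos = 14321L, s = 0.1,
                                   t_onset = 0, target_pop = "highland"))
  gs <- place_genes(cfgs)
  tg <- attr(gs, "truth_gene")
  hit <- gs[gs$gene_id == tg, ]
  expect_true(hit$start <= 14321 && hit$end >= 14321)
  expect_error(place_genes(mini_config(n_genes = 100)), "too short")
})

test_that("export writes a consistent bundle that round-trips", {
  cfg <- mini_config(seed = 17,
                     sweep = list(contig = "ctg1", pos = 15000L, s = 0.1,
                                  t_onset = 0, target_pop = "highland"))
  sim <- simulate_two_pop(cfg)
  genes <- place_genes(cfg, sim$reference)
  dir <- withr::local_tempdir()
  paths <- export_simulation(sim, genes, dir, cfg)
  expect_true(all(file.exists(paths)))
  # VCF header declares the configured contig
  hdr <- readLines(paths[["vcf"]], n = 20)
  expect_true(any(grepl("##contig=<ID=ctg1,length=30000>", hdr, fixed = TRUE)))
  back <- read_vcf(paths[["vcf"]], paths[["popmap"]])
  expect_identical(back$genotypes, sim$dataset$genotypes)
  # truth.bed holds exactly one half-open interval at the sweep site
  bed <- read.table(paths[["truth"]], sep = "\t")
  expect_equal(nrow(bed), 1)
  expect_equal(c(bed$V2, bed$V3), c(14999, 15000))
  # GFF round-trip preserves the models, including CDS sequences
  gback <- read_gff3(paths[["gff"]], paths[["fasta"]])
  expect_equal(gback$gene_id, genes$gene_id)
  expect_equal(gback$seq, genes$seq)
  # config echo carries the seed
  cfg_back <- yaml::read_yaml(paths[["config"]])
  expect_equal(cfg_back$seed, 17)
  # identical seed reruns produce byte-identical files
  dir2 <- withr::local_tempdir()
  sim2 <- simulate_two_pop(cfg)
  export_simulation(sim2, place_genes(cfg, sim2$reference), dir2, cfg)
  for (f in c("sim.vcf", "popmap.tsv", "genes.gff3", "truth.bed")) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
  }
})
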