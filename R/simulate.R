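#' Two-population Wright-Fisher simulation scenario
#'
#' Defines a forward-in-time diploid Wright-Fisher scenario: an ancestral
#' population at mutation-drift equilibrium splits into a lowland and a
#' highland population; the highland population optionally passes through a
#' founder bottleneck (reduced diversity, elevated LD) and may carry a hard
#' sweep private to it. Parameters are rescaled to desk size (small N,
#' inflated per-site mutation rate) so that per-window SNP densities and the
#' qualitative highland/lowland contrasts match a resequencing study; the
#' rescaling is validated against Watterson's closed form in the test suite.
#'
#' @param n_anc,n_low,n_high Diploid population sizes (ancestral, lowland,
#'   highland).
#' @param bottleneck_frac Multiplier on `n_high` during the first
#'   `bottleneck_gens` generations after the split (1 = no bottleneck).
#' @param bottleneck_gens Duration of the founder bottleneck, generations.
#' @param t_split Generations since the split.
#' @param t_total Total simulated generations (burn-in = `t_total -
#'   t_split`).
#' @param mu Per-site per-generation mutation rate.
#' @param rho Per-bp per-generation crossover rate (crossover count per
#'   meiosis is Poisson(`rho * L`), breakpoints uniform).
#' @param contig_lengths Named vector of contig lengths (bp).
#' @param sweep Optional list `list(contig =, pos =, s =, h = 0.5,
#'   t_onset = 0, target_pop = "highland")` describing a hard sweep; the
#'   beneficial allele starts as a single copy and is re-seeded on loss
#'   (standard conditioning, logged).
#' @param sample_low,sample_high Diploid sample sizes drawn at the end.
#' @param n_genes Genes placed per contig by [place_genes()].
#' @param dp_mean Mean of the Poisson per-call depth written to VCF
#'   (floored at 1); with the default QC thresholds these depths pass.
#' @param mq Site RMS mapping quality written to VCF.
#' @param missing_rate Per-call missingness injected into the sampled
#'   genotypes (QC testing knob; default none).
#' @param max_reseed Error after this many sweep re-seedings.
#' @param seed Integer seed; identical configs and seeds give byte-identical
#'   output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_anc = 100, n_low = 100, n_high = 100,
                       bottleneck_frac = 0.1, bottleneck_gens = 20,
                       t_split = 50, t_total = 1050,
                       mu = 3e-7, rho = 1e-7,
                       contig_lengths = c(contig1 = 500000L,
                                          contig2 = 500000L,
                                          contig3 = 500000L,
                                          contig4 = 500000L),
                       sweep = NULL,
                       sample_low = 10, sample_high = 12,
                       n_genes = 8, dp_mean = 15, mq = 60,
                       missing_rate = 0, max_reseed = 1000, seed = 1L) {
  cfg <- list(n_anc = n_anc, n_low = n_low, n_high = n_high,
              bottleneck_frac = bottleneck_frac,
              bottleneck_gens = bottleneck_gens,
              t_split = t_split, t_total = t_total, mu = mu, rho = rho,
              contig_lengths = contig_lengths, sweep = sweep,
              sample_low = sample_low, sample_high = sample_high,
              n_genes = n_genes, dp_mean = dp_mean, mq = mq,
              missing_rate = missing_rate, max_reseed = max_reseed,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (length(contig_lengths) == 0) abort("at least one contig is required")
    if (is.null(names(contig_lengths)) || any(names(contig_lengths) == "")) {
      abort("contig_lengths must be named")
    }
    stopifnot(n_anc > 0, n_low > 0, n_high > 0, t_split > 0,
              t_total >= t_split, mu >= 0, mu <= 1, rho >= 0, rho <= 1,
              bottleneck_frac > 0, bottleneck_gens >= 0,
              all(contig_lengths > 0), sample_low > 0, sample_high > 0)
    if (sample_low > n_low) abort("sample_low exceeds n_low")
    n_high_min <- if (bottleneck_gens >= t_split) {
      max(1, round(bottleneck_frac * n_high))
    } else n_high
    if (sample_high > n_high_min) abort("sample_high exceeds n_high at sampling")
    if (!is.null(sweep)) {
      stopifnot(!is.null(sweep$contig), !is.null(sweep$pos),
                !is.null(sweep$s))
      if (!sweep$contig %in% names(contig_lengths)) {
        abort("sweep contig not in contig_lengths")
      }
      if (sweep$pos <= 0 || sweep$pos >= contig_lengths[[sweep$contig]]) {
        abort("sweep position must lie inside its contig")
      }
      t_onset <- if (is.null(sweep$t_onset)) 0 else sweep$t_onset
      if (t_onset >= t_split) abort("sweep t_onset must be < t_split")
      tp <- if (is.null(sweep$target_pop)) "highland" else sweep$target_pop
      if (!tp %in% c("highland", "lowland")) {
        abort("sweep target_pop must be 'highland' or 'lowland'")
      }
    }
  })
  invisible(cfg)
}

#' Simulate a two-population resequencing dataset
#'
#' Runs the forward Wright-Fisher model of a [sim_config()] contig by
#' contig and returns sampled diploid genotypes at all sites segregating in
#' the sample, together with ground truth for sweep-recovery benchmarks.
#' Population labels are `"lowland"` and `"highland"`.
#'
#' @param config A [sim_config()].
#' @return List with elements `dataset` (a [genotype_dataset()], including
#'   simulated per-call depths and site mapping qualities), `truth` (tibble
#'   with `sweep_contig`, `sweep_pos`, `fixed_in_target`, `seed`,
#'   `n_segregating`; zero rows when no sweep is configured), `reference`
#'   (named character vector of contig sequences) and `log` (collision and
#'   re-seed counts).
#' @export
simulate_two_pop <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  reference <- vapply(config$contig_lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))

  sw <- config$sweep
  target_high <- is.null(sw) || is.null(sw$target_pop) ||
    identical(sw$target_pop, "highland")
  res <- purrr::map(names(config$contig_lengths), function(ctg) {
    L <- as.integer(config$contig_lengths[[ctg]])
    on_this <- !is.null(sw) && identical(sw$contig, ctg)
    wf_sim_contig(
      L, config$n_anc, config$n_low, config$n_high,
      config$bottleneck_frac, config$bottleneck_gens,
      config$t_split, config$t_total, config$mu, config$rho,
      if (on_this) as.integer(sw$pos) else -1L,
      if (on_this) sw$s else 0,
      if (on_this && !is.null(sw$h)) sw$h else 0.5,
      if (on_this && !is.null(sw$t_onset)) as.integer(sw$t_onset) else 0L,
      as.integer(target_high),
      config$sample_low, config$sample_high, config$max_reseed)
  })
  names(res) <- names(config$contig_lengths)

  n_ind <- config$sample_low + config$sample_high
  samples <- c(sprintf("low_%02d", seq_len(config$sample_low)),
               sprintf("high_%02d", seq_len(config$sample_high)))
  popmap <- tibble(sample = samples,
                   population = rep(c("lowland", "highland"),
                                    c(config$sample_low, config$sample_high)))

  geno_list <- list()
  var_list <- list()
  for (ctg in names(res)) {
    r <- res[[ctg]]
    pos <- as.integer(r$positions)
    s <- length(pos)
    if (s == 0) next
    haps <- r$haplotypes
    g <- haps[seq(1, 2 * n_ind, by = 2), , drop = FALSE] +
      haps[seq(2, 2 * n_ind, by = 2), , drop = FALSE]
    refseq <- reference[[ctg]]
    ref_base <- substring(refseq, pos, pos)
    alt_base <- vapply(ref_base, function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1), USE.NAMES = FALSE)
    geno_list[[ctg]] <- g
    var_list[[ctg]] <- tibble(contig = ctg, pos = pos,
                              ref = ref_base, alt = alt_base,
                              mq = config$mq)
  }
  if (length(geno_list) > 0) {
    genotypes <- do.call(cbind, geno_list)
    variants <- bind_rows(var_list)
  } else {
    genotypes <- matrix(integer(), nrow = n_ind, ncol = 0)
    variants <- tibble(contig = character(), pos = integer(),
                       ref = character(), alt = character(), mq = numeric())
  }
  rownames(genotypes) <- samples
  storage.mode(genotypes) <- "integer"
  if (config$missing_rate > 0 && length(genotypes) > 0) {
    drop <- runif(length(genotypes)) < config$missing_rate
    genotypes[drop] <- NA_integer_
  }
  dp <- matrix(pmax(1L, rpois(length(genotypes), config$dp_mean)),
               nrow = n_ind, dimnames = dimnames(genotypes))
  ds <- genotype_dataset(variants, genotypes, popmap, dp = dp,
                         contig_lengths = config$contig_lengths)

  truth <- if (is.null(sw)) {
    tibble(sweep_contig = character(), sweep_pos = integer(),
           fixed_in_target = logical(), seed = integer(),
           n_segregating = integer())
  } else {
    r <- res[[sw$contig]]
    tibble(sweep_contig = sw$contig, sweep_pos = as.integer(sw$pos),
           fixed_in_target = !is.na(r$sweep_freq_target) &&
             r$sweep_freq_target >= 0.99,
           seed = config$seed, n_segregating = nrow(variants))
  }
  log <- tibble(contig = names(res),
                collisions = vapply(res, `[[`, numeric(1), "collisions"),
                reseeds = vapply(res, `[[`, numeric(1), "reseeds"))
  list(dataset = ds, truth = truth, reference = reference, log = log)
}

#' Place synthetic gene models on the simulated contigs
#'
#' Non-overlapping single-exon genes with CDS length divisible by 3 are
#' placed deterministically under the config seed; when a sweep is
#' configured, one gene is guaranteed to span the sweep position (the truth
#' gene, named in attribute `truth_gene`). Strands are random.
#'
#' @param config A [sim_config()].
#' @param reference Optional named character vector of contig sequences
#'   (from [simulate_two_pop()]); when given, CDS sequences are cached.
#' @return A [gene_models()] tibble.
#' @export
place_genes <- function(config, reference = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  sw <- config$sweep
  rows <- purrr::map_dfr(names(config$contig_lengths), function(ctg) {
    L <- as.integer(config$contig_lengths[[ctg]])
    ng <- config$n_genes
    # genes ~1.2 kb in slots spread evenly along the contig
    cds_len <- 3L * sample(300:600, ng, replace = TRUE)
    slot <- as.integer(floor(L / ng))
    if (slot < max(cds_len) + 2L) {
      abort(paste0("contig ", ctg, " too short for ", ng, " genes"))
    }
    start <- (seq_len(ng) - 1L) * slot +
      vapply(slot - cds_len, function(m) sample.int(m, 1), integer(1))
    tibble(contig = ctg,
           gene_id = sprintf("%s_g%03d", ctg, seq_len(ng)),
           start = start, end = start + cds_len - 1L,
           strand = sample(c("+", "-"), ng, replace = TRUE))
  })
  if (!is.null(sw)) {
    # re-anchor the nearest gene on the sweep contig so it spans sweep_pos
    i <- which(rows$contig == sw$contig)
    d <- abs((rows$start[i] + rows$end[i]) / 2 - sw$pos)
    j <- i[which.min(d)]
    len <- rows$end[j] - rows$start[j] + 1L
    new_start <- as.integer(max(1, min(sw$pos - floor(len / 2),
                                       config$contig_lengths[[sw$contig]] -
                                         len + 1)))
    rows$start[j] <- new_start
    rows$end[j] <- new_start + len - 1L
    truth_gene <- rows$gene_id[j]
  } else {
    truth_gene <- NA_character_
  }
  rows <- arrange(rows, .data$contig, .data$start)
  # drop any overlaps introduced by re-anchoring (keep the truth gene)
  keep <- rep(TRUE, nrow(rows))
  for (k in seq_len(nrow(rows))[-1]) {
    prev <- max(which(keep[seq_len(k - 1)] &
                        rows$contig[seq_len(k - 1)] == rows$contig[k]),
                -Inf)
    if (is.finite(prev) && rows$start[k] <= rows$end[prev]) {
      keep[if (rows$gene_id[k] == truth_gene %||% "") prev else k] <- FALSE
    }
  }
  rows <- rows[keep, ]
  out <- gene_models(rows$gene_id, rows$contig, rows$strand,
                     purrr::map2(rows$start, rows$end,
                                 function(s, e) tibble(start = s, end = e)))
  if (!is.null(reference)) out <- add_cds_sequence(out, reference)
  attr(out, "truth_gene") <- truth_gene
  out
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Export a simulation to analysis-ready files
#'
#' Writes `sim.vcf` (VCF 4.2 with GT and per-call DP, site INFO/MQ and
#' contig header lines), `popmap.tsv`, `genes.gff3`, `ref.fa`, `truth.bed`
#' (0-based half-open; one interval per configured sweep) and
#' `sim_config.yaml` (an echo of the full resolved configuration).
#' Reading `sim.vcf` back with [read_vcf()] reproduces the genotype matrix
#' exactly.
#'
#' @param sim Result of [simulate_two_pop()].
#' @param genes A [gene_models()] tibble from [place_genes()].
#' @param outdir Output directory (created if needed).
#' @param config The [sim_config()] used (echoed to YAML).
#' @return Named character vector of the written paths, invisibly.
#' @export
export_simulation <- function(sim, genes, outdir, config = NULL) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE)
  if (!ok) abort(paste0("cannot create output directory: ", outdir))
  paths <- c(vcf = file.path(outdir, "sim.vcf"),
             popmap = file.path(outdir, "popmap.tsv"),
             gff = file.path(outdir, "genes.gff3"),
             fasta = file.path(outdir, "ref.fa"),
             truth = file.path(outdir, "truth.bed"),
             config = file.path(outdir, "sim_config.yaml"))
  write_vcf(sim$dataset, paths[["vcf"]])
  write_popmap(sim$dataset$popmap, paths[["popmap"]])
  write_gff3(genes, paths[["gff"]])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$reference),
                              paths[["fasta"]])
  if (nrow(sim$truth) > 0) {
    writeLines(sprintf("%s\t%d\t%d\tsweep", sim$truth$sweep_contig,
                       sim$truth$sweep_pos - 1L, sim$truth$sweep_pos),
               paths[["truth"]])
  } else {
    writeLines(character(), paths[["truth"]])
  }
  if (!is.null(config)) {
    cfg <- unclass(config)
    cfg$contig_lengths <- as.list(cfg$contig_lengths)
    yaml::write_yaml(cfg, paths[["config"]])
  }
  invisible(paths)
}
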