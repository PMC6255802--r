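#' Pipeline: simulate a dataset and export it
#'
#' @param outdir Output directory.
#' @param config A [sim_config()]; built from `seed` and `...` overrides
#'   when `NULL`.
#' @param seed Seed used when `config` is `NULL`.
#' @param ... Passed to [sim_config()] when `config` is `NULL`.
#' @return Invisibly, the list from [simulate_two_pop()] plus `genes` and
#'   `paths`.
#' @export
run_simulate <- function(outdir, config = NULL, seed = 1L, ...) {
  if (is.null(config)) config <- sim_config(seed = seed, ...)
  sim <- simulate_two_pop(config)
  genes <- place_genes(config, sim$reference)
  paths <- export_simulation(sim, genes, outdir, config)
  message(sprintf("simulate: %d SNPs, %d samples -> %s",
                  nrow(sim$dataset$variants), nrow(sim$dataset$genotypes),
                  outdir))
  invisible(c(sim, list(genes = genes, paths = paths)))
}

#' Pipeline: QC-filter a VCF
#'
#' @param vcf,popmap Input paths.
#' @param outdir Output directory for `filtered.vcf` and `qc_report.tsv`.
#' @param thresholds A [qc_thresholds()].
#' @return Invisibly, the [apply_qc()] result.
#' @export
run_filter <- function(vcf, popmap, outdir, thresholds = qc_thresholds()) {
  ds <- read_vcf(vcf, popmap)
  res <- apply_qc(ds, thresholds)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(res$dataset, file.path(outdir, "filtered.vcf"))
  write_qc_report(res$report, file.path(outdir, "qc_report.tsv"))
  message(sprintf("filter: %d -> %d sites", res$report$sites_in,
                  res$report$sites_out))
  invisible(res)
}

#' Pipeline: windowed sweep scan
#'
#' QC, windowed statistics, Z-transformation, joint-quantile outlier
#' calling, region merging and (when gene models are given) gene overlap.
#' Writes `windows.tsv`, `regions.bed` and `psg_genes.txt`.
#'
#' @param vcf,popmap Input paths.
#' @param outdir Output directory.
#' @param gff Optional GFF3 of gene models.
#' @param size,step,min_snps,focal_pop,q,estimator Scan parameters, see
#'   [scan_windows()] and [call_outliers()].
#' @param thresholds QC thresholds applied before scanning (`NULL` to skip
#'   QC).
#' @return Invisibly, list with `windows`, `regions`, `psg`.
#' @export
run_scan <- function(vcf, popmap, outdir, gff = NULL,
                     size = 100000L, step = 50000L, min_snps = 10L,
                     focal_pop = "highland", q = 0.05,
                     estimator = "wc", thresholds = qc_thresholds()) {
  ds <- read_vcf(vcf, popmap)
  if (!is.null(thresholds)) ds <- apply_qc(ds, thresholds)$dataset
  rows <- scan_windows(ds, size = size, step = step, min_snps = min_snps,
                       focal_pop = focal_pop, estimator = estimator)
  rows <- call_outliers(rows, q = q)
  regions <- merge_regions(rows)
  psg <- character()
  if (!is.null(gff)) {
    genes <- read_gff3(gff)
    regions <- genes_in_regions(regions, genes)
    psg <- psg_genes(regions)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_windows_tsv(rows, file.path(outdir, "windows.tsv"))
  write_regions_bed(regions, file.path(outdir, "regions.bed"))
  writeLines(psg, file.path(outdir, "psg_genes.txt"))
  message(sprintf("scan: %d windows, %d outliers, %d regions (%.1f kb), %d genes",
                  nrow(rows), sum(rows$outlier, na.rm = TRUE),
                  nrow(regions), total_region_span(regions) / 1000,
                  length(psg)))
  invisible(list(windows = rows, regions = regions, psg = psg))
}

#' Pipeline: classify coding effects of all VCF variants
#'
#' @param vcf,popmap,gff,fasta Input paths.
#' @param outdir Output directory for `effects.tsv`.
#' @return Invisibly, the effects tibble.
#' @export
run_annotate <- function(vcf, popmap, gff, fasta, outdir) {
  ds <- read_vcf(vcf, popmap)
  genes <- read_gff3(gff, fasta)
  eff <- classify_variants(ds, genes)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_effects_tsv(eff, file.path(outdir, "effects.tsv"))
  message(sprintf("annotate: %d effects (%d amino-acid changing)",
                  nrow(eff),
                  sum(eff$category %in% c("missense", "nonsense",
                                          "stop_loss"))))
  invisible(eff)
}

#' Pipeline: per-locus diagnostics
#'
#' @param vcf,popmap Input paths.
#' @param region Region string `"contig:start-end"` (1-based inclusive).
#' @param outdir Output directory for `locus_report.tsv` and
#'   `locus_report_pca.tsv`.
#' @return Invisibly, the [locus_summary()] report.
#' @export
run_locus <- function(vcf, popmap, region, outdir) {
  ds <- read_vcf(vcf, popmap)
  rep <- locus_summary(ds, region)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_locus_tsv(rep, file.path(outdir, "locus_report.tsv"))
  invisible(rep)
}

#' Pipeline: LD decay curves
#'
#' @param vcf,popmap Input paths.
#' @param outdir Output directory for `ld_decay.tsv`.
#' @param max_dist,n_bins See [ld_decay()].
#' @return Invisibly, the decay tibble.
#' @export
run_ld_decay <- function(vcf, popmap, outdir, max_dist = 500000L,
                         n_bins = 50L) {
  ds <- read_vcf(vcf, popmap)
  curve <- ld_decay(ds, max_dist = max_dist, n_bins = n_bins)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(outdir, "ld_decay.tsv"), "w")
  writeLines(paste0("#", paste(names(curve), collapse = "\t")), con)
  write.table(as.data.frame(curve), con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(curve)
}
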