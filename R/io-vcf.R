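#' Read a multi-sample VCF with a population map
#'
#' Parses a VCF 4.2 file (via vcfR) into a [genotype_dataset()]. Diploid GT
#' fields are coded as alt-allele dosage 0/1/2; phased (`|`) and unphased
#' (`/`) separators are treated identically and any GT containing `.`
#' becomes a missing call. Multiallelic records and non-SNP records are
#' dropped with logged counts (attributes `n_multiallelic` and `n_non_snp`).
#' Per-sample FORMAT/DP and site INFO/MQ are kept when present.
#'
#' @param path Path to the VCF file.
#' @param popmap Either a path to a two-column TSV (`sample<TAB>population`,
#'   no header) or a tibble with columns `sample`, `population`. Must cover
#'   every sample in the VCF.
#' @return A [genotype_dataset()].
#' @export
read_vcf <- function(path, popmap) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  if (is.character(popmap)) popmap <- read_popmap(popmap)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1]
  missing_pop <- setdiff(samples, popmap$sample)
  if (length(missing_pop) > 0) {
    abort(paste0("VCF sample(s) absent from popmap: ",
                 paste(missing_pop, collapse = ", ")))
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  non_snp <- !multi & (nchar(fix$REF) != 1 | nchar(fix$ALT) != 1)
  keep <- !multi & !non_snp
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(v, "MQ")))
  gt_chr <- vcfR::extract.gt(v, element = "GT")
  dp <- NULL
  if (any(grepl("DP", v@gt[, "FORMAT"]))) {
    dp <- suppressWarnings(
      t(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)))
    dimnames(dp) <- list(samples, NULL)
  }
  gt_chr <- gsub("|", "/", gt_chr, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow = length(samples), ncol = nrow(fix),
                dimnames = list(samples, NULL))
  dos[t(gt_chr == "0/0")] <- 0L
  dos[t(gt_chr == "0/1" | gt_chr == "1/0")] <- 1L
  dos[t(gt_chr == "1/1")] <- 2L
  bad_site <- !is.na(gt_chr) & is.na(t(dos)) &
    !grepl(".", gt_chr, fixed = TRUE)
  dim(bad_site) <- dim(gt_chr)
  bad <- t(bad_site)
  if (any(bad[, keep])) {
    first <- which(apply(bad, 2, any) & keep)[1]
    abort(paste0("malformed GT in VCF record ", first,
                 " (", fix$CHROM[first], ":", fix$POS[first], ")"))
  }
  variants <- tibble(contig = fix$CHROM[keep],
                     pos = as.integer(fix$POS[keep]),
                     ref = fix$REF[keep], alt = fix$ALT[keep],
                     mq = if (all(is.na(mq))) NA_real_ else mq[keep])
  ds <- genotype_dataset(
    variants, dos[, keep, drop = FALSE], popmap,
    dp = if (is.null(dp)) NULL else dp[, keep, drop = FALSE],
    contig_lengths = vcf_contig_lengths(path))
  attr(ds, "n_multiallelic") <- sum(multi)
  attr(ds, "n_non_snp") <- sum(non_snp)
  ds
}

# contig lengths from ##contig header lines, if declared
vcf_contig_lengths <- function(path) {
  hdr <- readLines(path, n = 500L)
  hdr <- hdr[startsWith(hdr, "##contig")]
  if (length(hdr) == 0) return(NULL)
  ids <- sub(".*ID=([^,>]+).*", "\\1", hdr)
  lens <- suppressWarnings(as.integer(sub(".*length=([0-9]+).*", "\\1", hdr)))
  if (any(is.na(lens))) return(NULL)
  stats::setNames(lens, ids)
}

#' Read a sample-to-population map
#'
#' @param path Two-column TSV `sample<TAB>population`, no header.
#' @return Tibble with `sample`, `population`.
#' @export
read_popmap <- function(path) {
  if (!file.exists(path)) abort(paste0("popmap not found: ", path))
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("sample", "population"),
                   colClasses = "character")
  as_tibble(df)
}

#' Write a genotype dataset as VCF 4.2
#'
#' Emits GT:DP per sample (DP omitted when absent), site INFO/MQ and
#' `##contig` header lines when contig lengths are known. Round-tripping
#' through [read_vcf()] reproduces the genotype matrix exactly.
#'
#' @param x A [genotype_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) {
    abort(paste0("cannot open for writing: ", path))
  }
  on.exit(close(con))
  has_dp <- !is.null(x$dp)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=sweepscan")
  if (!is.null(x$contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(x$contig_lengths),
                          as.integer(x$contig_lengths)))
  }
  hdr <- c(hdr,
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (has_dp) {
    hdr <- c(hdr,
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  }
  samples <- rownames(x$genotypes)
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", samples),
                      collapse = "\t"))
  writeLines(hdr, con)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[x$genotypes + 1L],
                   nrow = nrow(x$genotypes))
  gt_str[is.na(gt_str)] <- "./."
  if (has_dp) {
    dp <- x$dp
    dp_str <- matrix(as.character(dp), nrow = nrow(dp))
    dp_str[is.na(dp_str)] <- "."
    gt_str <- matrix(paste(gt_str, dp_str, sep = ":"), nrow = nrow(gt_str))
  }
  mq <- x$variants$mq
  info <- ifelse(is.na(mq), ".", sprintf("MQ=%g", mq))
  body <- paste(x$variants$contig, x$variants$pos, ".",
                x$variants$ref, x$variants$alt, ".", "PASS", info,
                if (has_dp) "GT:DP" else "GT",
                sep = "\t")
  body <- paste(body, apply(gt_str, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Write a popmap TSV
#' @param popmap Tibble with `sample`, `population`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(popmap, path) {
  write.table(popmap[, c("sample", "population")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write regions as BED (0-based half-open)
#' @param regions Tibble with `contig`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  writeLines(sprintf("%s\t%d\t%d", regions$contig,
                     as.integer(regions$start), as.integer(regions$end)),
             path)
  invisible(path)
}

#' Write the window-scan table as TSV
#'
#' Columns are documented and stable; header lines start with `#` and
#' record the outlier thresholds and parameters when present.
#'
#' @param rows A `sweep_scan` tibble, optionally after [call_outliers()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_tsv <- function(rows, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(paste0("# focal_pop=", attr(rows, "focal_pop")),
            paste0("# other_pop=", attr(rows, "other_pop")))
  if (!is.null(attr(rows, "q"))) {
    meta <- c(meta,
              sprintf("# q=%g zfst_threshold=%.6g zhp_threshold=%.6g",
                      attr(rows, "q"), attr(rows, "zfst_threshold"),
                      attr(rows, "zhp_threshold")))
  }
  writeLines(meta, con)
  writeLines(paste0("#", paste(names(rows), collapse = "\t")), con)
  write.table(as.data.frame(rows), con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a QC report as TSV
#' @param report Tibble from [apply_qc()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(report), collapse = "\t")), con)
  write.table(as.data.frame(report), con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
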