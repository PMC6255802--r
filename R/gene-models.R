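#' Build a gene-model table
#'
#' Gene models are kept as a tibble, one row per gene, with a `cds`
#' list-column of genomic CDS segments (1-based inclusive, in strand-aware
#' translation order) and, when a reference is supplied, the cached coding
#' sequence (5'->3' mRNA orientation). Genes whose total CDS length is not
#' divisible by 3 are flagged non-translatable and effect calls on them are
#' refused.
#'
#' @param gene_id Character vector of gene ids.
#' @param contig Contig per gene.
#' @param strand `"+"` or `"-"` per gene.
#' @param cds List of tibbles with `start`, `end` (1-based inclusive).
#' @param seq Optional character vector of CDS sequences.
#' @return Tibble of class `gene_models` with `gene_id`, `contig`, `start`,
#'   `end` (gene span, 1-based inclusive), `strand`, `cds_len`,
#'   `translatable`, `cds`, `seq`.
#' @export
gene_models <- function(gene_id, contig, strand, cds, seq = NULL) {
  stopifnot(all(strand %in% c("+", "-")))
  cds <- lapply(cds, function(d) {
    d <- as_tibble(d)[, c("start", "end")]
    stopifnot(all(d$end >= d$start))
    d
  })
  cds_len <- vapply(cds, function(d) sum(d$end - d$start + 1L), integer(1))
  out <- tibble(
    gene_id = gene_id, contig = contig,
    start = vapply(cds, function(d) min(d$start), integer(1)),
    end = vapply(cds, function(d) max(d$end), integer(1)),
    strand = strand, cds_len = cds_len,
    translatable = cds_len %% 3L == 0L,
    cds = cds,
    seq = if (is.null(seq)) NA_character_ else seq)
  # translation order: genomic for "+", reverse genomic for "-"
  out$cds <- purrr::pmap(list(out$cds, out$strand), function(d, s) {
    if (s == "+") arrange(d, .data$start) else arrange(d, -.data$start)
  })
  class(out) <- c("gene_models", class(out))
  out
}

#' Attach CDS sequences from a reference FASTA
#'
#' Extracts each gene's coding sequence from the reference (strand
#' corrected, translation order) and caches it in the `seq` column.
#'
#' @param genes A [gene_models()] tibble.
#' @param fasta Path to the reference FASTA, or a named character vector /
#'   `Biostrings::DNAStringSet` of contig sequences.
#' @return `genes` with `seq` filled in.
#' @export
add_cds_sequence <- function(genes, fasta) {
  ref <- load_reference(fasta)
  genes$seq <- vapply(seq_len(nrow(genes)), function(i) {
    ctg <- as.character(ref[[genes$contig[i]]])
    segs <- genes$cds[[i]]
    pieces <- vapply(seq_len(nrow(segs)), function(j) {
      s <- substr(ctg, segs$start[j], segs$end[j])
      if (genes$strand[i] == "-") revcomp(s) else s
    }, character(1))
    paste(pieces, collapse = "")
  }, character(1))
  genes
}

load_reference <- function(fasta) {
  if (inherits(fasta, "DNAStringSet")) return(fasta)
  if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta)) {
    return(Biostrings::readDNAStringSet(fasta))
  }
  Biostrings::DNAStringSet(fasta)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Read gene models from GFF3
#'
#' Expects `gene`, `mRNA` and `CDS` features with `ID`/`Parent` attributes
#' (1-based inclusive, as written by [write_gff3()] and standard annotation
#' pipelines). CDS segments are ordered in strand-aware translation order.
#'
#' @param path Path to a GFF3 file.
#' @param fasta Optional reference FASTA (see [add_cds_sequence()]).
#' @return A [gene_models()] tibble.
#' @export
read_gff3 <- function(path, fasta = NULL) {
  if (!file.exists(path)) abort(paste0("GFF3 not found: ", path))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(gr$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    id = if (is.null(gr$ID)) NA_character_ else as.character(gr$ID),
    parent = vapply(as.list(gr$Parent),
                    function(p) if (length(p)) p[[1]] else NA_character_,
                    character(1)))
  mrna <- df[df$type == "mRNA", ]
  mrna_gene <- stats::setNames(mrna$parent, mrna$id)
  cds <- df[df$type == "CDS", ]
  if (nrow(cds) == 0) abort("GFF3 contains no CDS features")
  parent <- cds$parent
  gene_of <- ifelse(parent %in% names(mrna_gene),
                    mrna_gene[parent], parent)
  ids <- unique(gene_of)
  segs <- lapply(ids, function(g) {
    tibble(start = cds$start[gene_of == g], end = cds$end[gene_of == g])
  })
  strands <- vapply(ids, function(g) cds$strand[gene_of == g][1], "",
                    USE.NAMES = FALSE)
  contigs <- vapply(ids, function(g) cds$contig[gene_of == g][1], "",
                    USE.NAMES = FALSE)
  out <- gene_models(unname(ids), contigs, strands, segs)
  if (!is.null(fasta)) out <- add_cds_sequence(out, fasta)
  out
}

#' Write gene models as GFF3
#'
#' Emits `gene`, `mRNA` and `CDS` features with `ID`/`Parent` attributes,
#' 1-based inclusive coordinates.
#'
#' @param genes A [gene_models()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gid <- g$gene_id
    mid <- paste0(gid, ".t1")
    lines <- c(lines,
      sprintf("%s\tsweepscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$contig, g$start, g$end, g$strand, gid),
      sprintf("%s\tsweepscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$contig, g$start, g$end, g$strand, mid, gid))
    segs <- arrange(g$cds[[1]], .data$start)
    lines <- c(lines,
      sprintf("%s\tsweepscan\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
              g$contig, segs$start, segs$end, g$strand, mid, mid))
  }
  writeLines(lines, path)
  invisible(path)
}
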