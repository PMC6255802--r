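# three-letter amino-acid codes for HGVS p. notation
AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter")

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[[codon]])
}

#' Classify a SNP against a gene model
#'
#' Maps a genomic single-nucleotide substitution onto a gene's coding
#' sequence (strand-aware), mutates the affected codon, translates both
#' alleles with the standard nuclear genetic code and reports the effect
#' with HGVS-style `c.` and `p.` notation (three-letter amino-acid codes,
#' e.g. `p.Asn349Ile`). Variants outside all CDS segments are classified
#' `noncoding` with no protein notation.
#'
#' @param gene One row of a [gene_models()] tibble (with `seq` cached).
#' @param pos Genomic position of the variant (1-based).
#' @param ref,alt Reference and alternate alleles on the forward genomic
#'   strand (single nucleotides).
#' @return One-row tibble: `gene_id`, `contig`, `pos`, `ref`, `alt`,
#'   `cds_pos`, `codon_index`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`,
#'   `category` (one of synonymous, missense, nonsense, stop_loss,
#'   noncoding), `hgvs_c`, `hgvs_p`.
#' @export
#' @examples
#' g <- gene_models("g1", "chr1", "+",
#'                  list(tibble::tibble(start = 1L, end = 9L)),
#'                  seq = "ATGAATTGA")
#' classify_variant(g[1, ], pos = 5L, ref = "A", alt = "T")
classify_variant <- function(gene, pos, ref, alt) {
  gene <- as.list(gene[1, ])
  gene$cds <- gene$cds[[1]]
  if (is.list(gene$seq)) gene$seq <- gene$seq[[1]]
  stopifnot(nchar(ref) == 1, nchar(alt) == 1)
  base <- tibble(gene_id = gene$gene_id, contig = gene$contig,
                 pos = as.integer(pos), ref = ref, alt = alt)
  segs <- gene$cds
  hit <- which(pos >= segs$start & pos <= segs$end)
  if (length(hit) == 0) {
    return(mutate(base, cds_pos = NA_integer_, codon_index = NA_integer_,
                  ref_codon = NA_character_, alt_codon = NA_character_,
                  ref_aa = NA_character_, alt_aa = NA_character_,
                  category = "noncoding", hgvs_c = NA_character_,
                  hgvs_p = NA_character_))
  }
  hit <- hit[1]
  if (!isTRUE(gene$translatable)) {
    abort(paste0("gene ", gene$gene_id,
                 " has CDS length not divisible by 3; effect call refused"))
  }
  if (is.na(gene$seq)) {
    abort(paste0("gene ", gene$gene_id, " has no cached CDS sequence"))
  }
  # offset of preceding segments in translation order
  seg_lens <- segs$end - segs$start + 1L
  before <- if (hit > 1) sum(seg_lens[seq_len(hit - 1)]) else 0L
  if (gene$strand == "+") {
    cds_pos <- before + (pos - segs$start[hit] + 1L)
    ref_c <- ref
    alt_c <- alt
  } else {
    cds_pos <- before + (segs$end[hit] - pos + 1L)
    ref_c <- revcomp(ref)
    alt_c <- revcomp(alt)
  }
  cds_pos <- as.integer(cds_pos)
  have <- toupper(substr(gene$seq, cds_pos, cds_pos))
  if (have != toupper(ref_c)) {
    abort(paste0("REF mismatch for gene ", gene$gene_id, " at genomic pos ",
                 pos, " (CDS pos ", cds_pos, "): CDS has ", have,
                 ", variant REF maps to ", ref_c))
  }
  ci <- as.integer(ceiling(cds_pos / 3))
  off <- cds_pos - 3L * (ci - 1L)
  ref_codon <- toupper(substr(gene$seq, 3 * (ci - 1) + 1, 3 * ci))
  alt_codon <- ref_codon
  substr(alt_codon, off, off) <- toupper(alt_c)
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  category <- if (ref_aa == alt_aa) "synonymous"
    else if (alt_aa == "*") "nonsense"
    else if (ref_aa == "*") "stop_loss"
    else "missense"
  hgvs_p <- if (category == "synonymous") {
    paste0("p.", AA3[[ref_aa]], ci, "=")
  } else {
    paste0("p.", AA3[[ref_aa]], ci, AA3[[alt_aa]])
  }
  mutate(base, cds_pos = cds_pos, codon_index = ci,
         ref_codon = ref_codon, alt_codon = alt_codon,
         ref_aa = ref_aa, alt_aa = alt_aa, category = category,
         hgvs_c = paste0("c.", cds_pos, toupper(ref_c), ">", toupper(alt_c)),
         hgvs_p = hgvs_p)
}

#' Classify all variants of a dataset against gene models
#'
#' Each variant is classified against every gene whose CDS span contains it;
#' variants inside no gene are reported once as `noncoding` with `gene_id`
#' `NA`.
#'
#' @param x A [genotype_dataset()] or a variants tibble with `contig`,
#'   `pos`, `ref`, `alt`.
#' @param genes A [gene_models()] tibble with cached sequences.
#' @return Tibble of coding effects (one row per variant-gene pair).
#' @export
classify_variants <- function(x, genes) {
  variants <- if (inherits(x, "genotype_dataset")) x$variants else as_tibble(x)
  purrr::map_dfr(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    hit <- which(genes$contig == v$contig &
                   v$pos >= genes$start & v$pos <= genes$end)
    if (length(hit) == 0) {
      return(tibble(gene_id = NA_character_, contig = v$contig, pos = v$pos,
                    ref = v$ref, alt = v$alt, cds_pos = NA_integer_,
                    codon_index = NA_integer_, ref_codon = NA_character_,
                    alt_codon = NA_character_, ref_aa = NA_character_,
                    alt_aa = NA_character_, category = "noncoding",
                    hgvs_c = NA_character_, hgvs_p = NA_character_))
    }
    purrr::map_dfr(hit, function(h) {
      classify_variant(genes[h, ], v$pos, v$ref, v$alt)
    })
  })
}

#' Count nonsynonymous variants per gene
#'
#' Tallies effects in the amino-acid-changing categories (missense,
#' nonsense, stop_loss) per gene.
#'
#' @param effects Tibble from [classify_variants()].
#' @param gene_subset Optional character vector restricting the genes
#'   counted (e.g. the PSG candidate list).
#' @return Tibble with `gene_id` and `n_nonsynonymous`; the total over all
#'   rows is in attribute `total`.
#' @export
count_nonsynonymous <- function(effects, gene_subset = NULL) {
  changing <- c("missense", "nonsense", "stop_loss")
  eff <- filter(effects, !is.na(.data$gene_id))
  if (!is.null(gene_subset)) eff <- filter(eff, .data$gene_id %in% gene_subset)
  out <- eff %>%
    group_by(.data$gene_id) %>%
    summarise(n_nonsynonymous = sum(.data$category %in% changing),
              .groups = "drop") %>%
    arrange(.data$gene_id)
  attr(out, "total") <- sum(out$n_nonsynonymous)
  out
}

#' Write coding effects as TSV
#' @param effects Tibble from [classify_variants()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_effects_tsv <- function(effects, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(effects), collapse = "\t")), con)
  write.table(as.data.frame(effects), con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
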