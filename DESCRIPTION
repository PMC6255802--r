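Package: sweepscan
Title: Selective-Sweep Genome Scans from Pooled Heterozygosity and Fst
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate selective sweeps between a highland and a
    lowland population from diploid resequencing genotypes. Implements SNP
    quality control, windowed pooled heterozygosity (Hp), Weir-Cockerham and
    Hudson Fst, nucleotide diversity, Tajima's D, linkage-disequilibrium r2
    decay, Z-transformation with joint top-quantile outlier calling, outlier
    region merging with gene overlap, synonymous/missense variant
    classification with HGVS-style notation, and per-locus diagnostics
    (allele and genotype-class frequencies, locus PCA). A forward-in-time
    two-population Wright-Fisher simulator with bottleneck and hard-sweep
    options generates VCF-ready test data with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    Rcpp,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
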