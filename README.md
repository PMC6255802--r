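# sweepscan

Selective-sweep genome scans for two-population resequencing data.

When a population adapts to a new environment — the motivating case is
insect populations colonizing a high-altitude plateau — beneficial alleles
sweep to fixation and leave local signatures in the genome: elevated
differentiation from the source population, collapsed diversity, skewed
allele-frequency spectra and elevated linkage disequilibrium. `sweepscan`
implements the standard two-statistic scan for such loci and everything
around it:

- **SNP quality control**: per-call depth masking (keep 3 ≤ DP ≤ 50), site
  RMS mapping quality ≥ 20, minor allele frequency ≥ 0.05, missingness
  ≤ 0.1 (all inclusive, applied in that order), with a reconciled removal
  report.
- **Windowed statistics** in 100-kb windows with 50-kb increments
  (0-based half-open): pooled heterozygosity
  *H*<sub>P</sub> = 2Σ*n*<sub>MAJ</sub>Σ*n*<sub>MIN</sub>/(Σ*n*<sub>MAJ</sub>+Σ*n*<sub>MIN</sub>)²,
  Weir–Cockerham (1984) *F*<sub>ST</sub> (ratio of averages; Hudson
  available), nucleotide diversity π, Tajima's *D*, and pairwise *r*²
  from unphased dosages with LD-decay curves.
- **Outlier calling**: genome-wide Z-transformation of *H*<sub>P</sub>
  and *F*<sub>ST</sub>; a window is a candidate sweep iff it is jointly in
  the top 5 % of Z*F*<sub>ST</sub> *and* the bottom 5 % of the focal
  population's Z*H*<sub>P</sub>; flagged windows merge into regions and
  overlap gene models to give the candidate (PSG) list, with
  ΔZ*H*<sub>P</sub> available for per-gene ranking.
- **Coding-effect classification**: strand-aware synonymous / missense /
  nonsense calls with HGVS-style notation (e.g. `c.1046A>T` →
  `p.Asn349Ile`).
- **Locus diagnostics**: per-population allele and genotype-class
  frequencies, region mean *r*², Tajima's *D* and a Patterson-scaled
  locus PCA.
- **A forward Wright–Fisher simulator** (diploid, two populations, founder
  bottleneck, hard sweep with logged establishment conditioning) that
  writes VCF/popmap/GFF3/FASTA/BED ground-truth bundles for benchmarking.

Everything is tibble-first: readers return a `genotype_dataset`, the scan
returns a tibble you can pipe through `dplyr`, results have
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` figures.

## Worked example

Simulate a hard sweep (s = 0.1) private to the highland population on
chr2 at 100 kb, then run the QC → scan → outlier → region → gene pipeline:

```r
library(sweepscan)

cfg <- sim_config(
  n_anc = 200, n_low = 200, n_high = 200,
  bottleneck_frac = 1, t_split = 200, t_total = 1200, mu = 2e-7,
  contig_lengths = setNames(rep(200000L, 10), paste0("chr", 1:10)),
  sweep = list(contig = "chr2", pos = 100000L, s = 0.1,
               t_onset = 0, target_pop = "highland"),
  seed = 13)
sim <- simulate_two_pop(cfg)
sim$truth
#> # A tibble: 1 × 5
#>   sweep_contig sweep_pos fixed_in_target  seed n_segregating
#>   <chr>            <int> <lgl>           <int>         <int>
#> 1 chr2            100000 TRUE               13          1714

qc <- apply_qc(sim$dataset)
qc$report
#> # A tibble: 1 × 6
#>   sites_in masked_calls_dp removed_mq removed_missing removed_maf sites_out
#>      <int>           <int>      <int>           <int>       <int>     <int>
#> 1     1714               3          0               0         833       881

scan <- qc$dataset |>
  scan_windows(focal_pop = "highland") |>
  call_outliers(q = 0.05)
dplyr::filter(scan, outlier) |>
  dplyr::select(contig, start, end, n_snps, fst, zfst, zhp_focal)
#> # A tibble: 1 × 7
#>   contig start    end n_snps   fst  zfst zhp_focal
#>   <chr>  <int>  <int>  <int> <dbl> <dbl>     <dbl>
#> 1 chr2   50000 150000     26 0.651  2.19     -2.21

regions <- merge_regions(scan)
genes <- place_genes(cfg, sim$reference)
psg_genes(genes_in_regions(regions, genes))
#> [1] "chr2_g003" "chr2_g004" "chr2_g005" "chr2_g006"
attr(genes, "truth_gene")
#> [1] "chr2_g005"
```

The single flagged window (high Z*F*<sub>ST</sub> = 2.19, low highland
Z*H*<sub>P</sub> = −2.21) spans the true sweep position, and the candidate
gene list recovers the gene placed over it. `plot_scan(scan)` draws the
Z*F*<sub>ST</sub>-vs-Z*H*<sub>P</sub> scatter with the quantile
thresholds; `autoplot(locus_pca(...))` plots the locus PCA.

Classifying a coding variant:

```r
gene <- gene_models("locus", "chr1", "+",
                    list(tibble::tibble(start = 1L, end = 1047L)),
                    seq = strrep("AAT", 349))
classify_variant(gene[1, ], pos = 1046L, ref = "A", alt = "T")[
  , c("category", "codon_index", "hgvs_c", "hgvs_p")]
#> # A tibble: 1 × 4
#>   category codon_index hgvs_c    hgvs_p
#>   <chr>          <int> <chr>     <chr>
#> 1 missense         349 c.1046A>T p.Asn349Ile
```

A thin command-line wrapper over the same pipeline functions lives at
`inst/cli/sweepscan.R`
(`Rscript sweepscan.R {simulate|filter|scan|annotate|locus|ld-decay} ...`).

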