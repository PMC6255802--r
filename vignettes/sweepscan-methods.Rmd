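---
title: "Detecting selective sweeps with sweepscan: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps with sweepscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

## The problem

When a population colonizes a new environment — say, a high-altitude
plateau — beneficial alleles can rise rapidly to fixation, dragging linked
variation with them. Such hard selective sweeps leave a characteristic
local signature: allele-frequency differentiation from the source
population (high Fst), depleted within-population diversity (low pooled
heterozygosity Hp and nucleotide diversity π), an excess of rare variants
(negative Tajima's D) and elevated linkage disequilibrium (r²).

`sweepscan` implements the full desk workflow for finding and
characterizing such loci from diploid resequencing genotypes of a
*highland* (focal, putatively selected) and a *lowland* (reference)
population: SNP quality control, windowed statistics, genome-wide
Z-transformation with joint-quantile outlier calling, merging of outlier
windows into candidate regions, gene overlap, protein-level classification
of candidate variants, and per-locus diagnostics. A forward Wright–Fisher
simulator generates ground-truthed synthetic data so every step can be
benchmarked.

## Statistics

**Pooled heterozygosity.** For each window, per-site major and minor
allele counts (nMAJ, nMIN — derived from genotype allele copies) are
summed into \(A = \sum \mathrm{nMAJ}\) and \(B = \sum \mathrm{nMIN}\), and

\[ H_P = \frac{2AB}{(A+B)^2} . \]

This normalization is bounded on \([0, 0.5]\), maximal when the summed
minor fraction is one half, and decreases monotonically as windows
approach fixation. An alternative normalization, \(AB/(A+B)\), is
available via `pooled_heterozygosity(..., normalization = "printed")`; it
is count-scale and unbounded, which makes it unsuitable for
Z-transformation across windows of unequal SNP content, so the bounded
form is the default.

**Fst.** The default estimator is Weir & Cockerham's (1984)
variance-components \(\hat\theta\) with two populations and allele copies
as sampling units, accumulated over windows as a ratio of summed
numerators to summed denominators ("ratio of averages"). Negative window
values are reported as computed. Hudson's (1992) estimator is available
with `estimator = "hudson"`. Sites lacking a non-missing allele copy in
either population are skipped.

**π and Tajima's D.** Nucleotide diversity uses the unbiased per-site
pairwise estimator \(2 n_{\mathrm{ref}} n_{\mathrm{alt}} / (n(n-1))\)
summed over SNPs and divided by window length, with the monomorphic
remainder assumed invariant. Tajima's D uses the standard constants
\(a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2\); under missingness the sample
size entering the constants is the minimum per-site allele-copy count in
the window — a conservative simplification that avoids per-site
renormalization of the variance term.

**Linkage disequilibrium.** r² is the squared Pearson correlation of
unphased genotype dosages over samples non-missing at both sites
(Rogers–Huff style). No EM phasing is attempted; for the comparisons the
package makes (between populations, between regions) the dosage-based
estimator preserves ordering while avoiding phase inference. LD decay
curves average r² in physical-distance bins up to 500 kb by default.

**Z-transformation and outlier calling.** Each windowed statistic is
standardized to mean 0, sd 1 (sample sd, NA windows excluded). A window
is an outlier iff its ZFst is at or above the empirical \(1-q\) quantile
*and* the focal population's ZHp is at or below the empirical \(q\)
quantile (default \(q = 0.05\); type-7 quantiles). The focal population's
ZHp is used because the selected population is where diversity collapses;
`hp_condition` can switch this to the reference population or the minimum
of both. ΔZHp is defined as `zhp_other - zhp_focal`, large when
highland diversity is depleted relative to lowland.

## Quality control

Thresholds default to per-call depth in \([3, 50]\), site RMS mapping
quality ≥ 20, minor allele frequency ≥ 0.05 and missingness ≤ 0.1, all
bounds inclusive. The order is fixed and deliberate: (1) depth-mask
genotype calls, (2) drop low-MQ sites, (3) drop high-missingness sites,
(4) drop low-MAF sites. Depth masking runs first so that unreliable calls
propagate into the missingness and MAF computations, as they would in a
variant-calling pipeline; MAF is always computed on the post-mask
non-missing calls. The QC report satisfies the identity
`sites_in = sites_out + removed_mq + removed_missing + removed_maf`, and
QC is idempotent. Whether "coverage depth" in such pipelines is per-sample
or per-site total is often ambiguous; per-sample FORMAT/DP masking is
used here because the samples are individually sequenced.

## Windowing conventions

Windows are 100 kb with 50-kb increments by default, 0-based half-open.
Terminal partial windows are emitted iff their length is at least half
the window size — dropping them loses genome tails, while emitting tiny
slivers produces noisy statistics. A SNP at position \(p\) (0-based)
belongs to every window with \(start \le p < end\). Windows with fewer
than `min_snps` (default 10) SNPs receive NA statistics and are excluded
from the Z-transformation; a scan with fewer than 10 usable windows is
refused because empirical tail quantiles are meaningless there.
Overlapping or book-ended flagged windows merge into regions; a gene is
assigned to a region if their intervals intersect by at least 1 bp.

## Variant effects

Coding effects are classified per SNV against single- or multi-exon gene
models: the genomic position is mapped strand-aware to a CDS coordinate,
the affected codon is mutated and both alleles translated with the
standard nuclear code. Categories are synonymous, missense, nonsense,
stop_loss and noncoding, with HGVS-style `c.` and `p.` notation
(three-letter amino-acid codes). Start-codon positions are classified
like any other codon, and multi-nucleotide substitutions are rejected —
the pipeline is SNP-only. Genes whose CDS length is not divisible by 3
are flagged non-translatable and effect calls on them are refused rather
than silently frame-shifted.

## Locus diagnostics

`locus_summary()` reproduces the standard candidate-locus workup:
per-population allele frequency and genotype-class fractions at a focal
variant, region mean r², per-population Tajima's D, and a
region-restricted PCA. The PCA mean-imputes missing dosages per SNP,
centers by twice the allele frequency and scales by
\(\sqrt{2p(1-p)}\) (Patterson scaling), drops monomorphic SNPs, and
canonicalizes component signs so the largest-magnitude SNP loading is
positive — making coordinates reproducible across linear-algebra
backends. Genotype classes are reported by dosage (hom-ref / het /
hom-alt); biological labels such as "wild type" are left to the user
because which allele is ancestral is not decidable from the genotype
matrix alone.

## The synthetic-data generator

`simulate_two_pop()` runs a discrete-generation diploid Wright–Fisher
model (implemented in C++, driven by R's RNG so a seed fully determines
the output): an ancestral population evolves to mutation–drift
equilibrium, splits into a lowland and a highland population, and the
highland population optionally passes through a founder bottleneck and/or
carries a hard sweep private to it. Mutation is infinite-sites on a
finite grid (at most one mutation is ever retained per site; collisions
are dropped and counted). Recombination draws a Poisson(\(\rho L\))
crossover count per meiosis with uniform breakpoints — no interference,
no gene conversion. A configured beneficial allele starts as a single
copy and is re-seeded on loss (up to `max_reseed` times); this standard
conditioning on establishment is logged, never hidden.

Parameters are rescaled to desk size: small \(N\), inflated per-site
mutation rate. The defaults define the package's reference scenario:

| parameter | default | rationale |
|---|---|---|
| `n_anc`, `n_low`, `n_high` | 100 diploids | smallest size at which drift, sweeps and sampling behave regularly |
| `t_split` | 50 generations (0.25 × 2N) | recent split: strong but incomplete differentiation, window Fst ≈ 0.15–0.3 |
| `t_total` | 1050 generations | ≥ 10N burn-in reaches mutation–drift equilibrium (validated against Watterson's E[S] in the tests) |
| `mu` | 3 × 10⁻⁷ /site/gen | ≈ 50–90 sample SNPs per 100-kb window after QC, a realistic scan density |
| `rho` | 1 × 10⁻⁷ /bp/gen | LD decay scale 1/(4Nρ) ≈ 25 kb, so 500-kb LD windows and 10–20-kb bins are informative |
| `bottleneck_frac`, `bottleneck_gens` | 0.1 × for 20 generations | founder effect at colonization: ≈ 50 % π reduction and clearly elevated LD in the highland sample at sampling time |
| `sample_low`, `sample_high` | 10, 12 diploids | mirrors a typical two-population resequencing design |

The generator emulates the *contrasts* real highland/lowland data show —
reduced highland π, elevated highland LD and homozygosity, sweep troughs
in Hp with locally elevated Fst — not the absolute scales of a real
genome (Gbp lengths, per-bp mutation rates, deep time). Tests passing on
these simulations therefore validate the statistical machinery and the
qualitative behaviour of the scan, not genome-scale power for any
particular species.

The sweep-recovery benchmark in the test suite uses a deliberately harder
scenario chosen to keep selection and drift distinguishable at desk
scale: a 200-kb sweep contig (s = 0.1, h = 0.5, sweep starting at the
split) embedded among 20 neutral 200-kb contigs, N = 200 in all
populations, split 200 generations (0.5 × 2N) before sampling so that the
beneficial allele has time to fix. Recovery is assessed only among
replicates where the allele actually fixed. At this scale the swept
window's Fst competes with the upper tail of pure drift: 4Ns = 80 here,
orders of magnitude below a real sweep, so the joint top-5 % rule
recovers the swept region in only roughly half of the fixed replicates
(the acceptance test reports the exact rate). This is an intrinsic
property of the rescaled regime, not of the scan: the same machinery
flags essentially no windows (fraction ≤ q) under the matched neutral
null, which is the calibration that matters for false positives.

`place_genes()` adds non-overlapping single-exon genes (CDS length
divisible by 3) deterministically under the seed, guaranteeing one gene
spans a configured sweep so that gene-recovery benchmarks have ground
truth. `export_simulation()` writes the analysis-ready bundle (VCF 4.2
with GT:DP and INFO/MQ, popmap TSV, GFF3, reference FASTA, truth BED,
YAML config echo); simulated depths are Poisson(mean 15, floored at 1)
and MQ is fixed at 60 so the default QC passes unless failures are
injected on purpose (`missing_rate`, custom `dp_mean`/`mq`).

## Numerical and degenerate-input choices

- `zscore()` refuses zero-spread input instead of emitting infinities;
  NA passes through and is excluded from the mean and sd (ddof = 1).
- Window Fst is NA when the summed denominator is zero; negative values
  are not clipped.
- Hp is NA when a window has no allele copies; major-allele ties at
  frequency 0.5 break REF-first for determinism.
- Tajima's D is NA for fewer than 3 allele copies or zero segregating
  sites.
- r² pairs with a zero-variance column or fewer than two complete
  observations are skipped and counted, never propagated as NA poison.
- QC returning an empty dataset is a warning, not an error, so pipelines
  can report it.
- All internal window/region arithmetic is 0-based half-open; VCF and
  GFF3 coordinates (1-based) are converted exactly once at the I/O
  boundary, and CLI region strings are 1-based inclusive.

## Known limitations

- r² is genotype-based; haplotype-phase r² would differ in absolute
  value (not in the orderings the package compares).
- The per-window Tajima's D sample size under missingness is the window
  minimum, slightly conservative when missingness is very uneven.
- The simulator has no migration, growth curves, soft sweeps or
  background selection; those are out of scope by design.
- The scan's power at desk scale is limited by drift (see the
  sweep-recovery discussion above); on real data with large \(N_e\) the
  drift tail is far tighter relative to a sweep.
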