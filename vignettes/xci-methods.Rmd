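---
title: "Methods: sex-specificity scanning and allele-specific XCI analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-specificity scanning and allele-specific XCI analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xcitools)
```

# Scope

`xcitools` packages the computational building blocks of an allele-specific
study of X chromosome inactivation (XCI) in F1 hybrid mice: a genome-wide
scanner for sex-specific chromatin accessibility, an allelic-ratio engine
for maternal/paternal read counts, a single-cell active-X (Xa) classifier
with pseudobulk escape-gene detection, downstream arithmetic for
differential-expression (DE) overlaps and phenotype tallies, and a
synthetic-data module that generates every input with ground-truth labels.
Read alignment, allele splitting of BAM files, peak calling, DE model
fitting and gene-set enrichment are deliberately out of scope: the package
consumes their outputs (BED peaks, count tables, DE tables) in plain-text
formats.

# The sliding-window sex-specificity score

Peak calls from several organs, both sexes, and replicated samples are
compared on a sliding-window lattice: windows of width $W$ (default
100 kb) every $s$ bp (default 50 kb), clipped at chromosome ends so every
base is covered. Replicate peak sets of an organ-sex group are first
reduced to their *consensus*: the genomic intersection of the replicate
peak sets, i.e. only accessibility supported by every replicate survives
(a union mode is available because "intersecting" replicate peak calls is
an ambiguous operation; intersection is the default because it is the
conservative reading).

Each consensus peak is assigned to every window containing its midpoint
$\lfloor (\mathrm{start}+\mathrm{end})/2 \rfloor$. Midpoint containment
gives each peak a well-defined multiplicity (exactly two windows under
50% overlap, except at chromosome starts); assigning by any-overlap would
make multiplicity depend on peak width.

Per window, let $f$ and $m$ be the medians of the female and male
organ-level counts, rounded to integers (half-up by default; medians over
an even number of organs can be half-integers, and the binomial test needs
integers — floor/ceiling modes are available). With $k=\max(f,m)$ and
$n=f+m$, the one-sided binomial p-value is

$$p = P\!\left(X \ge k \mid X \sim \mathrm{Bin}(n, 1/2)\right),$$

and the score is $-\log_{10} p$, signed positive when females have more
peaks and negative when males do. Windows with $f=m$ score 0 and windows
with $f=m=0$ are flagged uninformative. The score is a ranking statistic,
not a calibrated test: raw p-values are used without multiple-testing
correction, and ties are broken by genomic position. As a worked anchor,
counts of 21 female versus 9 male peaks give
$p=\sum_{k=21}^{30}\binom{30}{k}2^{-30} \approx 0.021$, score $+1.67$.

# The allelic-ratio engine

Biallelic counts arrive as strain-labelled columns
(`strain1_count`/`strain2_count`). A cross design (e.g. BL6×CAST, mother
first) maps them to maternal/paternal columns; all downstream logic is
orientation-agnostic, so single-cell analyses can keep a strain1
orientation instead (the CAST-Xa convention).

SNP-level counts are aggregated to features (genes, or 50 kb windows for
ATAC data): a SNP contributes iff its total count is at least 1 read and
its position falls inside the feature's half-open interval. Feature
ratios are always ratios of summed counts,
$r=\sum \mathrm{mat}/(\sum \mathrm{mat}+\sum \mathrm{pat})$ — never means
of per-SNP ratios, which weight shallow SNPs incorrectly. SNPs under
overlapping features contribute to each and mark those features
ambiguous; this mirrors the known artifact that an unstranded analysis
assigns *Xist* reads to the overlapping *Tsix* as well. A strand-aware
mode restricts SNPs to same-strand features when strand is available.

Ratios are reported only for features passing a total-read filter: 30
reads for gene-level RNA data, 50 for ATAC windows. Status calls use the
0.7/0.3 thresholds (boundary inclusive): `maternal` at $r \ge 0.7$,
`paternal` at $r \le 0.3$, `biallelic` between. The same cut-offs are
reused at gene level for escape classification; no separate gene-level
threshold is introduced, keeping one convention throughout (exposed as
parameters everywhere). Filtered features are emitted with status
`filtered` rather than dropped, so the "informative in every group" set
logic of `median_ratios(strict = TRUE)` is exactly reproducible.

# Single-cell Xa classification

Quality control mirrors standard droplet scRNA-seq practice with strict
inequalities: cells kept with detected features in (500, 5000), total
counts in (2000, 20000) and mitochondrial percentage < 10; genes kept if
expressed in > 10 remaining cells. A cell with exactly 5,000 features is
removed.

Each cell's chromosome-wide X allelic ratio is the strain-1 share of all
allelic reads over X-linked genes. Cells with fewer than 10 X reads are
`LOW_COVERAGE` and excluded downstream. Otherwise the cell is
`STRAIN1_Xa` at ratio $\ge 0.7$, `STRAIN2_Xa` at $\le 0.3$ (the only
self-consistent reading of the paired thresholds, boundaries inclusive),
and `BIALLELIC_EXCLUDED` in between. Two apparent active X's is the
doublet signature; such cells are retained in the output table — so the
excluded-cell accounting is reproducible — but never enter pseudobulk.

Cells with a definite state are summed per genotype × Xa-state group
(four groups in a WT / heterozygous-knockout design). Group-level gene
ratios come from the same allelic-ratio engine at a 30-read filter. An
X-linked gene is called *escaping* in a group when it passes the filter
with a ratio strictly between the thresholds, and *Xi-exclusive* (the
Xist signature) when its ratio lies beyond the threshold opposite to the
group's Xa strain.

# DE overlap arithmetic, TPM and phenotype tallies

DE tables are thresholded inclusively at FDR $\le$ 0.01 and
$|\log_2 \mathrm{FC}| \ge 1$; the test itself is an upstream input. For
set comparisons, the shared count is the gene-id intersection, concordant
genes additionally match direction, and the concordance percentage is
taken against the smaller set by default (73 concordant genes against a
smaller set of 103 give 70.87%); the denominator is configurable because
the convention is not universal. Fold ratios between set totals are
reported to one decimal (1190/104 → 11.4), percentages to two decimals.
TPM follows the standard closed form
$\mathrm{TPM}_g = 10^6 (c_g/L_g)/\sum_j (c_j/L_j)$ and display values are
$\log_{10}(\overline{\mathrm{TPM}}+1)$ per tissue. Phenotyping-screen
parameters are significant at uncorrected $p < 0.05$ (strict), tallied by
group and assay category.

# The synthetic-data generators

The generators produce data with the statistical structure the pipeline
assumes, plus complete truth labels, so every stage is testable without
any external download. They emulate distributions and label structure —
not read-level artifacts: no mapping bias, no ambient RNA, no batch
effects, no cell-type structure. Passing tests therefore demonstrate
correctness of the *procedures* under the stated models, not performance
on real sequencing data.

**Peak sets.** Latent peak loci per organ-sex follow a Poisson process at
`baseline_rate` (default 5 peaks/100 kb, a typical broad-peak density);
inside configured enriched windows the female rate is multiplied by
`fold`. Replicates re-emit the *shared* latent loci with Gaussian
positional jitter (25 bp): replicate peak calls of one condition are
reproducible observations of the same loci, and fully independent
replicates would leave the intersection consensus nearly empty. At the
default `rep_reproducibility = 1` the per-replicate marginal count is
exactly Poisson. The default experiment (six organs, two replicates per
sex) matches the multi-organ survey design the scanner targets.

**Bulk allele counts.** Features take one of five classes — biallelic
(maternal fraction 0.5), X-silenced (1, the maternal-Xa convention of
imprinted XCI in placenta), escaper (uniform in (0.35, 0.65), safely
inside the open (0.3, 0.7) biallelic band), imprinted-maternal (1), and
Xist-like (0). X-only classes are drawn only for X-linked features and
imprinting only for autosomal ones, renormalising the configured class
fractions within each chromosome type. Totals are negative-binomial
(mean 60, size 2 — overdispersed counts with most informative features in
the tens-to-hundreds of reads), and observed fractions are attenuated by
symmetric per-read misassignment noise,
$p_{\mathrm{obs}} = p(1-\varepsilon) + (1-p)\varepsilon$. The default
$\varepsilon = 0.02$ is a free choice: the off-allele noise level of real
data is not characterised, and 2% reproduces the faint off-allele signal
visible in monoallelic genes.

**Single-cell allele counts.** Each cell draws its Xa strain with the
genotype's skew probability, a depth from a negative-binomial model
(mean 8,000, size 4), and distributes reads over a fixed gene universe
(default 2,000 autosomal + 200 X genes plus 13 mitochondrial genes at a
4% read share) by fixed expression weights. X-gene reads follow the Xa
strain up to noise; escape genes split 50/50; the Xist-like gene is
expressed from the Xi strain only, at six times the median gene's weight
— prominent, while keeping skewed singlets confidently monoallelic
chromosome-wide. Doublets are additive mixtures of two independent cells
of the same genotype (the interpretation of biallelic-X barcodes as
duplicates), which means unbalanced-depth doublets can evade the
biallelic window, exactly as in real data. Default skews are the
definite-call Xa fractions reported for F1 BL6×CAST spleen: 0.677 for
wild type and 0.848 for the heterozygous triple knockout. QC-outlier
barcodes (2%) are drawn too shallow, too deep, or with ~20%
mitochondrial load.

**DE tables.** Two tables with configured significant-set sizes, shared
fraction and direction concordance; true genes get FDR < 0.01 and
$|\log_2\mathrm{FC}| \in [1, 3]$, null genes FDR > 0.01, so the
threshold rule recovers the truth exactly. Defaults mirror the
417/103-with-73-shared-concordant configuration the overlap arithmetic is
anchored on.

All generators are deterministic given their config seed (the RNG state
is saved and restored, so they never disturb the caller's stream).

# Numerical choices and degenerate inputs

* Half-integer medians are rounded half-up by default (documented,
  configurable); the choice only matters for even numbers of organs.
* A zero total never divides: the ratio is `NA` with status `filtered`,
  even when the coverage filter is disabled.
* Windows are clipped at chromosome ends, not dropped, so terminal loci
  remain scoreable; a chromosome shorter than one window still gets
  windows.
* Empty pseudobulk groups are emitted with zero counts and a warning
  rather than omitted, keeping the four-group layout stable.
* Ties in window ranking are broken by (chrom, start) so output order is
  deterministic.

# Problem sizes used in the test suite

The packaged tests run on deliberately small instances chosen to keep the
full suite in a few minutes on a single core while leaving the
statistical contracts sharp: a 12–40 Mb toy genome (hundreds of windows),
Monte-Carlo loops of 100–1,000 seeds for Poisson/recovery checks, 2,000
cells for skew recovery (3-standard-error bands), and 10,000+ features
for marginal calibration. These sizes are the package's own choices; all
scale linearly if enlarged.

# Known limitations

* The scanner scores windows independently; no spatial smoothing or
  neighbour correction is attempted, matching the ranking-statistic use.
* The biallelic-X doublet heuristic cannot see same-Xa doublets, and
  unbalanced mixed doublets may evade it; it is an exclusion filter, not
  a doublet detector.
* Escape calls are threshold-based; no significance test of allelic
  imbalance is performed, because the source procedures report ratios,
  not imbalance p-values.
* The generators do not simulate reads, alignments, mapping bias or
  chromatin 3-D structure, and phenotype tables are consumed as given —
  assay statistics are out of scope beyond the significance tally.
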