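---
title: "Methods: integrative CNV / methylation / expression candidate screening"
author: "tsoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative CNV / methylation / expression candidate screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsoscan)
```

## The model

Cancer genomes accumulate copy-number aberrations and promoter-methylation
changes, and both can drive expression. tsoscan formalizes the classical
quadrant picture of how these modalities combine per gene:

* an **oncogene-like** gene is *amplified*, *hypomethylated* and
  *overexpressed* relative to normal tissue;
* a **tumor-suppressor-like** gene is *deleted*, *hypermethylated* and
  *underexpressed*;
* the two **cross classes** — amplified-but-suppressed (epigenetic
  silencing despite copy gain) and deleted-but-expressed (hypomethylation
  compensating copy loss) — capture genes whose epigenetic state overrides
  their dosage.

Copy number is the base feature. Genes are first assigned a per-sample
seg.mean from CBS segment tables, then screened and classified using
expression ratios against normal tissue and promoter methylation, with all
multiple testing controlled by Benjamini–Hochberg FDR.

## Segment-to-gene assignment

A gene/sample cell receives the seg.mean of the **unique segment fully
containing the gene locus**. Cells are missing — never zero-filled — when
the gene is split across two or more segments, partially covered,
uncovered, or supported by a segment with fewer than 4 informative markers
(`min_num_info`). Missingness is the honest state for these cells: a
split gene is not a neutral gene.

After assignment, 5% of strictly positive cells nearest a seg.mean of 0
and 5% of negative cells nearest 0 are masked (`trim_near_zero`),
retaining the 90% of the data carrying usable copy-number signal. The
trim pools cells across the whole matrix (not per gene or per sample):
the noise floor around diploid is a property of the platform, not of a
gene. Ambiguity between global and per-sample trimming was resolved in
favor of the global reading.

CNV states use two thresholds: amplified at seg.mean ≥ 0.50 and deleted
at seg.mean < 0.00 (frequency tables), with neutral in between; a
seg.mean of exactly 0 is neutral because the deleted rule is strict. The
rank-sum screen instead uses *extreme* cutoffs — high ≥ 1.25 and
low < −0.50, the deletion bound capturing at minimum a loss of
heterozygosity. All four are fields of `threshold_config()` because the
gene counts any screen reports are threshold-sensitive; `threshold_sweep()`
makes that dependence explicit.

### Cross-platform calibration

Platforms compress seg.mean differently. `calibrate_platform_threshold()`
transfers a deletion threshold from a reference platform to a target
platform over shared samples by maximizing *sensitivity − false-positive
rate* on the reference deleted calls over a user grid, ties resolved
toward zero. The verbal criterion ("maximum captured deletions at minimum
false positives") admits many scalarizations; the Youden-style difference
was chosen because it is symmetric, bounded and has no tuning constant.

## Methylation assignment

Two dialects are supported, both on a "higher = more methylated" scale:

* **moma_ratio** (McrBc-vs-mock GeoMeanRatio tiling arrays, centered at
  1.0): per restriction fragment the maximum probe score per sample, each
  fragment attributed to the gene whose TSS-proximal end is nearest the
  fragment midpoint, per gene the maximum over its fragments. The
  "closest gene" rule is TSS distance with ties broken by gene-body
  distance then lexicographic id — promoter methylation is the signal of
  interest, so TSS proximity is the appropriate notion of "closest"; the
  alternative (any-overlap priority) is not used.
* **beta** (Infinium-style, values in [0, 1], centered at 0.5): per-gene
  mean beta, reported only when 2 or more probes support the gene.

Sample-level methylation matrices are quantile-normalized before
analysis. `quantile_normalize()` maps every column onto the row-wise mean
of the sorted columns; tied values receive the mean of the reference
values at their tied ranks (deterministic, order-independent), and
columns with missing cells are mapped through quantile interpolation of
the reference. This exact tie rule is why the function is implemented in
the package rather than delegated to an array-normalization library whose
tie handling differs at multiplicity ≥ 3.

## Association screens

`wilcoxon_cnv_screen()` contrasts expression between the low-CNV and
high-CNV sample groups of each gene. Although historically described as a
signed-rank procedure in this context, the comparison is between two
*independent* sample groups — there is no pairing — so the two-sample
Mann–Whitney rank-sum test is the correct form and is what the package
computes. The p-value is exact when both groups have at most 8 samples
and the pooled values are tie-free; otherwise the tie-corrected normal
approximation with continuity correction is used. A gene is tested only
when each group covers at least `min_sample_fraction` (default 20%) of
the tumor samples; the gate is applied per group, which is the stricter
reading of "a minimum 20% of the tumor samples". Skipped genes carry
their reason. BH q-values are computed within each screen invocation —
one test family per analysis.

`per_gene_correlation()` screens CNV–expression and
methylation–expression with product-moment correlations and t-transform
p-values; the methylation screen reports the correlation of
(−methylation, expression) so that repressively methylated genes score
positive, flagged in the output. `cnv_expression_cdf_gap()` summarizes
the separation of deleted-pair and amplified-pair expression as the
two-sample Kolmogorov–Smirnov statistic. `normal_deviation_filter()`
retains genes whose gated-tumor mean expression deviates from the normal
mean by more than one tumor standard deviation; the garbled original
phrasing ("not within the standard deviation") is implemented as
retain-if-deviant, consistent with the screen's purpose of finding
differentially expressed CNV-altered genes.

## Feature classification

Genes enter the amplified class when ≥ 20% of tumors are amplified
(seg.mean ≥ 0.50) and the deleted class when ≥ 20% fall below the
extreme-deletion cutoff (−0.50 by default). The deleted gate deliberately
uses the extreme cutoff rather than the `< 0.00` frequency threshold:
around half of all neutral noise sits below zero, and a gate there would
flood the deleted class with every gene in the cohort. A gene may enter
both classes through different sample subsets.

Expression is summarized as the tumor:normal ratio of **linear-scale**
means (log2 input is unlogged first — a ratio of signals, not a
difference of logs). When native normal expression is missing for a gene,
the normal mean is estimated by a 50× bootstrap over a donor normal
matrix (resample size equal to the donor count, mean of resample means),
deterministic given its seed. Classification cutpoints are the 25% and
75% empirical quantiles (linear interpolation) of the *entire* ratio
distribution and of the entire per-gene tumor methylation distribution —
global, not per CNV class, following the "entire ratio distribution"
reading. The methylation value a gene is judged on is its tumor mean over
the class-defining samples (the amplified samples for the amplified
class), which is where the epigenetic state matters.

Significance against normals is computed per gene from the joint
(methylation, expression) per-sample observations: Euclidean distances
between the tumor-mean and normal-mean points are reported as effect
sizes; two-sided Welch t-tests per modality and a two-sample Hotelling
T² test jointly give the p-values, with BH over genes on the
multivariate p. The T² is the **unequal-covariance (Behrens–Fisher) form**
`d' (S1/n1 + S2/n2)^{-1} d` with Nel–van der Merwe degrees of freedom
rather than the pooled-covariance classic: tumor and normal groups here
are grossly heteroscedastic (tumors carry the alteration mixture; normals
do not) and unbalanced, conditions under which the pooled form both
miscalibrates and loses most of its power — and it is the multivariate
analog of the Welch t-tests used univariately. Under a singular
covariance (e.g. perfectly correlated modalities) the statistic is
computed through the Moore–Penrose pseudoinverse — collapsing, as it
should, to the squared Welch t of the shared coordinate — and the p-value
is reported missing. Genes passing FDR 0.05 are percentile-ranked by
q-value: `100·(1 − (rank−1)/(n−1))`, a single passing gene scoring 100.

`hypergeometric_enrichment()` tests each feature class for
over-representation in user-supplied gene sets with the exact upper tail
of the hypergeometric distribution (one-sided; over-representation only)
and BH across sets. The universe is the set of genes observed in all
three modalities in the run — enrichment against untestable genes would
be inflated. No pathway collection is bundled; gene sets arrive as GMT.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, with planted ground truth for recovery testing. Defaults mirror
a serous ovarian cohort: 42 tumors, 7 tissue normals, genes tiled over 22
chromosomes. Genes are 10 kb tiles separated by 10 kb gaps; per tumor
sample, each altered gene receives its own CBS segment and consecutive
unaltered genes merge into one neutral segment, so segments partition
every chromosome and every gene is fully contained in exactly one
segment — the clean baseline on which `inject_edge_cases()` plants
split-gene and low-marker exclusions as positive controls.

Planted classes are drawn per gene as round-half-up(fraction × n_genes);
remainder genes are null (round-half-up makes the counts deterministic
and testable). A planted gene's realized seg.mean effect is
`sign · cnv_effect · U(0.6, 1.4)` — a continuum of aberration magnitudes,
as real cohorts show, which also gives the calibration operation a
populated decision boundary — carried by a random
`altered_sample_fraction` of tumors. `cnv_flip_prob` (default 0) lets
individual carriers flip alteration sign, reproducing genes amplified in
some tumors and deleted in others; with the expression slope set to zero
this is the package's association-null construction for FDR validation:
the screen then has populated low and high groups but nothing to detect.

Expression follows the additive mechanism

```
log2 expr = baseline + expr_dosage_slope · seg.mean
            − meth_coupling · (methylation − platform center) + N(0, sd)
```

so dosage and methylation effects on expression arise mechanistically.
Two consequences worth knowing:

* the **cross quadrants are parameter-dependent**: an
  amplified-suppressed gene needs `meth_coupling · meth_effect >
  expr_dosage_slope · cnv_effect`, otherwise dosage wins and the gene
  presents as oncogene-like. The defaults favor the main quadrants;
  cohorts meant to exercise the cross classes should raise
  `meth_coupling` or `meth_effect` (the package's tests do exactly that).
* normals sit at seg.mean ≈ 0 (sd 0.02), platform-center methylation and
  baseline expression — the reference state.

Default noise levels (`cnv` 0.1 seg.mean units, `meth` 0.05 platform
units, `expr` 0.3 log2 units) were chosen once as plausible array-scale
noise: seg.mean noise well below the 0.5 amplification threshold,
methylation noise matching the ~0.9–1.25 spread of ratio-scale platform
summaries, expression noise a fraction of a typical 1-unit log2 effect.
No effect-size distributions for real aberrations are available to copy,
so these are testability choices, documented rather than tuned.

All randomness flows from the single integer `seed`; identical
configurations reproduce byte-identical on-disk artifacts, which the
pipeline's manifest (per-stage seed, config hash, row counts, md5s,
filter counts in/out) makes checkable.

## What the tests do and do not show

The validation suite recovers planted truth at desk scale: on a
1000-gene, 60-tumor/7-normal cohort with unit dosage slope and a 0.3
methylation shift, ≥ 90% of planted oncogene-like/TS-like genes receive
their planted class with multivariate q < 0.05, ranking by q separates
planted from null genes with AUC ≥ 0.95, the screen's realized FDR on
500 association-null replicates (200 genes × 50 tumors) stays within
Monte-Carlo slack of the 5% target, and a platform at half scale
calibrates to half the deletion threshold exactly. Statistical
primitives are checked against independent oracles: full enumeration for
the exact rank-sum p, the step-up definition for BH, brute-force draws
for hypergeometric tails, a direct per-gene scan for interval
assignment. Problem sizes in the suite (hundreds of genes, tens of
samples, 500 null replicates) are the package's chosen validation scale.

The generator does **not** simulate probe-level intensities, CBS itself,
batch or dye effects, subclonal mixtures, correlated gene neighborhoods
beyond shared segments, or non-Gaussian heavy-tailed noise. Passing
these tests therefore demonstrates that the implementation computes its
statistics correctly and recovers structure it models — not that the
thresholds transfer to any particular real platform, where calibration
(`calibrate_platform_threshold`) and threshold sweeps are the intended
first step.

## Known limitations

* Strand is read but ignored by segment overlap (assignment is
  strand-agnostic); only the TSS rule uses it.
* The per-group 20% screen gate is one reading of an ambiguous rule; the
  combined-group alternative is expressible by lowering
  `min_sample_fraction`.
* Euclidean distances are reported as effect sizes alongside the tests;
  how distances and tests were originally combined is not recoverable,
  and the package's choice (tests on the observations, distances as
  summaries) is the defensible deterministic one.
* The hypergeometric universe ("genes with all three modalities") is a
  design decision; published analyses rarely state theirs.
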