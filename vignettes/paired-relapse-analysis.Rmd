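---
title: "Methods: paired primary–relapse transcriptome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired primary-relapse transcriptome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

relapsedelta implements a complete analysis path for cohorts of matched
primary and relapse tumor transcriptomes: a pair-variance statistic,
pair-blocked moderated differential expression, signature-based cell-type
deconvolution with paired shift tests, a rank-based enrichment cross-check,
survival scanning and metagenes, and SNV fingerprint identity verification.
This vignette records the models, the parameters that matter, and the design
decisions behind each step.

## The pair-variance statistic

The central descriptive quantity is the transcriptome movement of one tumor
between diagnosis and recurrence. Expression is first put on the log2 RPKM
scale, `log2(count * 1e9 / (libsize * length) + 1)`, with library size taken
as the within-matrix column sum (the pipeline starts at count matrices and
never sees aligner totals; the pseudocount of 1 maps zero counts to exactly
zero and bounds values below). The `n_hvg = 500` genes with largest
cross-sample variance are kept, genes are mean-centered (not unit-scaled —
HVG selection deliberately emphasizes high-variance genes, and unit scaling
would undo that choice), and samples are projected onto the top `n_pcs = 3`
right singular directions. The statistic is the Euclidean distance between a
patient's two samples in that 3-dimensional score space, on raw (unweighted)
scores; variance-weighted distances are available via the `weights` argument
of `pair_distances()`.

Two conventions make results reproducible: ties in HVG selection break by
lexicographic gene id, and each component's sign is fixed by forcing its
largest-magnitude loading positive.

Group contrasts of distances use Welch's unequal-variance t-test (group
sizes in these designs are routinely unbalanced, e.g. 12 vs 4 vs 8);
covariate associations (age) default to Pearson correlation, matching the
linear-trend displays such studies use, with Spearman exposed as an option.
Subset analyses (one molecular group at a time) recompute HVGs and
components inside the subset, so excluded samples cannot leak in.

## Pair-blocked moderated differential expression

Patient pairing is handled by within-pair differencing — for balanced pairs
this is exactly the paired two-level linear model with a patient blocking
factor, and it reduces the test to a one-sample problem on the difference
matrix. Gene-wise variances are moderated with the standard empirical-Bayes
scaled-inverse-chi-squared prior: the prior degrees of freedom `d0` and
prior variance `s0^2` are estimated by moment matching on `log(s_g^2)` using
digamma/trigamma identities (closed-form and directly testable, rather than
a marginal-likelihood fit), the posterior variance is
`(d0*s0^2 + d_g*s_g^2) / (d0 + d_g)`, and the moderated t is referred to a
t distribution on `d0 + d_g` degrees of freedom (normal when `d0` is
infinite, which the estimator returns when the observed log-variance spread
is no wider than sampling noise). Unit tests verify the whole path against
limma on shared inputs and recover generating hyperparameters from
simulation within 15%.

Differential calls use Benjamini–Hochberg control at adjusted p < 0.05 with
no additional fold-change filter. Top-k lists order by adjusted p, then
|log2FC|, then gene id. Groups 3 and 4 are merged by default (the
non-SHH/non-WNT convention); any group subset can be analyzed. Enrichment of
DEG lists against user-supplied GMT collections uses the upper-tail
hypergeometric test with BH across sets.

## Deconvolution and the enrichment cross-check

Cell-type signatures are built from a labeled single-cell reference: per-type
mean CPM profiles, with markers chosen per type by the log2 CPM margin over
the best competing type (top 50 per type by default; at least 20 cells per
type required). Bulk CPM profiles are decomposed over the signature genes by
non-negative least squares and renormalized to proportions.

The least-squares rows are weighted by the inverse mean signature expression
by default. Sequencing counts are overdispersed with roughly constant
coefficient of variation, so unweighted least squares on the CPM scale lets
a handful of very highly expressed genes dominate the fit; inverse-mean
weighting is the corresponding variance stabilization. Unweighted NNLS
remains available (`weighting = "none"`). Goodness of fit per sample is the
Pearson correlation between fitted and observed log2 CPM, with a permutation
p-value (default 100 gene relabelings, mirroring common practice for
deconvolution significance).

Composition shifts are paired t-tests per cell type, stratified by molecular
group (strata below 3 pairs are reported with `p = NA` rather than tested —
small-group results are flagged, not silently computed). As an independent
cross-check, `gsva_like_scores()` computes a single-sample rank-weighted
Kolmogorov–Smirnov running-sum score of each cell type's marker set on
group-mean expression profiles; for programmed composition shifts the shift
direction from deconvolution and the primary→relapse score direction must
agree, and the acceptance suite enforces exactly that. The weight exponent
defaults to 1 (value-weighted); 0 gives the classical unweighted KS
statistic. Note that with all-positive expression values the weighted score
of a random set is slightly positive by construction; direction comparisons
are always relapse vs primary of the *same* set, which cancels that offset.

## Survival machinery

Kaplan–Meier, log-rank and Cox models delegate to the survival package
(Efron tie handling — more accurate than Breslow at monthly resolution);
unit tests pin them against hand-coded product-limit, risk-table and Efron
partial-likelihood oracles. The expression-cutoff scan tries every distinct
expression value between the 10th and 90th percentile as a high/low split,
requires at least 5 patients per side, keeps the split with minimal raw
log-rank p, and multiplies by the number of cutoffs tested (Bonferroni).
The window and minimum group size prevent degenerate splits and are
configurable rather than fixed truths, since published "scan" tools rarely
document their exact parameters. Because splits depend only on ranks, the
scan is invariant to monotone transforms of expression.

Metagenes pool scan-significant genes whose risk direction is concordant
with their differential-expression direction: relapse-up genes with
high-expression risk form the unfavorable set, relapse-down genes with
high-expression protection the favorable set. The per-sample score is the
mean of z-scored member genes — scale-free and standard where no aggregation
is prescribed. In survival analyses of relapsed cohorts the clock starts at
re-operation; the generator emits both OS and PFS clocks.

Categorical clinical associations use Fisher's exact test when any expected
cell is below 5 and the chi-squared test otherwise.

## SNV fingerprints

Genotypes are called from variant allele fractions with thresholds 0.1/0.9
(strict inequalities; boundary values call heterozygous), and pair identity
is the fraction of jointly called sites with equal codes, requiring at least
20 sites and a 0.8 concordance for a match verdict. Concordance on genotype
codes is robust to FFPE-level VAF noise, unlike raw VAF correlation; the
threshold is configurable since no published criterion exists. Expected
concordance for unrelated patients at common-variant sites is ~0.4–0.5,
leaving a wide margin to the 0.8 verdict line.

## What the synthetic cohort emulates

`simulate_cohort()` generates the structure the methods assume, with ground
truth returned alongside:

- **Design.** 43 patients (24 SHH, 5 Group 3, 14 Group 4) with one primary
  and one relapse sample each; 2000 genes with log-uniform lengths
  (300 bp–30 kb) on 22 synthetic chromosomes assigned in contiguous blocks.
- **Expression.** Each sample is a negative-binomial draw (size 8 — FFPE-
  grade overdispersion) around a library-size-scaled mixture of six
  cell-type signature profiles at Dirichlet-drawn fractions; libraries span
  0.5–1.5M counts.
- **Composition.** Per-group Dirichlet parameters give each molecular group
  a distinct dominant compartment. Relapse parameters preserve each group's
  total concentration so targeted ratios are exact: B1 ×1.5 and C1 ×0.6 in
  SHH, A1 ×1.5 and C1 ×0.6 in Groups 3/4 — the 1.5-fold cell-cycle gain
  matching the magnitude described for Group 4 medulloblastoma relapses. The total concentration
  (40 per group) was chosen once so that a 1.5× shift of one subtype is
  detectable by a paired t-test at the smallest per-group sample size
  (analytic power ≈ 0.9 at 14 pairs); it is a study condition, not a free
  dial.
- **Expression signal.** 100 designated DE genes (half up, half down at
  relapse, |log2FC| 1.5, disjoint from marker genes so composition and
  expression signals stay separable) and, in half of the pairs, a
  relapse-only ×1.6 expression shift on a contiguous block of 5% of genes
  on one chromosome (an arm-level CNV footprint).
- **Outcomes.** Exponential survival (scale 60 months) with log hazard ratio
  0.8 per SD of the mean expression of the relapse-up genes; censoring hits
  an exact 30% rate by construction. SHH ages are bimodal (infant/adult),
  Groups 3/4 unimodal childhood, so age-association analyses have structure
  to find when configured.
- **Identity.** 200 SNP sites with minor allele frequencies 0.15–0.5;
  genotypes are shared between a patient's two samples, VAFs observed with
  Gaussian noise (sd 0.04).

What it does **not** emulate: FFPE degradation artifacts, platform/batch
effects between bulk and reference (the published deconvolution tool's
batch-correction mode is out of scope here — synthetic bulk and reference
share a generative platform), methylation data, and real marker gene lists
for the six subtypes (published subtype signatures are not available as
plain gene lists; synthetic signatures stand in). Passing tests therefore demonstrate
statistical correctness and calibration of the machinery, not robustness to
cross-platform technical artifacts.

## Numerical choices and degenerate inputs

- Zero library-size columns, missing gene lengths, duplicate ids, unknown
  timepoint labels and inverted thresholds are hard errors naming the
  culprit.
- All-zero gene variance across pairs is degenerate for moderation and
  errors; single zero-variance genes are excluded from hyperparameter
  estimation but still scored.
- NNLS renormalizes fractions to sum 1; an all-zero fit (never observed in
  practice) falls back to uniform fractions.
- The trigamma inversion for `d0` uses Newton iteration with the standard
  asymptotic branches; convergence tolerance 1e-10.
- Cox fits error on non-convergence and on separation (|beta| > 20).

## Problem sizes in the test suite

The suite exercises calibration and recovery at deliberately scaled sizes:
null-calibration sweeps use 120–250 replicate cohorts or scans at 250–1500
genes and 10 pairs per group; recovery checks run the full default cohort
(2000 genes, 86 samples) for deconvolution, 25 replicate 14-pair Group 4
cohorts for shift power, 50 replicates at n = 400 for Cox recovery, and 20
replicates of 4000–5000 genes for hyperparameter recovery. These sizes give
Monte-Carlo error comfortably below the margins asserted.

## Known limitations

- The moderated model assumes exchangeable gene variances; strongly
  structured variance (e.g. expression-dependent trends) would call for a
  trended prior, which is not implemented.
- NNLS deconvolution assumes the reference spans the bulk content; missing
  cell types are absorbed into the closest available profiles.
- The cutoff scan's Bonferroni correction is conservative because adjacent
  cutoffs give highly correlated tests; calibration is at-or-below nominal,
  never above.
- Survival generation uses an exponential baseline; methods are validated
  under proportional hazards only.
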