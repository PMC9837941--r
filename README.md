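# relapsedelta

Tools for analyzing matched **primary–relapse tumor transcriptome cohorts**,
modeled on paired medulloblastoma study designs. The package answers the
questions such studies ask: *how far does a tumor's expression profile move
between diagnosis and recurrence, which genes drive the move, how does the
cellular composition shift, and do relapse-associated genes carry prognostic
weight?* Because real paired FFPE cohorts are rarely public, the package
ships a synthetic paired-cohort generator with known ground truth, so every
method is testable end to end.

It is written for computational biologists working with bulk RNA-seq count
matrices plus clinical annotation; all results are tibbles, all plots are
ggplot2, and fitted objects support `tidy()`/`glance()`/`autoplot()`.

## Methods at the core

- **Pair-variance statistic.** For each patient *p* with primary/relapse
  samples, compute sample scores on the top *k* = 3 principal components of
  the top 500 highly variable genes (log2 RPKM), and take
  *d(p)* = ‖**s**(primary) − **s**(relapse)‖₂. Group differences are Welch
  t-tests on *d*; covariate effects (e.g. age) are Pearson correlations.
- **Pair-blocked moderated differential expression.** Within-pair differences
  *d₍pg₎* = relapse − primary are tested with an empirical-Bayes moderated
  one-sample t: gene variances *s²_g* are shrunk toward a prior,
  *s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g)*, with (d₀, s₀²) estimated by
  moment matching on log *s²_g*; BH control at adjusted p < 0.05.
- **Cell-composition deconvolution.** Marker-gene signatures for six tumor
  cell subtypes (cell-cycle A1/A2, progenitor B1/B2, differentiated neuronal
  C1/C2) are built from a labeled single-cell reference; bulk CPM profiles
  are decomposed by non-negative least squares (inverse-mean row weighting),
  fractions renormalized to 1, primary→relapse shifts tested with paired
  t-tests per molecular group, and cross-checked by a rank-weighted KS
  enrichment score on group-mean profiles.
- **Survival.** Kaplan–Meier, log-rank, an expression-cutoff scan over all
  admissible cutoffs with Bonferroni correction ("Kaplan scan"), pooling of
  risk-concordant genes into favorable/unfavorable metagenes (mean z-score),
  and Cox proportional-hazards models with Efron tie handling.
- **SNV fingerprinting.** Genotypes called from variant allele fractions and
  pairwise concordance confirm that both samples of a pair share a patient.

## Worked example

```r
library(relapsedelta)

cfg <- simulation_config(seed = 1)      # 43 pairs: 24 SHH, 5 G3, 14 G4
sim <- simulate_cohort(cfg)
lrpkm <- log2_rpkm(sim$counts, sim$gene_info)

pair_variance(lrpkm, sim$annotation)
#> Pair-variance analysis (all): 43 pairs, 500 HVGs, 3 PCs
#> Variance explained (%): 22.4, 8.2, 4.6
#> Median pair distance: 16.528

paired_dge(lrpkm, sim$annotation, groups = c("G3", "G4"))
#> Paired DGE (G3+G4): 19 pairs, 2000 genes
#>   up in relapse: 56  down in relapse: 53

sc  <- simulate_sc_reference(cfg)
sig <- build_signature(sc$sc_counts, sc$labels)
dec <- deconvolve_nnls(cpm_normalize(sim$counts), sig, n_perm = 0)
strata <- setNames(subset(sim$annotation, timepoint == "primary",
                          c(patient_id, group)), c("patient_id", "stratum"))
cmp <- compare_fractions(dec, pair_index(sim$annotation), strata)
subset(cmp, stratum == "G4" & cell_type %in% c("A1", "C1"))
#>   stratum cell_type n_pairs mean_primary mean_relapse mean_diff     t       p
#> 1 G4      A1             14        0.154        0.231    0.0765  2.96 0.0111
#> 2 G4      C1             14        0.249        0.173   -0.0755 -4.14 0.00115
```

The Group 4 relapse samples show the programmed composition change: the
cell-cycle subtype A1 rises roughly 1.5-fold (0.154 → 0.231) while the
differentiated C1 population falls, both significant by paired t-test at
the 14-pair sample size. Fingerprinting (`fingerprint_check(sim$vaf,
sim$annotation)`) verifies all 43 pairs as same-patient matches.

A full seeded run of every stage, with a hash manifest:

```r
run_pipeline(pipeline_config(list(out_dir = "run1", seed = 1)))
```

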