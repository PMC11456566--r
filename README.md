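# azasig

Response signatures and clonal dynamics for azacytidine-treated MDS.

Hypomethylating therapy with 5-azacytidine (AZA) is standard care for
high-risk myelodysplastic syndrome (MDS), but only a minority of patients
respond, and there is no routine way to predict response or survival before
starting therapy. `azasig` implements, as a tested R pipeline, the analysis
stages used to study paired pre-/post-AZA patient cohorts profiled at the
DNA level (targeted myeloid panels, variant allele frequencies) and the RNA
level (bulk counts from sorted CD34+ stem/progenitor cells), for
bioinformaticians and translational hematology groups who want to apply or
stress-test this kind of classifier on their own cohorts.

## What the package computes

**Clonal dynamics.** Variant calls carry a VAF (% of reads supporting the
mutant allele) per timepoint and marrow compartment. Calls are filtered at a
5% VAF cutoff with a symmetric *paired rescue*: a sub-cutoff call is kept
when the same mutation clears the cutoff at the other timepoint (an
expanding subclone seen at 1.27% pre-treatment, or a collapsing clone at
3.98% post-treatment). Each paired mutation is classified as
ACQUIRED / INCREASED / STABLE / DECREASED / LOST, with STABLE meaning a
relative change below 25% of the pre-treatment VAF. The package summarizes
the transition/transversion spectrum, per-substitution dynamics, bulk-vs-CD34+
VAF correlation, and per-patient mutational burden.

**Differential expression.** Counts are normalized by the median-of-ratios
size-factor scheme. Per gene, log2FC is the difference of group means of
log2(normalized + 1) and p comes from a Welch two-sample t (paired t
available). DEGs satisfy |log2FC| >= 1 with p < 0.01.

**The Δ(NR−R) classifier.** DEG sets for blast responders (R) and
non-responders (NR), each versus healthy controls, are reduced to
*unique* signatures: R\NR and NR\R. Any sample is scored against each
signature by the mean cohort z-score over signature genes, and

  Δ(NR−R) = NR score − R score.

Samples with Δ(NR−R) ≥ median(Δ(NR−R)) are labeled NR-like, the rest R-like;
each class is further split high/low at the within-class median of its own
signature score. Scoring, standardization and medians are always computed
inside the cohort being classified, so signatures transfer across cohorts on
gene membership alone.

**Survival.** Kaplan–Meier curves, the k-group log-rank test and the
Yates-corrected chi-square are implemented from the standard formulas and
validated against `survival` and `stats` in the test suite.

**Synthetic cohorts.** Seeded generators produce (i) negative-binomial
expression cohorts (variance μ + φμ²) with planted arm-specific genes and
paired pre/post samples, (ii) paired variant tables with known dynamics
categories and a calibrated compartment correlation, and (iii) validation
cohorts whose hazard is `baseline_rate·exp(hazard_beta·b)` for a latent
NR-burden `b` that also drives NR-signature expression. Truth records make
every stage testable by parameter recovery.

## Worked example

```r
library(azasig)
res <- run_aza_pipeline(
  seed = 1,
  sim  = sim_config(n_controls = 20, n_patients = 40, n_undetermined = 0,
                    frac_R = 0.5, seed = 1),
  surv = survival_sim_config(n_samples = 180, hazard_beta = 1))
res
#> aza_pipeline run (seed 1, config 8670e0bd)
#>   signatures: 49 R-unique, 69 NR-unique genes
#>   validation: 180 samples -> 90 NR-like / 90 R-like
#>   log-rank NR-like vs R-like: p = 1.66e-15
res$survival_report
#> Survival report
#>   NR_like: n = 90, events = 74, median survival = 5.744
#>   R_like: n = 90, events = 49, median survival = 26.89
#>   log-rank NR_like vs R_like: chi2 = 63.4, p = 1.66e-15
```

The derivation cohort planted 50 responder-specific and 70
non-responder-specific genes; the derived unique signatures recovered 49 and
69 of them with no cross-arm contamination. On the independent validation
cohort the median split labels exactly half the samples NR-like, and the
NR-like arm — the samples carrying the planted non-responder expression
burden — shows the expected sharply worse survival (median 5.7 vs 26.9 time
units, log-rank p ≈ 2e-15).

The shipped B-cell development panel (56 genes, mean expression in controls
and in R/NR patients pre/post therapy) reproduces its directional summary:

```r
panel <- system.file("extdata", "bcell_panel_means.tsv", package = "azasig")
panel_directional_counts(panel)[c("n_genes", "n_down_pre_vs_control", "n_up_post_vs_pre")]
#> $n_genes        [1] 56
#> $n_down_pre_vs_control [1] 43
#> $n_up_post_vs_pre      [1] 30
```

i.e. 43 of the 56 B-cell genes are lower in pre-treatment patients than in
healthy controls, and 30 rise again after therapy.

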