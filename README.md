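# mitotwin

Twin-pair statistical machinery for studies linking adipose-tissue DNA
methylation, mitochondrial DNA quantity (mtDNAq) and obesity-related
traits. The package is aimed at biostatisticians and genetic
epidemiologists working with co-twin designs: it provides the full
inferential chain such a study needs — from qPCR cycle-threshold tables to
a causal-pattern label — together with a synthetic twin-cohort generator
with known ground truth, so every estimator can be validated without
access-restricted cohort data.

## What it implements

* **qPCR relative quantification** (`relative_quantities`,
  `impute_missing_gene`, `mtdnaq_score`): the 2^-ΔΔCt chain to calibrated
  normalized relative quantities (CNRQ) for the mitochondrial genes ND5 and
  CYTB against the genomic references APP and B2M, stochastic-regression
  imputation of a dropped target gene on the log2 scale, and the two-gene
  mean as the mtDNAq metric.
* **Exchangeable GEE** (`fit_gee_exchangeable`, `wald_test`): a
  Gaussian-identity generalized estimating equation with exchangeable
  working correlation for twin pairs, moment estimation of the within-pair
  correlation α, cluster-robust sandwich covariance and z-tests.
* **EWAS** (`run_ewas` and its parts `consensus_pair_correlation`,
  `fit_probe_models`, `ebayes_moderate`, `bh_fdr`): probe-wise association
  of an exposure with a CpG × sample M-value matrix, twin relatedness
  handled through a consensus within-pair correlation ρ (GLS by pairwise
  whitening), empirical-Bayes variance moderation with moderated
  t-statistics `t_j = β_j / (u_j · s̃_j)` where
  `s̃_j² = (d₀s₀² + d_j s_j²)/(d₀ + d_j)`, and Benjamini–Hochberg FDR.
* **ICE FALCON** (`run_bidirectional`, `build_paired_dataset`,
  `fit_models123`, `coefficient_changes`, `classify_causal_pattern`):
  Inference about Causation from Examination of FAmilial CONfounding. For
  each twin as "self",

      Model 1:  Y_self ~ α + β_self  X_self
      Model 2:  Y_self ~ α + β_cotwin X_cotwin
      Model 3:  Y_self ~ α + β_self  X_self + β_cotwin X_cotwin

  with covariates, clustered on pair. Attenuation of β_cotwin toward null
  under mutual adjustment (with β_self stable) is evidence of causation
  X → Y; joint attenuation indicates familial confounding. Coefficient
  changes Δβ get standard errors from a pair-resampling bootstrap, and an
  explicit, fully-traced rule set assigns one of six evidence labels.
* **Trait associations and variance partition**
  (`trait_gee_association`, `batch_associations_with_fdr`,
  `pearson_correlation`, `variance_explained_lmm`): standardized GEE betas
  with robust 95% CIs for batteries of obesity-related traits, per-outcome
  FDR with a three-way significance partition, and marginal/conditional R²
  from a pair random-intercept mixed model.
* **Synthetic cohorts** (`sim_scenario`, `simulate_twin_cohort`,
  `simulate_methylation_matrix`, `simulate_qpcr_plate`): MZ/DZ pairs with
  ACE-style familial structure and configurable causal mode
  (causation in either direction, familial or within-individual
  confounding, null), methylation matrices with a small causal set among
  nulls, and qPCR plates with the exact log2 link and missingness.

## Worked example

Simulate a cohort in which mtDNAq causally raises methylation at ten CpGs,
then recover the structure:

```r
library(mitotwin)

co  <- simulate_twin_cohort(sim_scenario(75, causal_mode = "x_causes_y",
                                         beta_causal = 0.5, seed = 1))
sim <- simulate_methylation_matrix(co, "x", n_cpgs = 2000, n_causal = 10,
                                   effect = 0.5, seed = 1)
tab <- run_ewas(sim$m, ewas_design(co, "x",
                                   covariates = c("age", "sex", "smoking")),
                seed = 1)
attr(tab, "rho")                      # consensus pair correlation
sum(tab$fdr_q < 0.05)                 # discoveries

res <- run_bidirectional(co, x = "x", y = "y",
                         covariates = c("age", "sex", "smoking"),
                         n_boot = 1000, seed = 1)
print(res)
```

A run of the bundled analysis workflow (`analysis/01_simulate_cohort.R` …
`05_associations.R`, written to `results/`) prints, for the ICE FALCON step
on the top EWAS CpG:

```
ICE FALCON models: top_cpg (Y) ~ mtdnaq (X), 75 pairs
  Model 1 beta_self  : +0.555 (SE 0.082, p 1.23e-11)
  Model 2 beta_cotwin: +0.337 (SE 0.093, p 0.000285)
  Model 3 beta_self  : +0.543 (SE 0.067, p 3.71e-16)
  Model 3 beta_cotwin: +0.020 (SE 0.066, p 0.764)
Pattern: evidence_x_causes_y
```

Read: the cross-twin cross-trait association (0.337 ≈ β·r) collapses to
0.020 once the twin's own mtDNAq is adjusted for, while β_self barely moves
— the signature of causation from mtDNAq to methylation, which is exactly
how the cohort was generated. The EWAS step on the same run reports
ρ = 0.47, d₀ = 4.0 and 10/10 causal CpGs recovered at q < 0.05.

`published_icefalcon_estimates()` ships the printed estimates of a
published 68-pair MZ twin analysis of mtDNAq against SH3BP4/DHRS3
methylation; `icefalcon_from_estimates()` + `classify_causal_pattern()`
reproduce its coefficient-change arithmetic and its causal reading of the
mtDNAq → cg19998400 direction.

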