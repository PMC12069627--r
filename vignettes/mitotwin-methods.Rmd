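---
title: "Statistical methods for twin-pair analyses of mtDNA quantity, methylation and obesity traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for twin-pair analyses of mtDNA quantity, methylation and obesity traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitotwin)
```

# Scope

`mitotwin` implements the inferential machinery of a twin-pair study design
that links adipose-tissue DNA methylation, mitochondrial DNA quantity
(mtDNAq) and obesity-related traits: qPCR relative quantification, a
clustered epigenome-wide association scan (EWAS) with moderated
t-statistics, GEE trait-association batteries, a mixed-model variance
partition, and the ICE FALCON causal-inference procedure. Because the
cohorts such analyses are run on are access-restricted, the package ships a
synthetic twin-cohort generator with full ground truth; every statistical
claim made by the package is testable against that truth.

# The synthetic twin cohort

`simulate_twin_cohort()` generates standardized traits for MZ and DZ pairs
under a reduced ACE-style parameterization: each trait component may load on
a pair-shared factor whose twin–twin correlation is 1 for MZ pairs and 1/2
for DZ pairs (the additive-genetic share), so a within-pair correlation `r`
declared for MZ pairs yields `r/2` in DZ pairs by construction. A full
biometric (A/C/E) decomposition is deliberately not modeled: the downstream
methods consume only within-pair and cross-twin covariances, which the
single-factor construction already controls exactly.

Five causal structures connect the exposure X to the outcome Y:

* `null` — independent traits;
* `x_causes_y` — `Y = beta X + e`, residual scaled so `Var(Y) = 1`;
* `y_causes_x` — the mirror construction;
* `familial_confounding` — a fully pair-shared factor with variance
  `var_familial` loads equally on X and Y;
* `within_individual_confounding` — an individual-level factor with variance
  `var_within_conf` loads equally on both.

Key defaults and why:

* `r_withinpair_x = 0.75`, `r_withinpair_y = 0.5`. Within-pair correlations
  of mtDNAq and CpG methylation are not published for cohorts of this kind,
  so these are design choices in the plausible MZ range: a high value for
  the exposure (cross-twin regressions have power only when the exposure is
  familially correlated) and a moderate value for the outcome's residual.
  They are fixed once; tests and the acceptance script use them as the study
  conditions.
* `beta_causal`, `var_familial`, `var_within_conf` have no defaults in
  spirit: scenario-recovery runs use 0.4, the analytic-limit runs 0.5,
  matching effect sizes of the order reported for standardized twin-pair
  regressions.
* Covariates (age uniform over 23–70 years and shared within pair, sex 59%
  female and shared within pair, smoking never/former/current at roughly
  39/31/30%) are independent of the causal block unless `covariate_effects`
  turns them into measured confounders; trait variance is renormalized to 1
  after covariate effects are added.
* One global seed expands into per-component sub-seeds (`sub_seed()`), so
  the cohort, the methylation matrix, the qPCR plate and every bootstrap are
  decoupled but jointly reproducible.

What the generator does *not* emulate: genotypes and meQTL structure, array
intensities and normalization artifacts, platform batches, cell-type
composition, non-Gaussian trait margins (raw-scale trait shapes are
cosmetic, analysis happens on standardized or log-transformed scales), and
selection into the cohort. Passing tests therefore demonstrate correctness
of the estimators under the stated statistical structure, not robustness to
every artifact of real array data.

# qPCR relative quantification

`relative_quantities()` fixes the conventions the processing software leaves
open: amplification efficiency 2.0 for all genes, the normalization factor
is the geometric mean of the two reference genes (APP, B2M), and the
calibrator is the geometric mean across samples, so each gene's calibrated
normalized relative quantity (CNRQ) has geometric mean 1. Any other
calibrator differs by a global factor that downstream standardization
removes. The simulated plate uses the exact log2 link
`Ct = baseline − log2(quantity) + noise`, so on noise-free plates the
pipeline inverts the simulation up to a global constant — a property the
acceptance suite checks at tolerance 1e−10 on the log scale.

Missing target genes (one of ND5/CYTB) are imputed by *stochastic
regression*: least squares of the missing gene's log2 CNRQ on the observed
gene's over complete cases, plus a single normal residual draw with the
fit's residual SD. The log2 scale is a documented choice (quantities are
multiplicative); single rather than multiple imputation matches the
single-value workflow the score feeds. `mtdnaq_score()` is the arithmetic
mean of the two target CNRQs.

# The GEE engine

`fit_gee_exchangeable()` is a Gaussian-identity GEE with exchangeable
working correlation, written around the closed form of the inverse
exchangeable correlation matrix so that all estimating-equation quantities
assemble from per-cluster row sums; no per-cluster loops are needed and
fits at tens of thousands of pairs take milliseconds. The working
correlation is re-estimated between coefficient solves by the standard
moment estimator (Pearson residual cross-products within clusters,
denominator = total within-cluster pair count minus the number of
regression parameters, clamped into the admissible range
`(-1/(m-1), 1)`). Standard errors are the cluster-robust sandwich from
cluster-level score outer products, and inference is by two-sided z-tests;
no small-sample correction is applied, matching the z-test convention of
the reported analyses. Degenerate inputs are handled explicitly:
all-singleton data fix `alpha = 0` and reduce to OLS; rank-deficient
designs and zero-variance columns are errors, not silent drops.

# EWAS with a consensus pair correlation

The probe-wise "random effect for twin pairs" is implemented as a
*consensus-correlation GLS*: `consensus_pair_correlation()` profiles each
sampled CpG's Gaussian likelihood over a common within-pair residual
correlation on a fixed grid (step 0.005, range ±0.95), then combines
per-CpG maximizers by a 15% trimmed mean on the Fisher-z scale. A shared
`rho` across CpGs is the established equivalent of per-probe random
intercepts at array scale, at a tiny fraction of the cost; the trimming
fraction and z-scale averaging are fixed choices. `fit_probe_models()` then
whitens the design and the data once (pair-wise Cholesky) and solves every
probe in a single least-squares pass; `rho = 0` is exactly probe-wise OLS.

`ebayes_moderate()` shrinks residual variances toward a scaled
inverse-chi-square prior whose hyperparameters `(d0, s0^2)` are estimated by
matching the first two moments of the log residual variances to a scaled F
distribution (digamma/trigamma inversion by Newton iteration). When the
observed spread of log-variances does not exceed chi-square sampling noise,
`d0` is flagged infinite and the prior collapses to a point mass at the mean
variance. Moderated t-statistics gain `d0` degrees of freedom;
Benjamini–Hochberg FDR is applied across all analyzed CpGs. The test suite
cross-checks the whole chain against the independent limma implementation
(consensus correlation, GLS coefficients, prior df/scale, moderated t).

# ICE FALCON

For twin pairs with exposure X and outcome Y, three models are fitted on the
doubled-pair layout (each twin serves once as "self"):

* Model 1: `Y_self ~ X_self`
* Model 2: `Y_self ~ X_cotwin`
* Model 3: `Y_self ~ X_self + X_cotwin`

always with the covariates, clustered on pair, with standardized
coefficients. If the cross-twin cross-trait coefficient (beta_cotwin) is
present marginally and attenuates toward null once the twin's own exposure
is adjusted for — while beta_self stays stable — the pattern is consistent
with causation from X to Y. If beta_cotwin instead appears or strengthens
only upon conditioning, the pattern points to causation from Y to X; if both
coefficients attenuate together, to familial confounding; a cross-twin
coefficient that appears in Model 3 with no marginal counterpart is the
signature of possible within-individual confounding, which a twin design
cannot remove.

**Estimation choice.** Coefficients are estimated under the *independence*
working correlation (with pair-clustered sandwich SEs), not the weighted
exchangeable fit. The reason is statistical, not computational: when the
mean model omits the co-twin's exposure (Models 1 and 2), a weighted GEE no
longer converges to the marginal regression coefficient — the
full-covariate conditional-mean condition fails — and at realistic
within-pair correlations the distortion is large (at `beta = 0.5`,
`r = 0.75`, the weighted Model-2 cross-twin coefficient converges to about
0.24 instead of `beta * r = 0.375`). ICE FALCON's interpretation is written
entirely in terms of marginal coefficients, so the unweighted estimating
equations are the faithful estimator; `working = "exchangeable"` remains
available for comparison. Under independence estimation, the analytic
large-sample limits hold exactly: pure causation gives
`(beta_self^M1, beta_cotwin^M2, beta_cotwin^M3, beta_self^M3) ->
(beta, beta r, 0, beta)`, and pure MZ-shared confounding with equal
loadings gives Model-3 coefficients `beta_marginal / (1 + r_x)`.

**Coefficient changes.** The evidence summaries are
`Δbeta_self = beta_self(M3) − beta_self(M1)` and
`Δbeta_cotwin = beta_cotwin(M3) − beta_cotwin(M2)`, with standard errors
from a non-parametric bootstrap that resamples *pairs* with replacement to
the original number of pairs (1000 replicates for inference), stratified by
zygosity when DZ pairs are included — the MZ/DZ mix is part of the design
and is held fixed across replicates. Change p-values use the normal
approximation with the bootstrap SE, matching SE-based reporting;
percentile intervals can be derived from the stored replicates if needed.
No multiple-testing adjustment is applied within ICE FALCON.

**Classification.** The published criteria for "attenuated toward null" and
"remained stable" are verbal; `classify_causal_pattern()` makes them
explicit, configurable, and fully traced. Defaults: coefficient gate
`alpha = 0.05`; marginal gate `alpha_marginal = 0.10` (analyses of this
design treat p-values just below 0.10 as marginal evidence); "stable
beta_self" means change p > 0.05 *and* relative change < 25%; "attenuated
toward null" requires the Model-3 cross-twin coefficient to be
non-significant *or* to have lost more than 50% of its magnitude (this is
what separates causation, where the coefficient goes to 0, from familial
confounding, where it settles at `beta/(1+r)` and stays significant); the
familial rule additionally demands a significant beta_self attenuation of
at least 10%. The thresholds were derived from the analytic limits of the
four generative scenarios before the recovery suite was run. Reverse
causation and within-individual confounding produce overlapping signatures
(both can flip the cross-twin sign under conditioning); they are separated
by whether a *marginal* cross-twin association exists in Model 2 — present
under reverse causation (`beta r_y`), absent under purely individual
confounding. The within-individual label is deliberately suffixed
`_possible`, and the recovery tests accept it as the correct answer for
that scenario.

The headline label of `run_bidirectional()` comes from the forward
direction; the reverse direction's coefficients are recorded in the rule
trace (and a missing reverse direction sets a reduced-certainty flag), which
mirrors how bidirectional runs are read in practice: each direction is
classified on its own terms and the two readings are reconciled narratively.

# Trait associations and the variance partition

`trait_gee_association()` log10-transforms flagged skewed traits (the flag
is config, not an automated normality test — reproducibility over
automation), standardizes outcome and trait, and reports the standardized
GEE beta with robust 95% CI. `batch_associations_with_fdr()` applies BH-FDR
*per outcome family* (methylation and mtDNAq families adjusted separately,
matching per-outcome FDR reporting; a joint family is a trivial variation)
and emits the three-way partition of traits significant for one outcome,
the other, or both.

`variance_explained_lmm()` answers the expression-on-methylation question
with a different estimator on purpose: a random-intercept-per-pair linear
mixed model (lme4, ML by default with a REML flag, since the convention is
not fixed) partitioned Nakagawa-style — marginal R² is the fixed-effect
share `var(X b) / (var(X b) + var_pair + var_resid)`, conditional R² adds
the pair share. A boundary fit with zero pair variance collapses marginal
and conditional, as it should.

# Numerical and scale choices

* Problem sizes used by the test and acceptance runs — 50,000 pairs for
  analytic limits, 500 null replicates at 200 pairs (200 bootstrap
  draws each) for change-test calibration, 50 seeds × 4 scenarios at 2000
  pairs for classifier recovery, 20 fixture seeds of 2000 CpGs × 150
  samples for EWAS operating characteristics — were chosen to make
  binomial/Monte-Carlo noise comfortably smaller than the tolerances being
  checked while keeping a full run in the minutes range on one core.
* GEE convergence: alternating updates stop when the maximum coefficient
  change is below `tol` (default 1e−8), with a 25-iteration cap and a
  non-convergence flag on the returned fit.
* The consensus-correlation grid (step 0.005) bounds the per-CpG maximizer
  error well below the ±0.05 recovery tolerance and keeps the profiling
  deterministic.
* Trigamma inversion uses Newton steps with closed-form guards at both
  extremes; non-convergence degrades to the infinite-`d0` point-mass prior
  rather than failing.
* Bootstrap replicates that fail to fit are skipped; more than 10% failures
  aborts the analysis, since at that point the SE is no longer trustworthy.

# Known limitations

* The generator's covariance structure is exact but its margins are
  Gaussian; heavy-tailed traits are only represented through the log10
  transform hook.
* The consensus-correlation EWAS assumes a shared within-pair correlation
  across CpGs; probes with idiosyncratic familiality are mildly mis-weighted
  (the same trade-off the array-scale consensus approach always makes).
* ICE FALCON cannot, by construction, distinguish reverse causation from
  within-individual confounding when the marginal cross-twin association is
  weak; the classifier surfaces this as the `_possible` label rather than
  forcing a choice.
* All inference is z-based; at very small pair counts (a few dozen pairs)
  the sandwich SEs are anti-conservative, and no bias-corrected sandwich is
  enabled by default.
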