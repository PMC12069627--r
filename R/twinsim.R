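## twinsim: synthetic twin cohorts with known causal structure.
##
## The generator mirrors the data-generating assumptions of the downstream
## analyses: standardized traits, a reduced ACE-style familial structure (one
## pair-shared factor per component, twin-twin correlation 1 for MZ and 1/2
## for DZ), and a configurable causal mechanism between the exposure X and
## the outcome Y. Full ground truth is attached so recovery tests can compare
## estimates against the generating values.

#' Define a twin-cohort simulation scenario
#'
#' @param n_pairs_mz,n_pairs_dz Numbers of MZ and DZ twin pairs.
#' @param causal_mode One of `"null"`, `"x_causes_y"`, `"y_causes_x"`,
#'   `"familial_confounding"`, `"within_individual_confounding"`. Controls how
#'   the outcome trait Y is tied to the exposure trait X.
#' @param beta_causal Standardized causal effect (|beta| < 1); used by the two
#'   causation modes.
#' @param r_withinpair_x Within-pair correlation of X in MZ pairs (DZ pairs
#'   realize half of it, the additive-genetic share). In
#'   `familial_confounding` mode the shared confounder contributes
#'   `var_familial` of this correlation, so `r_withinpair_x >= var_familial`
#'   is required.
#' @param r_withinpair_y Within-pair correlation of the outcome's residual
#'   component (same MZ/DZ convention).
#' @param var_familial Variance share of the pair-shared confounder loading
#'   equally on X and Y (`familial_confounding` mode).
#' @param var_within_conf Variance share of the individual-level confounder
#'   loading equally on X and Y (`within_individual_confounding` mode).
#' @param covariate_effects Optional list with elements `x` and/or `y`, each a
#'   named numeric vector of effects for `age`, `sex`, `smoking` acting as
#'   measured confounders; by default covariates are independent of the
#'   causal block.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_pairs_mz,
                         n_pairs_dz = 0L,
                         causal_mode = c("null", "x_causes_y", "y_causes_x",
                                         "familial_confounding",
                                         "within_individual_confounding"),
                         beta_causal = 0,
                         r_withinpair_x = 0.75,
                         r_withinpair_y = 0.5,
                         var_familial = 0,
                         var_within_conf = 0,
                         covariate_effects = NULL,
                         seed = 1L) {
  causal_mode <- match.arg(causal_mode)
  stopifnot(n_pairs_mz >= 0, n_pairs_dz >= 0, n_pairs_mz + n_pairs_dz >= 1)
  stopifnot(r_withinpair_x >= 0, r_withinpair_x <= 1,
            r_withinpair_y >= 0, r_withinpair_y <= 1,
            var_familial >= 0, var_within_conf >= 0)
  if (abs(beta_causal) >= 1)
    stop("beta_causal must satisfy |beta| < 1 for standardized traits")
  if (causal_mode == "familial_confounding") {
    if (var_familial > min(r_withinpair_x, r_withinpair_y) + 1e-12)
      stop("var_familial exceeds the within-pair correlation it must be ",
           "part of; implied residual familial variance would be negative")
    if (var_familial > 1) stop("var_familial > 1 leaves negative residual variance")
  }
  if (causal_mode == "within_individual_confounding" && var_within_conf > 1)
    stop("var_within_conf > 1 leaves negative residual variance")
  structure(list(n_pairs_mz = as.integer(n_pairs_mz),
                 n_pairs_dz = as.integer(n_pairs_dz),
                 causal_mode = causal_mode,
                 beta_causal = beta_causal,
                 r_withinpair_x = r_withinpair_x,
                 r_withinpair_y = r_withinpair_y,
                 var_familial = var_familial,
                 var_within_conf = var_within_conf,
                 covariate_effects = covariate_effects,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Simulate a twin cohort under a scenario
#'
#' Traits are generated on the standardized scale (mean 0, variance 1 in
#' expectation). The exposure X carries within-pair correlation
#' `r_withinpair_x` in MZ pairs; the outcome Y is assembled according to
#' `causal_mode`:
#' \describe{
#'   \item{null}{X and Y independent.}
#'   \item{x_causes_y}{`Y = beta * X + e`, residual scaled to unit total
#'     variance, residual within-pair correlation `r_withinpair_y`.}
#'   \item{y_causes_x}{the mirror construction: Y is generated with
#'     within-pair correlation `r_withinpair_y` and `X = beta * Y + e`, with
#'     the X-residual carrying `r_withinpair_x`.}
#'   \item{familial_confounding}{a pair-shared factor with variance
#'     `var_familial` loads equally on X and Y.}
#'   \item{within_individual_confounding}{an individual-level factor with
#'     variance `var_within_conf` loads equally on X and Y.}
#' }
#' Age (uniform 23-70 years, shared within pair), sex (59% female, shared
#' within pair) and smoking (never/former/current) are generated
#' independently of the causal block unless `covariate_effects` says
#' otherwise. The generating scenario and latent confounder values are
#' attached as `attr(, "truth")`.
#'
#' @param scenario A [sim_scenario()].
#' @return A data.frame with one row per individual: `individual_id`,
#'   `pair_id`, `zygosity`, `twin_order`, `age`, `sex`, `smoking`, `x`, `y`.
#' @export
simulate_twin_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(sub_seed(scenario$seed, "cohort"))
  np <- scenario$n_pairs_mz + scenario$n_pairs_dz
  zyg <- rep(c("MZ", "DZ"), c(scenario$n_pairs_mz, scenario$n_pairs_dz))
  rx <- scenario$r_withinpair_x
  ry <- scenario$r_withinpair_y
  beta <- scenario$beta_causal
  mode <- scenario$causal_mode

  base_x <- pair_correlated_noise(np, zyg, rx)
  base_y <- pair_correlated_noise(np, zyg, ry)
  truth_latent <- NULL

  if (mode == "null") {
    x <- base_x; y <- base_y
  } else if (mode == "x_causes_y") {
    x <- base_x
    y <- beta * x + sqrt(1 - beta^2) * base_y
  } else if (mode == "y_causes_x") {
    y <- base_y
    x <- beta * y + sqrt(1 - beta^2) * base_x
  } else if (mode == "familial_confounding") {
    vf <- scenario$var_familial
    conf <- pair_correlated_noise(np, zyg, 1)  # fully pair-shared for MZ
    ex <- pair_correlated_noise(np, zyg, if (vf < rx) (rx - vf) / (1 - vf) else 0)
    ey <- pair_correlated_noise(np, zyg, if (vf < ry) (ry - vf) / (1 - vf) else 0)
    x <- sqrt(vf) * conf + sqrt(1 - vf) * ex
    y <- sqrt(vf) * conf + sqrt(1 - vf) * ey
    truth_latent <- list(familial_confounder = conf)
  } else { # within_individual_confounding
    vw <- scenario$var_within_conf
    u <- matrix(stats::rnorm(2 * np), np, 2)
    x <- sqrt(vw) * u + sqrt(1 - vw) * base_x
    y <- sqrt(vw) * u + sqrt(1 - vw) * base_y
    truth_latent <- list(within_confounder = u)
  }

  age <- round(stats::runif(np, 23, 70), 1)
  sex <- stats::rbinom(np, 1, 0.59)           # 1 = female, shared within pair
  smoking <- matrix(sample(c("never", "former", "current"), 2 * np,
                           replace = TRUE, prob = c(0.393, 0.306, 0.301)),
                    np, 2)

  ce <- scenario$covariate_effects
  if (!is.null(ce)) {
    zage <- (age - mean(age)) / stats::sd(age)
    zsex <- (sex - mean(sex)) / max(stats::sd(sex), 1e-12)
    smk_num <- matrix(match(smoking, c("never", "former", "current")) - 1,
                      np, 2) / 2
    zsmk <- (smk_num - mean(smk_num)) / max(stats::sd(c(smk_num)), 1e-12)
    add_cov <- function(tr, eff) {
      full <- c(age = 0, sex = 0, smoking = 0)
      full[intersect(names(eff), names(full))] <-
        eff[intersect(names(eff), names(full))]
      lin <- full[["age"]] * zage + full[["sex"]] * zsex  # pair-shared
      tr <- tr + lin + full[["smoking"]] * zsmk
      tr / sqrt(1 + sum(full^2))
    }
    if (!is.null(ce$x)) x <- add_cov(x, ce$x)
    if (!is.null(ce$y)) y <- add_cov(y, ce$y)
  }

  pair_id <- sprintf("P%05d", seq_len(np))
  cohort <- data.frame(
    individual_id = paste0(rep(pair_id, each = 2), "_", rep(1:2, np)),
    pair_id = rep(pair_id, each = 2),
    zygosity = rep(zyg, each = 2),
    twin_order = rep(1:2, np),
    age = rep(age, each = 2),
    sex = rep(sex, each = 2),
    smoking = as.vector(t(smoking)),
    x = as.vector(t(x)),
    y = as.vector(t(y)),
    stringsAsFactors = FALSE
  )
  attr(cohort, "truth") <- c(list(scenario = scenario), truth_latent)
  cohort
}

#' Simulate a CpG x sample methylation M-value matrix
#'
#' Null CpGs are pure pair-correlated noise; `n_causal` CpGs additionally gain
#' `effect * sd_j` M-value units per standard deviation of the driver trait,
#' where `sd_j` is that CpG's residual SD. Residual SDs are drawn from a
#' right-skewed scaled inverse-chi-square distribution (prior df `var_d0`,
#' prior scale `var_s0`) so empirical-Bayes variance moderation is exercised.
#'
#' @param cohort A twin cohort table (from [simulate_twin_cohort()]).
#' @param driver_trait Name of the cohort column driving the causal CpGs.
#' @param n_cpgs,n_causal CpG counts, `n_causal <= n_cpgs`.
#' @param effect Causal effect size in units of each CpG's residual SD.
#' @param seed Integer seed.
#' @param rho_pair Within-MZ-pair correlation of the CpG noise (DZ: half).
#' @param var_d0,var_s0 Hyperparameters of the residual-SD distribution.
#' @return A list with `m` (matrix, CpGs x samples, dimnames set) and `truth`
#'   (data.frame: `cpg_id`, `causal`, `effect`, `sd`, plus `rho_pair`
#'   attribute).
#' @export
simulate_methylation_matrix <- function(cohort, driver_trait = "x",
                                        n_cpgs = 2000L, n_causal = 10L,
                                        effect = 0.5, seed = 1L,
                                        rho_pair = 0.5,
                                        var_d0 = 4, var_s0 = 0.5) {
  stopifnot(driver_trait %in% names(cohort), n_causal <= n_cpgs,
            nrow(cohort) > 0)
  set.seed(sub_seed(seed, "methylation"))
  n <- nrow(cohort)
  pair <- match(cohort$pair_id, unique(cohort$pair_id))
  np <- max(pair)
  zyg <- cohort$zygosity[!duplicated(cohort$pair_id)]
  driver <- cohort[[driver_trait]]
  driver <- (driver - mean(driver)) / stats::sd(driver)

  sds <- sqrt(var_s0^2 * var_d0 / stats::rchisq(n_cpgs, df = var_d0))

  fac <- matrix(stats::rnorm(n_cpgs * np), n_cpgs, np)
  ## DZ pairs share only half of the pair factor (additive-genetic halving)
  fmat <- fac[, pair, drop = FALSE]
  dzcol <- zyg[pair] == "DZ"
  if (any(dzcol)) {
    ## give DZ individuals a half-shared factor
    ind_f <- matrix(stats::rnorm(n_cpgs * sum(dzcol)), n_cpgs, sum(dzcol))
    fmat[, dzcol] <- sqrt(0.5) * fmat[, dzcol] + sqrt(0.5) * ind_f
  }
  emat <- matrix(stats::rnorm(n_cpgs * n), n_cpgs, n)
  m <- sqrt(rho_pair) * fmat + sqrt(1 - rho_pair) * emat
  m <- m * sds

  causal <- rep(FALSE, n_cpgs)
  eff <- rep(0, n_cpgs)
  if (n_causal > 0) {
    idx <- sample.int(n_cpgs, n_causal)
    causal[idx] <- TRUE
    eff[idx] <- effect * sds[idx]
    m[idx, ] <- m[idx, ] + eff[idx] %o% driver
  }
  cpg_id <- sprintf("cg%08d", seq_len(n_cpgs))
  dimnames(m) <- list(cpg_id, cohort$individual_id)
  truth <- data.frame(cpg_id = cpg_id, causal = causal, effect = eff,
                      sd = sds, stringsAsFactors = FALSE)
  attr(truth, "rho_pair") <- rho_pair
  list(m = m, truth = truth)
}

#' Simulate a qPCR plate for mtDNA quantification
#'
#' Target genes (`ND5`, `CYTB`) report the mitochondrial copy number per cell,
#' reference genes (`APP`, `B2M`) the genomic DNA input, through the log2 link
#' `Ct = baseline - log2(quantity) + noise`. Doubling a sample's true quantity
#' therefore lowers its target Ct by exactly one cycle at zero noise.
#' Missingness (poor amplification) removes one randomly chosen target gene
#' from a `missing_rate` fraction of samples.
#'
#' @param cohort Twin cohort table (supplies sample ids).
#' @param true_quantity Positive per-sample mtDNA quantity (relative scale).
#' @param missing_rate Probability that a sample loses one target gene.
#' @param seed Integer seed.
#' @param noise_sd SD of the Ct measurement noise, in cycles.
#' @param baselines Named baseline Ct per gene at unit quantity.
#' @param genomic_sd SD of the per-sample log2 genomic DNA input.
#' @return Long-format data.frame: `sample_id`, `gene`, `ct` (NA when missing).
#' @export
simulate_qpcr_plate <- function(cohort, true_quantity, missing_rate = 0,
                                seed = 1L, noise_sd = 0.15,
                                baselines = c(ND5 = 15, CYTB = 16,
                                              APP = 24, B2M = 25),
                                genomic_sd = 0.1) {
  n <- nrow(cohort)
  stopifnot(length(true_quantity) == n, missing_rate >= 0, missing_rate < 1)
  if (any(true_quantity <= 0)) stop("true quantities must be positive")
  set.seed(sub_seed(seed, "qpcr"))
  genomic <- 2^stats::rnorm(n, 0, genomic_sd)
  genes <- c("ND5", "CYTB", "APP", "B2M")
  qty <- cbind(ND5 = true_quantity * genomic, CYTB = true_quantity * genomic,
               APP = genomic, B2M = genomic)
  ct <- sweep(-log2(qty), 2, baselines[genes], "+") +
    matrix(stats::rnorm(n * 4, 0, noise_sd), n, 4)
  miss <- stats::runif(n) < missing_rate
  if (any(miss)) {
    gone <- sample(c("ND5", "CYTB"), sum(miss), replace = TRUE)
    ct[cbind(which(miss), match(gone, genes))] <- NA_real_
  }
  data.frame(sample_id = rep(cohort$individual_id, times = 4),
             gene = rep(genes, each = n),
             ct = as.vector(ct),
             stringsAsFactors = FALSE)
}
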