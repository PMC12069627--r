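## icefalcon: Inference about Causation from Examination of FAmilial
## CONfounding. Three regressions on twin-pair data,
##
##   Model 1:  Y_self ~ X_self
##   Model 2:  Y_self ~ X_cotwin
##   Model 3:  Y_self ~ X_self + X_cotwin
##
## each clustered on pair with an exchangeable GEE and always including the
## covariates. Causal vs confounding patterns are read from how the self and
## cross-twin cross-trait coefficients change under mutual adjustment, with
## pair-bootstrap standard errors for the changes. Each twin serves once as
## "self" (doubled-pair layout), which is symmetric under twin relabeling.

#' Build the paired (doubled) dataset for ICE FALCON
#'
#' Keeps complete pairs only (both members non-missing on `x`, `y` and the
#' covariates), emits two rows per pair — each twin once as "self", with the
#' co-twin's exposure alongside — and standardizes `x` and `y` over the
#' analysis sample.
#'
#' @param cohort Twin cohort table (one row per individual, `pair_id`,
#'   `zygosity` columns).
#' @param x,y Exposure and outcome column names.
#' @param covariates Covariate column names carried through to the models.
#' @param mz_only Restrict to MZ pairs (the primary analysis); `FALSE` adds
#'   DZ pairs.
#' @return Data.frame of class `paired_dataset` with columns `pair_id`,
#'   `zygosity`, `y_self`, `x_self`, `x_cotwin` and the covariates;
#'   `attr(, "n_pairs")` records the pair count.
#' @export
build_paired_dataset <- function(cohort, x, y, covariates = character(),
                                 mz_only = TRUE) {
  need <- c(x, y, covariates)
  stopifnot(all(c(need, "pair_id", "zygosity") %in% names(cohort)))
  d <- cohort
  if (mz_only) d <- d[d$zygosity == "MZ", , drop = FALSE]
  d <- d[stats::complete.cases(d[, need, drop = FALSE]), , drop = FALSE]
  cnt <- table(d$pair_id)
  keep <- names(cnt)[cnt == 2]
  d <- d[d$pair_id %in% keep, , drop = FALSE]
  n_pairs <- length(keep)
  if (n_pairs < 5) stop("fewer than 5 complete pairs; analysis uninformative")
  d <- d[order(d$pair_id), , drop = FALSE]
  i1 <- seq(1, nrow(d), by = 2)
  i2 <- i1 + 1
  self <- c(rbind(i1, i2))
  cotwin <- c(rbind(i2, i1))
  out <- data.frame(pair_id = d$pair_id[self],
                    zygosity = d$zygosity[self],
                    y_self = d[[y]][self],
                    x_self = d[[x]][self],
                    x_cotwin = d[[x]][cotwin],
                    stringsAsFactors = FALSE)
  for (cv in covariates) out[[cv]] <- d[[cv]][self]
  ## x_self and x_cotwin hold the same multiset of values, so one scaling
  ## standardizes both columns coherently.
  mx <- mean(out$x_self); sx <- stats::sd(out$x_self)
  my <- mean(out$y_self); sy <- stats::sd(out$y_self)
  if (sx == 0 || sy == 0) stop("x or y has zero variance in the paired sample")
  out$x_self <- (out$x_self - mx) / sx
  out$x_cotwin <- (out$x_cotwin - mx) / sx
  out$y_self <- (out$y_self - my) / sy
  attr(out, "n_pairs") <- n_pairs
  attr(out, "x") <- x
  attr(out, "y") <- y
  attr(out, "covariates") <- covariates
  class(out) <- c("paired_dataset", "data.frame")
  out
}

## Internal: design matrices shared by Models 1-3 and the bootstrap.
paired_design <- function(pd) {
  covariates <- attr(pd, "covariates")
  C <- if (length(covariates) > 0) {
    stats::model.matrix(stats::reformulate(covariates), data = pd)[, -1,
                                                                   drop = FALSE]
  } else {
    matrix(numeric(0), nrow(pd), 0)
  }
  list(y = pd$y_self,
       intercept = matrix(1, nrow(pd), 1, dimnames = list(NULL, "(Intercept)")),
       xs = matrix(pd$x_self, dimnames = list(NULL, "x_self")),
       xc = matrix(pd$x_cotwin, dimnames = list(NULL, "x_cotwin")),
       C = C,
       cluster = match(pd$pair_id, unique(pd$pair_id)))
}

## Internal: fit Models 1-3 on (possibly resampled) row indices. The mean
## coefficients are estimated under the independence working correlation by
## default (alpha fixed at 0): with an estimated exchangeable alpha the
## weighted estimator is inconsistent for the marginal cross-twin estimand
## whenever the mean model omits the co-twin's exposure (the full-covariate
## conditional-mean condition fails for Model 2), which would distort the
## coefficient patterns the procedure interprets. The sandwich covariance is
## pair-clustered either way.
fit_three <- function(des, idx = NULL, cluster = NULL,
                      working = c("independence", "exchangeable")) {
  working <- match.arg(working)
  alpha <- if (working == "independence") 0 else NULL
  if (is.null(idx)) {
    y <- des$y; one <- des$intercept; xs <- des$xs; xc <- des$xc; C <- des$C
    cl <- des$cluster
  } else {
    y <- des$y[idx]; one <- des$intercept[idx, , drop = FALSE]
    xs <- des$xs[idx, , drop = FALSE]; xc <- des$xc[idx, , drop = FALSE]
    C <- des$C[idx, , drop = FALSE]
    cl <- cluster
  }
  m1 <- gee_core_fit(y, cbind(one, xs, C), cl, alpha = alpha)
  m2 <- gee_core_fit(y, cbind(one, xc, C), cl, alpha = alpha)
  m3 <- gee_core_fit(y, cbind(one, xs, xc, C), cl, alpha = alpha)
  list(m1 = m1, m2 = m2, m3 = m3)
}

gee_term <- function(fit, term) {
  est <- fit$coefficients[[term]]
  se <- fit$se[[term]]
  z <- est / se
  c(est = est, se = se, p = 2 * stats::pnorm(-abs(z)))
}

#' Fit ICE FALCON Models 1-3
#'
#' Three GEE fits clustered on pair, on the shared complete-case paired
#' sample, with standardized coefficients (the paired dataset is
#' standardized at construction) and robust (pair-clustered sandwich)
#' z-tests. Coefficients are estimated under the independence working
#' correlation by default: when the mean model omits the co-twin's exposure
#' (Models 1 and 2), a weighted exchangeable fit no longer targets the
#' marginal coefficients whose attenuation pattern ICE FALCON reads, so the
#' unweighted estimating equations are the faithful choice;
#' `working = "exchangeable"` re-enables the weighted fit.
#'
#' @param pd A [build_paired_dataset()] result.
#' @param working Working correlation for coefficient estimation.
#' @return Object of class `icefalcon_models`: per model, the `beta_self`
#'   and/or `beta_cotwin` rows `(est, se, p)`; plus `n_pairs` and the
#'   covariate set used.
#' @export
fit_models123 <- function(pd, working = c("independence", "exchangeable")) {
  stopifnot(inherits(pd, "paired_dataset"))
  working <- match.arg(working)
  des <- paired_design(pd)
  f <- fit_three(des, working = working)
  out <- list(
    m1 = list(beta_self = gee_term(f$m1, "x_self")),
    m2 = list(beta_cotwin = gee_term(f$m2, "x_cotwin")),
    m3 = list(beta_self = gee_term(f$m3, "x_self"),
              beta_cotwin = gee_term(f$m3, "x_cotwin")),
    n_pairs = attr(pd, "n_pairs"),
    covariates = attr(pd, "covariates"),
    x = attr(pd, "x"), y = attr(pd, "y"), working = working,
    alpha_working = c(m1 = f$m1$alpha, m2 = f$m2$alpha, m3 = f$m3$alpha)
  )
  class(out) <- "icefalcon_models"
  out
}

#' @export
print.icefalcon_models <- function(x, ...) {
  cat("ICE FALCON models:", x$y, "(Y) ~", x$x, "(X),", x$n_pairs, "pairs\n")
  fmt <- function(v) sprintf("%+.3f (SE %.3f, p %.3g)", v["est"], v["se"],
                             v["p"])
  cat("  Model 1 beta_self  :", fmt(x$m1$beta_self), "\n")
  cat("  Model 2 beta_cotwin:", fmt(x$m2$beta_cotwin), "\n")
  cat("  Model 3 beta_self  :", fmt(x$m3$beta_self), "\n")
  cat("  Model 3 beta_cotwin:", fmt(x$m3$beta_cotwin), "\n")
  invisible(x)
}

#' Coefficient changes with pair-bootstrap standard errors
#'
#' The causal signal in ICE FALCON is the change
#' `delta beta_self = beta_self(M3) - beta_self(M1)` and
#' `delta beta_cotwin = beta_cotwin(M3) - beta_cotwin(M2)`. Their standard
#' errors come from a non-parametric bootstrap that resamples pairs (never
#' individuals) with replacement to the original number of pairs, stratified
#' by zygosity when both MZ and DZ pairs are present; p-values are two-sided
#' normal tails of change / bootstrap SE. Replicates whose fits fail are
#' skipped; more than 10% failures is an error.
#'
#' @param pd A [build_paired_dataset()] result.
#' @param models The [fit_models123()] fit on `pd`.
#' @param n_boot Number of bootstrap replicates (1000 for inference;
#'   smaller values are allowed for quick checks).
#' @param seed Integer seed; fixed seed gives identical SEs.
#' @return Object of class `coefficient_change` with elements `delta_self`,
#'   `delta_cotwin` (each `est`, `se`, `p`), `n_boot`, `seed`.
#' @export
coefficient_changes <- function(pd, models, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(pd, "paired_dataset"), inherits(models,
                                                     "icefalcon_models"))
  working <- if (is.null(models$working)) "independence" else models$working
  des <- paired_design(pd)
  n_pairs <- attr(pd, "n_pairs")
  pair_first <- seq(1, nrow(pd), by = 2)
  zyg <- pd$zygosity[pair_first]
  strata <- split(seq_len(n_pairs), zyg)

  obs_self <- models$m3$beta_self[["est"]] - models$m1$beta_self[["est"]]
  obs_cot <- models$m3$beta_cotwin[["est"]] - models$m2$beta_cotwin[["est"]]

  set.seed(sub_seed(seed, "boot"))
  d_self <- d_cot <- rep(NA_real_, n_boot)
  cl <- rep(seq_len(n_pairs), each = 2)
  for (b in seq_len(n_boot)) {
    pick <- unlist(lapply(strata, function(s)
      s[sample.int(length(s), length(s), replace = TRUE)]), use.names = FALSE)
    idx <- rep(pair_first[pick], each = 2) + c(0L, 1L)
    fb <- tryCatch(fit_three(des, idx, cl, working = working),
                   error = function(e) NULL)
    if (is.null(fb)) next
    d_self[b] <- fb$m3$coefficients[["x_self"]] -
      fb$m1$coefficients[["x_self"]]
    d_cot[b] <- fb$m3$coefficients[["x_cotwin"]] -
      fb$m2$coefficients[["x_cotwin"]]
  }
  fail <- mean(is.na(d_self))
  if (fail > 0.10) stop("more than 10% of bootstrap replicates failed")
  se_self <- stats::sd(d_self, na.rm = TRUE)
  se_cot <- stats::sd(d_cot, na.rm = TRUE)
  out <- list(
    delta_self = c(est = obs_self, se = se_self,
                   p = 2 * stats::pnorm(-abs(obs_self / se_self))),
    delta_cotwin = c(est = obs_cot, se = se_cot,
                     p = 2 * stats::pnorm(-abs(obs_cot / se_cot))),
    n_boot = as.integer(n_boot), seed = as.integer(seed),
    prop_failed = fail,
    replicates = data.frame(delta_self = d_self, delta_cotwin = d_cot)
  )
  class(out) <- "coefficient_change"
  out
}

#' Percentile confidence interval for a bootstrap coefficient change
#'
#' Alternative to the normal-approximation p-value: empirical quantiles of
#' the stored bootstrap replicates.
#'
#' @param changes A [coefficient_changes()] result with its `replicates`.
#' @param which `"delta_self"` or `"delta_cotwin"`.
#' @param level Confidence level.
#' @return Named vector `c(lo =, hi =)`.
#' @export
change_percentile_ci <- function(changes, which = c("delta_cotwin",
                                                    "delta_self"),
                                 level = 0.95) {
  stopifnot(inherits(changes, "coefficient_change"))
  which <- match.arg(which)
  reps <- changes$replicates[[which]]
  if (is.null(reps)) stop("replicates were not retained on this object")
  q <- stats::quantile(reps, probs = c((1 - level) / 2, (1 + level) / 2),
                       na.rm = TRUE, names = FALSE)
  c(lo = q[1], hi = q[2])
}

#' Classify the ICE FALCON evidence pattern
#'
#' Applies an ordered, explicit rule set to the forward-direction models and
#' coefficient changes (the reverse direction, when supplied, is noted in the
#' trace). All thresholds are configurable; every comparison made is recorded
#' in the rule trace.
#'
#' Rules, in order:
#' \enumerate{
#'   \item `no_association` — beta_self(M1) not significant at `alpha`.
#'   \item `evidence_x_causes_y` — beta_cotwin(M2) significant at
#'     `alpha_marginal` and attenuated toward null in M3 (smaller magnitude,
#'     sign preserved or M3 non-significant, and either M3 non-significant or
#'     > `atten_frac` of the magnitude lost), with beta_self approximately
#'     stable (change p > 0.05 and relative change < `stable_rel`).
#'   \item `evidence_y_causes_x` — beta_cotwin(M2) significant and its
#'     magnitude grows, or its sign flips to a significant M3 value, with a
#'     significant change: the cross-twin association strengthens only upon
#'     conditioning.
#'   \item `familial_confounding` — both beta_self and beta_cotwin attenuate
#'     (self change significant with at least `self_atten_min` relative
#'     attenuation; cotwin magnitude reduced with sign preserved or M3
#'     non-significant).
#'   \item `within_individual_confounding_possible` — a cross-twin
#'     coefficient appears in M3 without a marginal M2 association, or the
#'     M2/M3 cross-twin coefficients are both significant with opposite
#'     signs.
#'   \item `inconclusive` otherwise.
#' }
#'
#' @param forward List with elements `models` ([fit_models123()]) and
#'   `changes` ([coefficient_changes()]).
#' @param reverse Optional same-shaped list for the reversed direction;
#'   `NULL` flags the result as reduced certainty.
#' @param alpha Significance gate for model coefficients.
#' @param alpha_marginal Gate for marginal evidence (the cross-twin Model-2
#'   coefficient and change tests).
#' @param stable_rel Maximum relative beta_self change still called stable.
#' @param atten_frac Minimum fraction of the cross-twin magnitude that must
#'   vanish for "attenuated toward null" when M3 stays significant.
#' @param self_atten_min Minimum relative beta_self attenuation for the
#'   familial-confounding rule.
#' @return List with `label`, `trace` (character), `reduced_certainty`.
#' @export
classify_causal_pattern <- function(forward, reverse = NULL,
                                    alpha = 0.05, alpha_marginal = 0.10,
                                    stable_rel = 0.25, atten_frac = 0.5,
                                    self_atten_min = 0.10) {
  mo <- forward$models
  ch <- forward$changes
  bs1 <- mo$m1$beta_self[["est"]]; ps1 <- mo$m1$beta_self[["p"]]
  bc2 <- mo$m2$beta_cotwin[["est"]]; pc2 <- mo$m2$beta_cotwin[["p"]]
  bs3 <- mo$m3$beta_self[["est"]]; ps3 <- mo$m3$beta_self[["p"]]
  bc3 <- mo$m3$beta_cotwin[["est"]]; pc3 <- mo$m3$beta_cotwin[["p"]]
  dsp <- ch$delta_self[["p"]]; ds <- ch$delta_self[["est"]]
  dcp <- ch$delta_cotwin[["p"]]; dc <- ch$delta_cotwin[["est"]]

  trace <- character(0)
  note <- function(...) trace <<- c(trace, sprintf(...))

  note("beta_self(M1) = %.3f, p = %.3g (gate alpha = %.2f)", bs1, ps1, alpha)
  label <- NULL
  if (ps1 >= alpha) {
    label <- "no_association"
    note("M1 self association not significant -> no_association")
  }

  cotwin_m2_sig <- pc2 < alpha_marginal
  note("beta_cotwin(M2) = %.3f, p = %.3g; significant at %.2f: %s",
       bc2, pc2, alpha_marginal, cotwin_m2_sig)
  atten <- abs(bc3) < abs(bc2)
  same_sign_or_ns <- (sign(bc3) == sign(bc2)) || pc3 >= alpha
  toward_null <- pc3 >= alpha ||
    (abs(bc2) > 0 && 1 - abs(bc3) / abs(bc2) > atten_frac)
  self_stable <- dsp >= 0.05 && abs(ds) < stable_rel * abs(bs1)
  note("beta_cotwin(M3) = %.3f, p = %.3g; attenuated: %s; toward null: %s",
       bc3, pc3, atten, toward_null)
  note("beta_self change = %.3f, p = %.3g; self stable: %s", ds, dsp,
       self_stable)

  if (is.null(label) && cotwin_m2_sig && atten && same_sign_or_ns &&
      toward_null && self_stable) {
    label <- "evidence_x_causes_y"
    note("cross-twin association attenuates toward null with stable self -> evidence_x_causes_y")
  }
  if (is.null(label) && cotwin_m2_sig && dcp < alpha_marginal &&
      (abs(bc3) > abs(bc2) || (sign(bc3) != sign(bc2) && pc3 < alpha))) {
    label <- "evidence_y_causes_x"
    note("cross-twin association strengthens/flips upon conditioning (change p = %.3g) -> evidence_y_causes_x",
         dcp)
  }
  self_atten <- dsp < alpha_marginal && abs(bs3) < abs(bs1) &&
    (abs(bs1) > 0 && 1 - abs(bs3) / abs(bs1) >= self_atten_min)
  if (is.null(label) && cotwin_m2_sig && self_atten && atten &&
      same_sign_or_ns) {
    label <- "familial_confounding"
    note("both self and cross-twin coefficients attenuate -> familial_confounding")
  }
  if (is.null(label) &&
      ((pc2 >= alpha_marginal && pc3 < alpha) ||
       (pc2 < alpha_marginal && pc3 < alpha && sign(bc3) != sign(bc2)))) {
    label <- "within_individual_confounding_possible"
    note("cross-twin coefficient appears/flips without clean causal pattern -> within_individual_confounding_possible")
  }
  if (is.null(label)) {
    label <- "inconclusive"
    note("no rule fired cleanly -> inconclusive")
  }
  if (!is.null(reverse)) {
    rmo <- reverse$models
    note("reverse direction: beta_self(M1) = %.3f (p = %.3g), beta_cotwin(M2) = %.3f (p = %.3g), beta_cotwin(M3) = %.3f (p = %.3g)",
         rmo$m1$beta_self[["est"]], rmo$m1$beta_self[["p"]],
         rmo$m2$beta_cotwin[["est"]], rmo$m2$beta_cotwin[["p"]],
         rmo$m3$beta_cotwin[["est"]], rmo$m3$beta_cotwin[["p"]])
  }
  list(label = label, trace = trace, reduced_certainty = is.null(reverse))
}

#' Run ICE FALCON in both directions
#'
#' Executes the full procedure for `y ~ x` (forward) and `x ~ y` (reverse)
#' with identical options, computes pair-bootstrap coefficient changes for
#' each, and classifies the evidence pattern (headline label from the
#' forward direction, reverse noted in the trace). The result is a plain
#' list, directly JSON-serializable.
#'
#' @inheritParams build_paired_dataset
#' @param n_boot Bootstrap replicates per direction.
#' @param seed Integer seed.
#' @param working Working correlation for coefficient estimation (see
#'   [fit_models123()]).
#' @param ... Threshold overrides passed to [classify_causal_pattern()].
#' @return Object of class `icefalcon_result`: `forward`, `reverse` (each
#'   with `models` and `changes`), `label`, `trace`, `n_pairs`.
#' @export
run_bidirectional <- function(cohort, x, y, covariates = character(),
                              mz_only = TRUE, n_boot = 1000L, seed = 1L,
                              working = c("independence", "exchangeable"),
                              ...) {
  working <- match.arg(working)
  run_dir <- function(xv, yv, tag) {
    pd <- build_paired_dataset(cohort, xv, yv, covariates, mz_only)
    mo <- fit_models123(pd, working = working)
    chg <- coefficient_changes(pd, mo, n_boot = n_boot,
                               seed = sub_seed(seed, tag))
    chg$replicates <- NULL  # keep the result light and serializable
    list(models = mo, changes = chg)
  }
  fwd <- run_dir(x, y, "forward")
  rev <- run_dir(y, x, "reverse")
  cls <- classify_causal_pattern(fwd, rev, ...)
  out <- list(forward = fwd, reverse = rev, label = cls$label,
              trace = cls$trace, n_pairs = fwd$models$n_pairs,
              x = x, y = y, n_boot = as.integer(n_boot),
              seed = as.integer(seed))
  class(out) <- "icefalcon_result"
  out
}

#' @export
print.icefalcon_result <- function(x, ...) {
  cat("ICE FALCON bidirectional analysis:", x$x, "<->", x$y, "\n")
  print(x$forward$models)
  print(x$reverse$models)
  cat("Pattern:", x$label, "\n")
  invisible(x)
}

#' Published ICE FALCON estimates for adipose mtDNAq and two CpG sites
#'
#' Reference point estimates, standard errors and p-values from a published
#' twin study (68 monozygotic pairs, adipose tissue) of mitochondrial DNA
#' quantity against methylation at cg19998400 (SH3BP4) and cg17468563
#' (DHRS3), in both regression directions, including the printed
#' coefficient-change entries. Used for worked-example arithmetic and
#' classification checks.
#'
#' @return Data.frame: `direction` (`"<outcome>~<predictor>"`), `coef`
#'   (`beta_self`/`beta_cotwin`), `model` (`m1`/`m2`/`m3`/`change`), `est`,
#'   `se`, `p`.
#' @export
published_icefalcon_estimates <- function() {
  rows <- rbind(
    ## mtDNAq (Y) ~ cg19998400 (X)
    c("mtdnaq~cg19998400", "beta_self",   "m1", -0.350, 0.061, 9.2e-09),
    c("mtdnaq~cg19998400", "beta_self",   "m3", -0.358, 0.060, 2.1e-09),
    c("mtdnaq~cg19998400", "beta_self",   "change", -0.008, NA, 0.728),
    c("mtdnaq~cg19998400", "beta_cotwin", "m2",  0.006, 0.070, 0.930),
    c("mtdnaq~cg19998400", "beta_cotwin", "m3", -0.067, 0.059, 0.257),
    c("mtdnaq~cg19998400", "beta_cotwin", "change", -0.073, NA, 0.426),
    ## cg19998400 (Y) ~ mtDNAq (X)
    c("cg19998400~mtdnaq", "beta_self",   "m1", -0.487, 0.098, 7.3e-07),
    c("cg19998400~mtdnaq", "beta_self",   "m3", -0.475, 0.102, 3.6e-06),
    c("cg19998400~mtdnaq", "beta_self",   "change", 0.013, NA, 0.643),
    c("cg19998400~mtdnaq", "beta_cotwin", "m2", -0.167, 0.081, 0.039),
    c("cg19998400~mtdnaq", "beta_cotwin", "m3", -0.055, 0.072, 0.444),
    c("cg19998400~mtdnaq", "beta_cotwin", "change", 0.112, NA, 0.351),
    ## mtDNAq (Y) ~ cg17468563 (X)
    c("mtdnaq~cg17468563", "beta_self",   "m1", -0.431, 0.092, 2.9e-06),
    c("mtdnaq~cg17468563", "beta_self",   "m3", -0.428, 0.092, 3.6e-06),
    c("mtdnaq~cg17468563", "beta_self",   "change", 0.003, NA, 0.942),
    c("mtdnaq~cg17468563", "beta_cotwin", "m2",  0.163, 0.080, 0.043),
    c("mtdnaq~cg17468563", "beta_cotwin", "m3",  0.143, 0.073, 0.051),
    c("mtdnaq~cg17468563", "beta_cotwin", "change", -0.020, NA, 0.788),
    ## cg17468563 (Y) ~ mtDNAq (X)
    c("cg17468563~mtdnaq", "beta_self",   "m1", -0.342, 0.082, 2.9e-05),
    c("cg17468563~mtdnaq", "beta_self",   "m3", -0.331, 0.082, 5.0e-05),
    c("cg17468563~mtdnaq", "beta_self",   "change", 0.011, NA, 0.664),
    c("cg17468563~mtdnaq", "beta_cotwin", "m2",  0.132, 0.078, 0.090),
    c("cg17468563~mtdnaq", "beta_cotwin", "m3",  0.050, 0.067, 0.460),
    c("cg17468563~mtdnaq", "beta_cotwin", "change", -0.082, NA, 0.289)
  )
  data.frame(direction = rows[, 1], coef = rows[, 2], model = rows[, 3],
             est = as.numeric(rows[, 4]), se = as.numeric(rows[, 5]),
             p = as.numeric(rows[, 6]), stringsAsFactors = FALSE)
}

#' Assemble forward-direction inputs for the classifier from printed values
#'
#' Builds the `models`/`changes` structures consumed by
#' [classify_causal_pattern()] from a table shaped like
#' [published_icefalcon_estimates()], so printed regression summaries can be
#' classified without refitting.
#'
#' @param tab A table in the [published_icefalcon_estimates()] layout.
#' @param direction Direction string to extract.
#' @return List with `models` and `changes` entries.
#' @export
icefalcon_from_estimates <- function(tab, direction) {
  pick <- function(coef, model) {
    r <- tab[tab$direction == direction & tab$coef == coef &
               tab$model == model, ]
    if (nrow(r) != 1) stop("missing entry: ", coef, " ", model)
    c(est = r$est, se = r$se, p = r$p)
  }
  models <- structure(list(
    m1 = list(beta_self = pick("beta_self", "m1")),
    m2 = list(beta_cotwin = pick("beta_cotwin", "m2")),
    m3 = list(beta_self = pick("beta_self", "m3"),
              beta_cotwin = pick("beta_cotwin", "m3"))
  ), class = "icefalcon_models")
  changes <- structure(list(
    delta_self = c(
      est = pick("beta_self", "m3")[["est"]] -
        pick("beta_self", "m1")[["est"]],
      se = NA_real_, p = pick("beta_self", "change")[["p"]]),
    delta_cotwin = c(
      est = pick("beta_cotwin", "m3")[["est"]] -
        pick("beta_cotwin", "m2")[["est"]],
      se = NA_real_, p = pick("beta_cotwin", "change")[["p"]])
  ), class = "coefficient_change")
  list(models = models, changes = changes)
}
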