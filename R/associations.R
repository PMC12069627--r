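## associations: trait batteries against methylation / mtDNAq outcomes with
## standardized GEE coefficients and per-outcome FDR, Pearson correlation of
## methylation with expression, and the marginal / conditional R-squared
## variance partition from a random-intercept-per-pair mixed model.

#' Specify one trait association
#'
#' @param trait Trait column name.
#' @param log10_transform Log10-transform the trait first (strictly positive
#'   traits only; skewed biomarkers such as triglycerides, hsCRP, insulin,
#'   HOMA-IR or liver fat).
#' @param covariates Adjustment columns (age, sex, smoking; plus chip/row
#'   terms for methylation outcomes).
#' @return Object of class `trait_spec`.
#' @export
trait_spec <- function(trait, log10_transform = FALSE,
                       covariates = c("age", "sex", "smoking")) {
  structure(list(trait = trait, log10_transform = log10_transform,
                 covariates = covariates),
            class = "trait_spec")
}

#' Standardized GEE association of one trait with one outcome
#'
#' Optionally log10-transforms the trait, standardizes outcome and trait over
#' the complete-case sample, and fits an exchangeable GEE clustered on pair.
#' The outcome is the modeled variable (CpG M-value or mtDNAq) and the trait
#' the predictor; the reported beta is the standardized coefficient with its
#' robust 95% CI.
#'
#' @param cohort Twin cohort table.
#' @param spec A [trait_spec()].
#' @param outcome Outcome column name.
#' @param cluster Pair id column.
#' @return One-row data.frame: `trait`, `outcome`, `beta`, `se`, `ci_lo`,
#'   `ci_hi`, `p`, `n`.
#' @export
trait_gee_association <- function(cohort, spec, outcome,
                                  cluster = "pair_id") {
  stopifnot(inherits(spec, "trait_spec"),
            all(c(spec$trait, outcome) %in% names(cohort)))
  d <- cohort
  if (spec$log10_transform) {
    v <- d[[spec$trait]]
    if (any(v <= 0, na.rm = TRUE))
      stop("log10 transform requested for non-positive trait '",
           spec$trait, "'")
    d[[spec$trait]] <- log10(v)
  }
  cc <- stats::complete.cases(
    d[, c(outcome, spec$trait, spec$covariates, cluster), drop = FALSE])
  if (sum(cc) < 10) stop("fewer than 10 complete cases")
  fit <- fit_gee_exchangeable(
    d[cc, , drop = FALSE],
    gee_spec(outcome, spec$trait, spec$covariates, cluster = cluster,
             standardize = TRUE))
  est <- fit$coefficients[[spec$trait]]
  se <- fit$se[[spec$trait]]
  data.frame(trait = spec$trait, outcome = outcome, beta = est, se = se,
             ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se,
             p = unname(wald_test(fit, spec$trait)["p"]), n = fit$n_obs,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Trait battery against two outcomes with per-outcome FDR
#'
#' Runs every trait spec against each outcome, applies Benjamini-Hochberg
#' FDR within each outcome family, and partitions the traits into the
#' three-way split significant-for-A-only / B-only / both at `q_cut`.
#' Per-spec failures are recorded and the batch continues.
#'
#' @param cohort Twin cohort table.
#' @param specs List of [trait_spec()] objects.
#' @param outcomes Character vector of outcome columns (typically the CpG
#'   M-value and mtDNAq).
#' @param q_cut FDR threshold for the partition.
#' @param cluster Pair id column.
#' @return List: `results` (tidy data.frame with `fdr_q`), `partition`
#'   (named list of trait vectors `only_<A>`, `only_<B>`, `both`),
#'   `failures` (named character of error messages).
#' @export
batch_associations_with_fdr <- function(cohort, specs, outcomes,
                                        q_cut = 0.05, cluster = "pair_id") {
  stopifnot(length(specs) >= 1, length(outcomes) == 2)
  rows <- list()
  failures <- character(0)
  for (sp in specs) {
    for (oc in outcomes) {
      r <- tryCatch(trait_gee_association(cohort, sp, oc, cluster = cluster),
                    error = function(e) e)
      if (inherits(r, "error")) {
        failures[paste(sp$trait, oc, sep = ":")] <- conditionMessage(r)
      } else {
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  res <- do.call(rbind, rows)
  res$fdr_q <- NA_real_
  for (oc in outcomes) {
    sel <- res$outcome == oc
    res$fdr_q[sel] <- bh_fdr(res$p[sel])
  }
  sig <- function(oc) res$trait[res$outcome == oc & res$fdr_q < q_cut]
  a <- sig(outcomes[1]); b <- sig(outcomes[2])
  partition <- list(setdiff(a, b), setdiff(b, a), intersect(a, b))
  names(partition) <- c(paste0("only_", outcomes[1]),
                        paste0("only_", outcomes[2]), "both")
  list(results = res, partition = partition, failures = failures)
}

#' Pearson correlation with a two-sided t-test
#'
#' Product-moment correlation between two numeric vectors (e.g. CpG
#' methylation and log2-CPM expression of its gene).
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @return Named vector `c(r =, p =, n =)`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("need at least 3 finite pairs")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop("zero variance input")
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  c(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Marginal and conditional R-squared from a pair random-intercept model
#'
#' Fits `outcome ~ predictor + covariates + (1 | pair)` by maximum
#' likelihood (REML optional) and partitions the outcome variance into the
#' fixed-effect share (variance of the fixed-effect predictions), the
#' pair-shared share (random-intercept variance) and the residual. Marginal
#' R-squared is the fixed share of the total; conditional R-squared adds the
#' pair share — the variance explained by the predictor alone versus
#' together with familial factors common to a twin pair. A boundary fit with
#' zero pair variance gives marginal = conditional.
#'
#' @param data Data.frame with the model columns.
#' @param outcome,predictor Column names.
#' @param pair_id Pair id column.
#' @param covariates Optional covariate columns.
#' @param reml Use REML instead of ML.
#' @return List of class `variance_explained`: `marginal`, `conditional`,
#'   `components` (named: fixed, pair, residual), `r_pearson`.
#' @export
variance_explained_lmm <- function(data, outcome, predictor,
                                   pair_id = "pair_id",
                                   covariates = character(), reml = FALSE) {
  cols <- c(outcome, predictor, covariates, pair_id)
  stopifnot(all(cols %in% names(data)))
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
            drop = FALSE]
  if (length(unique(d[[pair_id]])) < 10) stop("need at least 10 pairs")
  fml <- stats::as.formula(paste(
    outcome, "~", paste(c(predictor, covariates), collapse = " + "),
    "+ (1 |", pair_id, ")"))
  fit <- lme4::lmer(fml, data = d, REML = reml)
  vf <- stats::var(drop(lme4::getME(fit, "X") %*% lme4::fixef(fit)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vp <- vc$vcov[vc$grp == pair_id]
  vr <- vc$vcov[vc$grp == "Residual"]
  tot <- vf + vp + vr
  out <- list(marginal = vf / tot, conditional = (vf + vp) / tot,
              components = c(fixed = vf, pair = vp, residual = vr),
              r_pearson = unname(pearson_correlation(d[[outcome]],
                                                     d[[predictor]])["r"]),
              n_obs = nrow(d), n_pairs = length(unique(d[[pair_id]])))
  class(out) <- "variance_explained"
  out
}

#' @export
print.variance_explained <- function(x, ...) {
  cat(sprintf(
    "Variance partition: marginal R2 = %.3f, conditional R2 = %.3f (r = %.2f, %d obs)\n",
    x$marginal, x$conditional, x$r_pearson, x$n_obs))
  invisible(x)
}
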