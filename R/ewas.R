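## ewas: probe-wise association of a quantitative exposure with a CpG x
## sample M-value matrix, accounting for twin relatedness through a single
## consensus intra-pair correlation (GLS with block-exchangeable correlation,
## the established device for random pair effects at array scale), followed
## by empirical-Bayes variance moderation and Benjamini-Hochberg FDR.

#' Describe an EWAS design
#'
#' @param pheno Data.frame with one row per sample, aligned to the matrix
#'   columns via `sample_id`.
#' @param exposure Exposure column name (e.g. mtDNAq).
#' @param covariates Covariate column names (age, sex, smoking, technical
#'   terms, cell-type proportions as plain numeric columns).
#' @param block Pair id column for the twin random-effect structure.
#' @param sample_id Column holding the matrix column names.
#' @return Object of class `ewas_design`.
#' @export
ewas_design <- function(pheno, exposure, covariates = character(),
                        block = "pair_id", sample_id = "individual_id") {
  stopifnot(all(c(exposure, covariates, block, sample_id) %in% names(pheno)))
  structure(list(pheno = pheno, exposure = exposure, covariates = covariates,
                 block = block, sample_id = sample_id),
            class = "ewas_design")
}

## Build the model matrix, pair index and whitening indices for a design
## aligned to the matrix columns.
ewas_prepare <- function(m, design) {
  ph <- design$pheno
  idx <- match(colnames(m), ph[[design$sample_id]])
  if (anyNA(idx)) stop("matrix columns missing from the design table")
  ph <- ph[idx, , drop = FALSE]
  X <- stats::model.matrix(
    stats::reformulate(c(design$exposure, design$covariates)), data = ph)
  if (nrow(X) != ncol(m))
    stop("design rows with missing values; supply complete covariates")
  if (qr(X)$rank < ncol(X)) stop("design matrix not of full rank")
  pair <- match(ph[[design$block]], unique(ph[[design$block]]))
  tw <- stats::ave(pair, pair, FUN = seq_along)
  first <- which(tw == 1)
  second <- which(tw == 2)
  mate <- match(pair[second], pair[first])   # row in `first` for each second
  list(X = X, pair = pair, i1 = first[mate], i2 = second,
       exposure_col = 2L)  # intercept first, exposure second by construction
}

## Cholesky whitening of the pair-exchangeable correlation: the second member
## of each pair becomes (x2 - rho * x1) / sqrt(1 - rho^2); singletons and
## first members are untouched. Works on vectors or (samples x k) matrices.
whiten_pairs <- function(x, i1, i2, rho) {
  if (length(i2) == 0 || rho == 0) return(x)
  s <- sqrt(1 - rho^2)
  if (is.matrix(x)) {
    x[i2, ] <- (x[i2, , drop = FALSE] - rho * x[i1, , drop = FALSE]) / s
  } else {
    x[i2] <- (x[i2] - rho * x[i1]) / s
  }
  x
}

#' Consensus within-pair residual correlation
#'
#' For a random subsample of CpGs, profiles the Gaussian likelihood of the
#' probe-wise linear model over a common within-pair residual correlation on
#' a fixed grid, then returns the 15%-trimmed mean of the Fisher-z
#' transformed per-CpG maximizers, back-transformed. The result is the shared
#' correlation used by [fit_probe_models()] — the consensus device standing
#' in for a per-probe random pair intercept.
#'
#' @param m CpG x sample M-value matrix.
#' @param design An [ewas_design()].
#' @param subsample Number of CpGs profiled (capped at `nrow(m)`).
#' @param seed Integer seed for the CpG subsample.
#' @param grid Grid of candidate correlations.
#' @return Scalar rho in (-1, 1) with the per-CpG estimates as
#'   `attr(, "per_cpg")`.
#' @export
consensus_pair_correlation <- function(m, design, subsample = 200L, seed = 1L,
                                       grid = seq(-0.95, 0.95, by = 0.005)) {
  prep <- ewas_prepare(m, design)
  if (length(prep$i2) < 2) stop("need at least 2 complete pairs")
  set.seed(sub_seed(seed, "consensus"))
  take <- if (nrow(m) > subsample) sort(sample.int(nrow(m), subsample))
          else seq_len(nrow(m))
  Y <- t(m[take, , drop = FALSE])          # samples x cpgs
  n <- nrow(Y)
  n_pairs <- length(prep$i2)
  ll <- matrix(NA_real_, length(grid), ncol(Y))
  for (g in seq_along(grid)) {
    rho <- grid[g]
    Xw <- whiten_pairs(prep$X, prep$i1, prep$i2, rho)
    Yw <- whiten_pairs(Y, prep$i1, prep$i2, rho)
    rss <- colSums(stats::lm.fit(Xw, Yw)$residuals^2)
    ll[g, ] <- -0.5 * (n * log(rss / n) + n_pairs * log(1 - rho^2))
  }
  best <- grid[max.col(t(ll), ties.method = "first")]
  z <- atanh(pmin(pmax(best, -0.999), 0.999))
  rho_hat <- tanh(mean(z, trim = 0.15))
  attr(rho_hat, "per_cpg") <- best
  rho_hat
}

#' Probe-wise GLS fits under a shared intra-pair correlation
#'
#' Fits every CpG's linear model by generalized least squares under a
#' block-exchangeable correlation `rho` within pairs (singletons keep an
#' identity block); `rho = 0` reduces to probe-wise OLS. Implemented by
#' whitening the design and data once and solving all probes in a single
#' least-squares pass.
#'
#' @param m CpG x sample M-value matrix.
#' @param design An [ewas_design()].
#' @param rho Shared within-pair residual correlation (> -1, < 1).
#' @return Data.frame per CpG: `cpg_id`, `coef` (exposure), `se_unscaled`
#'   (SE per unit residual SD), `sigma` (residual SD), `df` (residual
#'   degrees of freedom).
#' @export
fit_probe_models <- function(m, design, rho = 0) {
  stopifnot(rho > -1, rho < 1)
  prep <- ewas_prepare(m, design)
  if (anyNA(m)) stop("matrix contains missing values")
  Xw <- whiten_pairs(prep$X, prep$i1, prep$i2, rho)
  Yw <- whiten_pairs(t(m), prep$i1, prep$i2, rho)
  fit <- stats::lm.fit(Xw, Yw)
  p <- ncol(prep$X)
  df <- nrow(Xw) - p
  rss <- colSums(fit$residuals^2)
  sigma <- sqrt(rss / df)
  XtXinv <- chol2inv(chol(crossprod(Xw)))
  j <- prep$exposure_col
  coefs <- if (is.matrix(fit$coefficients)) fit$coefficients[j, ]
           else fit$coefficients[j]
  data.frame(cpg_id = rownames(m), coef = unname(coefs),
             se_unscaled = sqrt(XtXinv[j, j]), sigma = sigma,
             df = df, row.names = NULL, stringsAsFactors = FALSE)
}

## Newton inversion of the trigamma function (solve trigamma(x) = y), used
## by the moment-matching estimate of the prior degrees of freedom.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Empirical-Bayes variance moderation and moderated t-statistics
#'
#' Residual variances are modeled as draws from a scaled inverse chi-square
#' prior with `d0` degrees of freedom and scale `s0^2`. The hyperparameters
#' are estimated by matching the first two moments of the log residual
#' variances to a scaled F distribution (digamma/trigamma inversion with
#' Newton iteration). The posterior variance
#' `s2_post = (d0 s0^2 + df s^2) / (d0 + df)` replaces each probe's `s^2` in
#' the t-statistic, which then has `df + d0` degrees of freedom. When the log
#' variances show no excess spread over the chi-square sampling noise, `d0`
#' is flagged infinite and all variances shrink completely to `s0^2`.
#'
#' @param fits Output of [fit_probe_models()].
#' @return Data.frame per CpG: `cpg_id`, `coef`, `sigma`, `df`, `t`
#'   (moderated), `p`, `fdr_q`; hyperparameters in attributes `d0`, `s02`.
#' @export
ebayes_moderate <- function(fits) {
  stopifnot(all(c("coef", "se_unscaled", "sigma", "df") %in% names(fits)))
  ok <- fits$df > 0 & fits$sigma > 0
  if (sum(ok) < 10) stop("need >= 10 probes with positive residual df")
  s2 <- fits$sigma[ok]^2
  df <- fits$df[ok]
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  evar <- stats::var(e) * (length(e) - 1) / length(e) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    ## no excess spread over chi-square sampling noise: point-mass prior,
    ## estimated by the plain mean of the variances
    d0 <- Inf
    s02 <- mean(s2)
  }
  s2_all <- fits$sigma^2
  s2_post <- if (is.finite(d0)) (d0 * s02 + fits$df * s2_all) / (d0 + fits$df)
             else rep(s02, nrow(fits))
  tmod <- fits$coef / (fits$se_unscaled * sqrt(s2_post))
  dftot <- fits$df + d0
  pval <- 2 * stats::pt(-abs(tmod), df = dftot)
  out <- data.frame(cpg_id = fits$cpg_id, coef = fits$coef,
                    sigma = fits$sigma, df = fits$df, s2_post = s2_post,
                    t = tmod, p = pval, fdr_q = bh_fdr(pval),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; `NA` p-values are
#' excluded from the adjustment and propagated as `NA`.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Vector of adjusted q-values.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) stop("p-values outside [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Run a full EWAS of an exposure on a methylation matrix
#'
#' Convenience pipeline: estimate the consensus intra-pair correlation,
#' refit every probe by GLS under it, moderate the variances, and adjust for
#' multiple testing. Volcano-plot coordinates (`coef`, `-log10(p)`) are
#' derivable directly from the returned table.
#'
#' @inheritParams consensus_pair_correlation
#' @return The [ebayes_moderate()] table sorted by p-value, with attributes
#'   `d0`, `s02` and `rho`.
#' @export
run_ewas <- function(m, design, subsample = 200L, seed = 1L) {
  rho <- consensus_pair_correlation(m, design, subsample = subsample,
                                    seed = seed)
  tab <- ebayes_moderate(fit_probe_models(m, design, rho = as.numeric(rho)))
  d0 <- attr(tab, "d0")
  s02 <- attr(tab, "s02")
  tab <- tab[order(tab$p), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "d0") <- d0
  attr(tab, "s02") <- s02
  attr(tab, "rho") <- as.numeric(rho)
  tab
}
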