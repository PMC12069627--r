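## gee_core: Gaussian-identity GEE with exchangeable working correlation and
## robust (sandwich) covariance, the shared regression engine for the
## cross-twin models and the trait-association batteries.
##
## For the exchangeable structure, R(alpha)^{-1} has the closed form
## (1/(1-alpha)) [ I - alpha/(1 + (m-1) alpha) J ] for a cluster of size m,
## which lets every estimating-equation quantity be assembled from per-cluster
## row sums (rowsum) without looping over clusters. The common 1/(1-alpha)
## factor cancels in both the coefficient solve and the sandwich, so it is
## dropped throughout.

## Core numeric fit on a prepared response / design / integer cluster id.
## alpha = NULL estimates the working correlation by moments; a numeric value
## holds it fixed (used by the GLS oracle comparisons).
gee_core_fit <- function(y, X, cluster, alpha = NULL,
                         max_iter = 25L, tol = 1e-8,
                         bias_correct = FALSE) {
  n <- length(y)
  p <- ncol(X)
  cl <- match(cluster, unique(cluster))
  m_cl <- tabulate(cl)                    # cluster sizes
  m <- m_cl[cl]                           # size of own cluster, per row
  maxm <- max(m_cl)
  n_pairs <- sum(m_cl * (m_cl - 1) / 2)   # within-cluster pair count
  est_alpha <- is.null(alpha)
  a <- if (est_alpha) 0 else alpha
  if (!est_alpha && maxm > 1 && (a <= -1 / (maxm - 1) || a >= 1))
    stop("alpha outside the admissible range for the largest cluster")

  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  S <- rowsum(X, cl, reorder = TRUE)      # per-cluster column sums
  Sy <- rowsum(y, cl, reorder = TRUE)

  qrX <- qr(XtX)
  if (qrX$rank < p) stop("design matrix is rank deficient on complete cases")

  beta <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    k <- a / (1 + (m_cl - 1) * a)
    A <- XtX - crossprod(S, S * k)
    b <- Xty - crossprod(S, Sy * k)
    beta_new <- solve(A, b)
    if (!is.null(beta) && max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
    if (est_alpha && n_pairs > 0) {
      r <- y - drop(X %*% beta)
      phi <- sum(r^2) / (n - p)
      Sr <- rowsum(r, cl, reorder = TRUE)
      Sr2 <- rowsum(r^2, cl, reorder = TRUE)
      cross <- sum((Sr^2 - Sr2) / 2)
      a_new <- (cross / phi) / max(n_pairs - p, 1)
      lo <- if (maxm > 1) -1 / (maxm - 1) + 1e-6 else -0.99
      a <- min(max(a_new, lo), 0.999)
    } else if (it >= 2L) {
      converged <- TRUE
      break
    }
  }
  beta <- drop(beta)

  ## sandwich covariance from cluster-level scores
  r <- y - drop(X %*% beta)
  k <- a / (1 + (m_cl - 1) * a)
  A <- XtX - crossprod(S, S * k)
  Sr <- rowsum(r, cl, reorder = TRUE)
  U <- rowsum(X * r, cl, reorder = TRUE) - S * drop(k * Sr)
  Ainv <- solve(A)
  meat <- crossprod(U)
  if (bias_correct) {
    g <- length(m_cl)
    meat <- meat * g / max(g - 1, 1)  # CR1-style small-sample inflation
  }
  V <- Ainv %*% meat %*% Ainv
  V <- (V + t(V)) / 2
  se <- sqrt(pmax(diag(V), 0))
  names(beta) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))
  names(se) <- colnames(X)
  list(coefficients = beta, vcov = V, se = se, alpha = a,
       n_clusters = length(m_cl), n_obs = n, converged = converged,
       residuals = r)
}

#' Specify an exchangeable-GEE regression
#'
#' @param outcome Outcome column name.
#' @param predictors Character vector of predictor column names (reported
#'   terms of interest).
#' @param covariates Character vector of adjustment columns (may be factors).
#' @param cluster Cluster id column (twin pair).
#' @param standardize Standardize outcome and predictors to mean 0 / SD 1
#'   over the analysis sample (standardized coefficients)?
#' @param max_iter,tol Convergence controls for the alternating
#'   coefficient / working-correlation updates.
#' @return An object of class `gee_spec`.
#' @export
gee_spec <- function(outcome, predictors, covariates = character(),
                     cluster = "pair_id", standardize = TRUE,
                     max_iter = 25L, tol = 1e-8) {
  stopifnot(tol > 0, !(outcome %in% predictors))
  structure(list(outcome = outcome, predictors = predictors,
                 covariates = covariates, cluster = cluster,
                 standardize = standardize, max_iter = as.integer(max_iter),
                 tol = tol),
            class = "gee_spec")
}

#' Fit a Gaussian GEE with exchangeable working correlation
#'
#' Iterates (i) the weighted estimating-equation solve given the working
#' correlation `alpha` and (ii) a moment re-estimate of `alpha` from
#' standardized residual cross-products within clusters (denominator: total
#' within-cluster pair count minus the number of regression parameters,
#' clamped into the admissible range), until the maximum coefficient change
#' drops below `tol`. Standard errors come from the cluster-robust sandwich
#' assembled from cluster-level score outer products; p-values are two-sided
#' z-tests. Rows with missing values in any model column are dropped
#' (complete-case analysis).
#'
#' @param data A data.frame (e.g. a twin cohort table).
#' @param spec A [gee_spec()].
#' @param alpha Optional fixed working correlation (skips moment estimation).
#' @param bias_correct Apply a CR1-style small-sample inflation
#'   `G / (G - 1)` to the sandwich meat (off by default; inference is
#'   z-based without small-sample correction).
#' @return An object of class `gee_fit`: coefficients, robust `se` and
#'   `vcov`, `alpha`, `n_clusters`, `n_obs`, `converged`, and a `tidy`
#'   data.frame of terms.
#' @export
fit_gee_exchangeable <- function(data, spec, alpha = NULL,
                                 bias_correct = FALSE) {
  stopifnot(inherits(spec, "gee_spec"))
  cols <- c(spec$outcome, spec$predictors, spec$covariates, spec$cluster)
  stopifnot(all(cols %in% names(data)))
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
            drop = FALSE]
  if (length(unique(d[[spec$cluster]])) < 2)
    stop("need at least 2 clusters")
  if (spec$standardize)
    d <- standardize(d, c(spec$outcome, spec$predictors))
  rhs <- c(spec$predictors, spec$covariates)
  X <- stats::model.matrix(
    stats::reformulate(rhs), data = d)
  y <- d[[spec$outcome]]
  fit <- gee_core_fit(y, X, d[[spec$cluster]], alpha = alpha,
                      max_iter = spec$max_iter, tol = spec$tol,
                      bias_correct = bias_correct)
  z <- fit$coefficients / fit$se
  pval <- 2 * stats::pnorm(-abs(z))
  fit$tidy <- data.frame(term = names(fit$coefficients),
                         estimate = unname(fit$coefficients),
                         se = unname(fit$se), z = unname(z),
                         p = unname(pval), row.names = NULL,
                         stringsAsFactors = FALSE)
  fit$spec <- spec
  class(fit) <- "gee_fit"
  fit
}

#' @export
print.gee_fit <- function(x, ...) {
  cat("Exchangeable GEE fit:", x$n_obs, "obs in", x$n_clusters,
      "clusters; alpha =", format(x$alpha, digits = 3),
      if (!x$converged) "(NOT converged)" else "", "\n")
  print(x$tidy, digits = 3)
  invisible(x)
}

#' Robust Wald z-test for one GEE term
#'
#' @param fit A `gee_fit`.
#' @param term Coefficient name.
#' @return Named vector `c(z =, p =)` with the two-sided normal-tail p-value.
#' @export
wald_test <- function(fit, term) {
  stopifnot(inherits(fit, "gee_fit"), term %in% names(fit$coefficients))
  se <- fit$se[[term]]
  if (se == 0) stop("zero robust standard error for term '", term, "'")
  z <- fit$coefficients[[term]] / se
  c(z = unname(z), p = unname(2 * stats::pnorm(-abs(z))))
}
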