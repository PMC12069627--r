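#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a global seed
#'
#' Expands one global integer seed into per-component sub-seeds so that
#' independent generators (cohort, methylation matrix, qPCR plate, bootstrap)
#' stay decoupled: changing one component's draws never perturbs another's.
#'
#' @param seed Integer global seed.
#' @param tag Character tag naming the component.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
sub_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  # small deterministic string hash (polynomial rolling, 31-bit)
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483647)
}

geo_mean <- function(x, na.rm = TRUE) {
  exp(mean(log(x), na.rm = na.rm))
}

#' Standardize columns of a table to mean 0, SD 1
#'
#' Centering and scaling use the sample mean and sample standard deviation of
#' the non-missing rows, matching the standardized-coefficient convention of
#' the regression modules.
#'
#' @param data A data.frame.
#' @param columns Character vector of numeric column names.
#' @return `data` with the named columns replaced by their z-scores.
#' @export
standardize <- function(data, columns) {
  stopifnot(is.data.frame(data), all(columns %in% names(data)))
  for (cn in columns) {
    v <- data[[cn]]
    if (!is.numeric(v)) stop("column '", cn, "' is not numeric")
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) stop("column '", cn, "' has zero variance")
    data[[cn]] <- (v - mean(v, na.rm = TRUE)) / s
  }
  data
}

## Correlated pair noise: one standardized deviate per twin with within-pair
## correlation rho for MZ pairs and rho/2 for DZ pairs (additive-genetic
## halving). Returns an n_pairs x 2 matrix.
pair_correlated_noise <- function(n_pairs, zygosity, rho) {
  stopifnot(rho >= 0, rho <= 1, length(zygosity) == n_pairs)
  ## pair factor with twin-twin correlation 1 (MZ) or 1/2 (DZ)
  fp <- stats::rnorm(n_pairs)
  f1 <- fp
  f2 <- fp
  dz <- zygosity == "DZ"
  if (any(dz)) {
    nd <- sum(dz)
    f1[dz] <- sqrt(0.5) * fp[dz] + sqrt(0.5) * stats::rnorm(nd)
    f2[dz] <- sqrt(0.5) * fp[dz] + sqrt(0.5) * stats::rnorm(nd)
  }
  e <- matrix(stats::rnorm(2 * n_pairs), n_pairs, 2)
  cbind(sqrt(rho) * f1 + sqrt(1 - rho) * e[, 1],
        sqrt(rho) * f2 + sqrt(1 - rho) * e[, 2])
}
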