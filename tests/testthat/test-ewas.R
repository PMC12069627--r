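## Shared small fixture: 100 pairs, known exposure effect on a handful of
## CpGs, pair-correlated noise.
ewas_fixture <- function(n_pairs = 100, n_cpgs = 200, rho = 0.6, seed = 31) {
  co <- simulate_twin_cohort(sim_scenario(n_pairs, causal_mode = "null",
                                          seed = seed))
  sim <- simulate_methylation_matrix(co, "x", n_cpgs = n_cpgs, n_causal = 0,
                                     effect = 0, seed = seed,
                                     rho_pair = rho)
  list(cohort = co, m = sim$m,
       design = ewas_design(co, "x", covariates = c("age", "sex")))
}

test_that("consensus correlation recovers the generating pair correlation", {
  f0 <- ewas_fixture(rho = 0)
  rho0 <- consensus_pair_correlation(f0$m, f0$design, subsample = 200,
                                     seed = 1)
  expect_lt(abs(as.numeric(rho0)), 0.05)

  f6 <- ewas_fixture(rho = 0.6, seed = 32)
  rho6 <- consensus_pair_correlation(f6$m, f6$design, subsample = 200,
                                     seed = 1)
  expect_lt(abs(as.numeric(rho6) - 0.6), 0.05)
  expect_gt(as.numeric(rho6), -1)
  expect_lt(as.numeric(rho6), 1)

  ## determinism under the subsampling seed
  rho6b <- consensus_pair_correlation(f6$m, f6$design, subsample = 150,
                                      seed = 9)
  rho6c <- consensus_pair_correlation(f6$m, f6$design, subsample = 150,
                                      seed = 9)
  expect_identical(as.numeric(rho6b), as.numeric(rho6c))
})

test_that("probe fits at rho = 0 are ordinary least squares", {
  f <- ewas_fixture(n_pairs = 30, n_cpgs = 20, rho = 0.4, seed = 33)
  fits <- fit_probe_models(f$m, f$design, rho = 0)
  X <- model.matrix(~ x + age + sex, data = f$cohort)
  for (j in c(1, 7, 20)) {
    ols <- lm.fit(X, f$m[j, ])
    expect_equal(fits$coef[j], unname(ols$coefficients["x"]),
                 tolerance = 1e-10)
  }
})

test_that("probe fits equal a dense GLS solve under the pair correlation", {
  f <- ewas_fixture(n_pairs = 4, n_cpgs = 3, rho = 0.5, seed = 34)
  rho <- 0.5
  fits <- fit_probe_models(f$m, f$design, rho = rho)
  X <- model.matrix(~ x + age + sex, data = f$cohort)
  n <- nrow(f$cohort)
  V <- diag(n)
  for (p in unique(f$cohort$pair_id)) {
    idx <- which(f$cohort$pair_id == p)
    V[idx[1], idx[2]] <- V[idx[2], idx[1]] <- rho
  }
  Vi <- solve(V)
  for (j in seq_len(3)) {
    beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% f$m[j, ])
    expect_equal(fits$coef[j], unname(beta["x", 1]), tolerance = 1e-10)
  }
})

test_that("moderated variances interpolate between probe and prior variance", {
  f <- ewas_fixture(n_pairs = 50, n_cpgs = 300, seed = 35)
  tab <- ebayes_moderate(fit_probe_models(f$m, f$design, rho = 0))
  s02 <- attr(tab, "s02")
  lo <- pmin(tab$sigma^2, s02)
  hi <- pmax(tab$sigma^2, s02)
  expect_true(all(tab$s2_post >= lo - 1e-12 & tab$s2_post <= hi + 1e-12))
  expect_equal(nrow(tab), 300)
})

test_that("identical residual variances flag an infinite prior df", {
  fits <- data.frame(cpg_id = sprintf("cg%03d", 1:50),
                     coef = rnorm(50), se_unscaled = 0.1,
                     sigma = 0.7, df = 20)
  tab <- ebayes_moderate(fits)
  expect_true(is.infinite(attr(tab, "d0")))
  expect_equal(unique(tab$s2_post), 0.49, tolerance = 1e-10)
})

test_that("moderation agrees with the limma empirical-Bayes machinery", {
  skip_if_not_installed("limma")
  f <- ewas_fixture(n_pairs = 60, n_cpgs = 400, rho = 0.5, seed = 36)
  rho <- as.numeric(consensus_pair_correlation(f$m, f$design,
                                               subsample = 200, seed = 2))
  lrho <- limma::duplicateCorrelation(
    f$m, design = model.matrix(~ x + age + sex, f$cohort),
    block = f$cohort$pair_id)$consensus.correlation
  expect_lt(abs(rho - lrho), 0.05)

  fits <- fit_probe_models(f$m, f$design, rho = rho)
  tab <- ebayes_moderate(fits)
  lfit <- limma::lmFit(f$m, design = model.matrix(~ x + age + sex, f$cohort),
                       block = f$cohort$pair_id, correlation = rho)
  efit <- limma::eBayes(lfit)
  expect_equal(tab$coef, unname(lfit$coefficients[, "x"]), tolerance = 1e-8)
  expect_lt(abs(attr(tab, "d0") - efit$df.prior), 0.2)
  expect_lt(abs(attr(tab, "s02") - efit$s2.prior),
            0.05 * efit$s2.prior)
  expect_equal(tab$t, unname(efit$t[, "x"]), tolerance = 1e-3)
})

test_that("BH adjustment matches the closed forms and handles NAs", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(37)
  p <- runif(200)
  expect_equal(bh_fdr(p), bh_bruteforce(p), tolerance = 1e-12)
  withna <- c(0.01, NA, 0.5)
  q <- bh_fdr(withna)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_bruteforce(c(0.01, 0.5)))
  ## monotone nondecreasing in p-rank
  o <- order(p)
  expect_true(all(diff(bh_fdr(p)[o]) >= -1e-12))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("a permuted exposure yields null coefficients on average", {
  f <- ewas_fixture(n_pairs = 40, n_cpgs = 100, seed = 38)
  set.seed(39)
  means <- replicate(20, {
    co <- f$cohort
    co$x <- sample(co$x)
    d <- ewas_design(co, "x", covariates = c("age", "sex"))
    mean(fit_probe_models(f$m, d, rho = 0)$coef)
  })
  expect_lt(abs(mean(means)), 0.02)
})

test_that("the full EWAS ranks strong causal CpGs first", {
  co <- simulate_twin_cohort(sim_scenario(75, causal_mode = "null",
                                          seed = 40))
  sim <- simulate_methylation_matrix(co, "x", n_cpgs = 500, n_causal = 5,
                                     effect = 0.8, seed = 40)
  tab <- run_ewas(sim$m, ewas_design(co, "x",
                                     covariates = c("age", "sex", "smoking")),
                  seed = 3)
  causal <- sim$truth$cpg_id[sim$truth$causal]
  expect_true(all(tab$cpg_id[1:5] %in% causal))
  expect_equal(nrow(tab), 500)
  ## volcano coordinates derive exactly from the table
  expect_true(all(is.finite(-log10(tab$p))))
})
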