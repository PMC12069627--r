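## Cohort with named traits driven by known standardized effects.
trait_cohort <- function(n_pairs = 1000, seed = 51) {
  co <- simulate_twin_cohort(sim_scenario(n_pairs, causal_mode = "null",
                                          seed = seed))
  names(co)[names(co) == "x"] <- "mtdnaq_z"
  names(co)[names(co) == "y"] <- "cpg_m"
  co
}

test_that("a trait identical to the outcome has standardized beta 1", {
  co <- trait_cohort(200)
  co$self_trait <- co$cpg_m
  r <- trait_gee_association(co, trait_spec("self_trait",
                                            covariates = character()),
                             "cpg_m")
  expect_equal(r$beta, 1, tolerance = 1e-8)
  expect_lt(r$p, 1e-10)
  expect_true(r$ci_lo <= r$beta && r$beta <= r$ci_hi)
  expect_equal(r$ci_hi - r$beta, 1.96 * r$se, tolerance = 1e-12)
})

test_that("an independent trait has a near-zero standardized beta", {
  co <- trait_cohort(2500, seed = 52)
  set.seed(53)
  co$noise_trait <- rnorm(nrow(co))
  r <- trait_gee_association(co, trait_spec("noise_trait",
                                            covariates = character()),
                             "cpg_m")
  expect_lt(abs(r$beta), 0.05)
})

test_that("a known standardized effect is recovered under pair correlation", {
  set.seed(54)
  co <- trait_cohort(1000, seed = 54)
  pair <- rep(seq_len(1000), each = 2)
  tr <- rnorm(2000)
  co$driver <- tr
  co$cpg_m <- 0.3 * tr + sqrt(1 - 0.09) *
    (sqrt(0.5) * rnorm(1000)[pair] + sqrt(0.5) * rnorm(2000))
  r <- trait_gee_association(co, trait_spec("driver",
                                            covariates = character()),
                             "cpg_m")
  expect_lt(abs(r$beta - 0.3), 0.05)
})

test_that("standardized beta is invariant to affine rescaling of the trait", {
  co <- trait_cohort(300, seed = 55)
  set.seed(56)
  co$tr <- co$cpg_m * 0.4 + rnorm(nrow(co))
  r1 <- trait_gee_association(co, trait_spec("tr", covariates = character()),
                              "cpg_m")
  co$tr <- co$tr * 37 + 1200
  r2 <- trait_gee_association(co, trait_spec("tr", covariates = character()),
                              "cpg_m")
  expect_equal(r1$beta, r2$beta, tolerance = 1e-10)
})

test_that("log10 transform is refused for non-positive traits", {
  co <- trait_cohort(50, seed = 57)
  co$tg <- co$cpg_m  # contains negatives
  expect_error(
    trait_gee_association(co, trait_spec("tg", log10_transform = TRUE,
                                         covariates = character()),
                          "cpg_m"),
    "non-positive")
})

test_that("batch partition is a disjoint cover of the significant set", {
  set.seed(58)
  co <- trait_cohort(300, seed = 58)
  pair <- rep(seq_len(300), each = 2)
  mk_noise <- function() sqrt(0.5) * rnorm(300)[pair] +
    sqrt(0.5) * rnorm(600)
  ## engineered truth: 2 traits hit outcome A only, 1 B only, 3 both, 2 null
  specs <- list()
  for (i in 1:2) {
    co[[paste0("a_only", i)]] <- 0.6 * co$cpg_m + mk_noise()
    specs <- c(specs, list(trait_spec(paste0("a_only", i),
                                      covariates = character())))
  }
  co$b_only1 <- 0.6 * co$mtdnaq_z + mk_noise()
  specs <- c(specs, list(trait_spec("b_only1", covariates = character())))
  for (i in 1:3) {
    co[[paste0("both", i)]] <- 0.5 * co$cpg_m + 0.5 * co$mtdnaq_z + mk_noise()
    specs <- c(specs, list(trait_spec(paste0("both", i),
                                      covariates = character())))
  }
  for (i in 1:2) {
    co[[paste0("null", i)]] <- mk_noise()
    specs <- c(specs, list(trait_spec(paste0("null", i),
                                      covariates = character())))
  }
  ## note cpg_m and mtdnaq_z are independent in this cohort by construction
  b <- batch_associations_with_fdr(co, specs, c("cpg_m", "mtdnaq_z"))
  expect_setequal(b$partition$only_cpg_m, c("a_only1", "a_only2"))
  expect_setequal(b$partition$only_mtdnaq_z, "b_only1")
  expect_setequal(b$partition$both, c("both1", "both2", "both3"))
  ## set algebra: disjoint, union equals significant set
  all_sig <- unlist(b$partition)
  expect_false(any(duplicated(all_sig)))
  sig_a <- b$results$trait[b$results$outcome == "cpg_m" &
                             b$results$fdr_q < 0.05]
  sig_b <- b$results$trait[b$results$outcome == "mtdnaq_z" &
                             b$results$fdr_q < 0.05]
  expect_setequal(all_sig, union(sig_a, sig_b))
})

test_that("batch records per-spec failures and continues", {
  co <- trait_cohort(100, seed = 59)
  co$bad <- rep(1, nrow(co))  # zero variance
  b <- batch_associations_with_fdr(
    co, list(trait_spec("bad", covariates = character()),
             trait_spec("age", covariates = character())),
    c("cpg_m", "mtdnaq_z"))
  expect_true(length(b$failures) >= 1)
  expect_true("age" %in% b$results$trait)
})

test_that("pearson_correlation matches the direct formula", {
  set.seed(60)
  x <- rnorm(50)
  expect_equal(unname(pearson_correlation(x, x)["r"]), 1)
  expect_equal(unname(pearson_correlation(x, -x)["r"]), -1)
  y <- 0.5 * x + rnorm(50)
  got <- pearson_correlation(x, y)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt(48 / (1 - r^2))
  expect_equal(unname(got["r"]), r, tolerance = 1e-12)
  expect_equal(unname(got["p"]), 2 * pt(-abs(tstat), 48), tolerance = 1e-12)
  expect_error(pearson_correlation(rep(1, 10), rnorm(10)), "variance")
})

test_that("variance partition brackets its invariants", {
  set.seed(61)
  np <- 400
  pair <- rep(seq_len(np), each = 2)
  meth <- rnorm(2 * np)
  expr <- sqrt(0.2) * scale(meth)[, 1] + sqrt(0.4) * rnorm(np)[pair] +
    sqrt(0.4) * rnorm(2 * np)
  d <- data.frame(pair_id = pair, expr = expr, meth = meth)
  ve <- variance_explained_lmm(d, "expr", "meth")
  expect_true(ve$marginal >= 0 && ve$marginal <= ve$conditional &&
                ve$conditional <= 1)
  expect_true(all(ve$components >= 0))
  expect_lt(abs(ve$marginal - 0.2), 0.08)
  expect_lt(abs(ve$conditional - 0.6), 0.08)
})

test_that("boundary variance components collapse gracefully", {
  set.seed(62)
  np <- 600
  pair <- rep(seq_len(np), each = 2)
  meth <- rnorm(2 * np)
  ## no pair component at all
  d <- data.frame(pair_id = pair, expr = 0.6 * meth + rnorm(2 * np, 0, 0.8),
                  meth = meth)
  ve <- variance_explained_lmm(d, "expr", "meth")
  expect_lt(abs(ve$conditional - ve$marginal), 0.03)
  ## near-deterministic outcome: both shares approach 1
  d2 <- data.frame(pair_id = pair, expr = meth + rnorm(2 * np, 0, 1e-4),
                   meth = meth)
  ve2 <- suppressWarnings(suppressMessages(
    variance_explained_lmm(d2, "expr", "meth")))
  expect_gt(ve2$marginal, 0.999)
  expect_gt(ve2$conditional, 0.999)
})
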