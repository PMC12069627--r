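test_that("paired dataset keeps complete pairs and mirrors exposures", {
  co <- simulate_twin_cohort(sim_scenario(7, causal_mode = "null", seed = 41))
  co$y[3] <- NA  # one member of pair 2 incomplete
  pd <- build_paired_dataset(co, "x", "y")
  expect_equal(attr(pd, "n_pairs"), 6)
  expect_equal(nrow(pd), 12)
  expect_false("P00002" %in% pd$pair_id)
  ## x_cotwin of twin 1 is x_self of twin 2 and vice versa
  for (p in unique(pd$pair_id)) {
    rows <- pd[pd$pair_id == p, ]
    expect_equal(rows$x_cotwin[1], rows$x_self[2])
    expect_equal(rows$x_cotwin[2], rows$x_self[1])
  }
  expect_lt(abs(mean(pd$x_self)), 1e-12)
  expect_lt(abs(sd(pd$y_self) - 1), 1e-12)
})

test_that("mz_only filters zygosity and small samples error", {
  co <- simulate_twin_cohort(sim_scenario(10, n_pairs_dz = 8, seed = 42))
  pd <- build_paired_dataset(co, "x", "y", mz_only = TRUE)
  expect_equal(attr(pd, "n_pairs"), 10)
  pd_all <- build_paired_dataset(co, "x", "y", mz_only = FALSE)
  expect_equal(attr(pd_all, "n_pairs"), 18)
  expect_error(build_paired_dataset(co[1:8, ], "x", "y"), "5 complete pairs")
})

test_that("estimates are symmetric under twin relabeling", {
  co <- simulate_twin_cohort(sim_scenario(60, causal_mode = "x_causes_y",
                                          beta_causal = 0.4, seed = 43))
  mo1 <- fit_models123(build_paired_dataset(co, "x", "y"))
  ## swap twin order labels within every pair
  co2 <- co
  swap <- rep(c(2L, 1L), nrow(co) / 2)
  co2 <- co2[order(co2$pair_id, swap), ]
  co2$twin_order <- rep(1:2, nrow(co2) / 2)
  mo2 <- fit_models123(build_paired_dataset(co2, "x", "y"))
  expect_equal(mo1$m3$beta_self, mo2$m3$beta_self, tolerance = 1e-10)
  expect_equal(mo1$m2$beta_cotwin, mo2$m2$beta_cotwin, tolerance = 1e-10)
})

test_that("independent traits give null coefficients in all three models", {
  co <- simulate_twin_cohort(sim_scenario(10000, causal_mode = "null",
                                          seed = 44))
  mo <- fit_models123(build_paired_dataset(co, "x", "y"))
  ests <- c(mo$m1$beta_self["est"], mo$m2$beta_cotwin["est"],
            mo$m3$beta_self["est"], mo$m3$beta_cotwin["est"])
  expect_true(all(abs(ests) < 0.03))
})

test_that("coefficient changes are the exact differences of point estimates", {
  co <- simulate_twin_cohort(sim_scenario(80, causal_mode = "x_causes_y",
                                          beta_causal = 0.5, seed = 45))
  pd <- build_paired_dataset(co, "x", "y")
  mo <- fit_models123(pd)
  ch <- coefficient_changes(pd, mo, n_boot = 50, seed = 1)
  expect_equal(ch$delta_self[["est"]],
               mo$m3$beta_self[["est"]] - mo$m1$beta_self[["est"]])
  expect_equal(ch$delta_cotwin[["est"]],
               mo$m3$beta_cotwin[["est"]] - mo$m2$beta_cotwin[["est"]])
})

test_that("pair bootstrap is deterministic under a fixed seed", {
  co <- simulate_twin_cohort(sim_scenario(60, causal_mode = "x_causes_y",
                                          beta_causal = 0.4, seed = 46))
  pd <- build_paired_dataset(co, "x", "y")
  mo <- fit_models123(pd)
  ch1 <- coefficient_changes(pd, mo, n_boot = 100, seed = 5)
  ch2 <- coefficient_changes(pd, mo, n_boot = 100, seed = 5)
  expect_identical(ch1$delta_self, ch2$delta_self)
  expect_identical(ch1$delta_cotwin, ch2$delta_cotwin)
  ch3 <- coefficient_changes(pd, mo, n_boot = 100, seed = 6)
  expect_false(identical(ch1$delta_cotwin[["se"]],
                         ch3$delta_cotwin[["se"]]))
})

test_that("percentile CI comes from the stored bootstrap replicates", {
  co <- simulate_twin_cohort(sim_scenario(60, causal_mode = "x_causes_y",
                                          beta_causal = 0.5, seed = 48))
  pd <- build_paired_dataset(co, "x", "y")
  mo <- fit_models123(pd)
  ch <- coefficient_changes(pd, mo, n_boot = 200, seed = 3)
  ci <- change_percentile_ci(ch, "delta_cotwin")
  expect_lt(ci[["lo"]], ci[["hi"]])
  expect_equal(unname(ci),
               unname(quantile(ch$replicates$delta_cotwin,
                               c(0.025, 0.975), na.rm = TRUE)))
})

test_that("classifier reproduces the canonical rule patterns", {
  mk <- function(bs1, ps1, bc2, pc2, bs3, ps3, bc3, pc3, ds, dsp, dc, dcp) {
    models <- structure(list(
      m1 = list(beta_self = c(est = bs1, se = 0.05, p = ps1)),
      m2 = list(beta_cotwin = c(est = bc2, se = 0.05, p = pc2)),
      m3 = list(beta_self = c(est = bs3, se = 0.05, p = ps3),
                beta_cotwin = c(est = bc3, se = 0.05, p = pc3))
    ), class = "icefalcon_models")
    changes <- structure(list(
      delta_self = c(est = ds, se = 0.02, p = dsp),
      delta_cotwin = c(est = dc, se = 0.02, p = dcp)
    ), class = "coefficient_change")
    list(models = models, changes = changes)
  }
  ## forced causal pattern: cotwin halves with significant change, self fixed
  causal <- classify_causal_pattern(
    mk(0.5, 1e-8, 0.5, 1e-6, 0.5, 1e-8, 0.05, 0.5, 0, 0.9, -0.45, 1e-4))
  expect_equal(causal$label, "evidence_x_causes_y")
  expect_true(length(causal$trace) > 0)

  ## all zero: no association
  null <- classify_causal_pattern(
    mk(0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1))
  expect_equal(null$label, "no_association")

  ## both attenuate: familial confounding
  fam <- classify_causal_pattern(
    mk(0.5, 1e-8, 0.5, 1e-8, 0.3, 1e-6, 0.3, 1e-6, -0.2, 0.001, -0.2, 0.001))
  expect_equal(fam$label, "familial_confounding")

  ## cotwin appears only in M3: within-individual confounding possible
  wic <- classify_causal_pattern(
    mk(0.4, 1e-8, 0.01, 0.9, 0.5, 1e-8, -0.25, 1e-4, 0.1, 0.01, -0.26, 1e-4))
  expect_equal(wic$label, "within_individual_confounding_possible")

  ## reduced certainty flag without a reverse direction
  expect_true(causal$reduced_certainty)
})

test_that("published worked example classifies as causation from mtDNAq", {
  est <- published_icefalcon_estimates()
  fwd <- icefalcon_from_estimates(est, "cg19998400~mtdnaq")
  cls <- classify_causal_pattern(fwd)
  expect_equal(cls$label, "evidence_x_causes_y")
})

test_that("swapping x and y mirrors the bidirectional result", {
  co <- simulate_twin_cohort(sim_scenario(100, causal_mode = "x_causes_y",
                                          beta_causal = 0.5, seed = 47))
  r1 <- run_bidirectional(co, "x", "y", n_boot = 50, seed = 9)
  r2 <- run_bidirectional(co, "y", "x", n_boot = 50, seed = 9)
  expect_equal(r1$forward$models$m1$beta_self,
               r2$reverse$models$m1$beta_self, tolerance = 1e-10)
  expect_equal(r1$reverse$models$m3$beta_cotwin,
               r2$forward$models$m3$beta_cotwin, tolerance = 1e-10)
})

test_that("a null cohort is labeled no_association in both directions", {
  hits <- sapply(1:10, function(s) {
    co <- simulate_twin_cohort(sim_scenario(500, causal_mode = "null",
                                            seed = 100 + s))
    res <- run_bidirectional(co, "x", "y", n_boot = 100, seed = s)
    rev_lab <- classify_causal_pattern(res$reverse)$label
    res$label == "no_association" && rev_lab == "no_association"
  })
  expect_gte(mean(hits), 0.8)
})
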