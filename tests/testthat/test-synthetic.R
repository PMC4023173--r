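test_that("paired binary generator honors the seed and the joint structure", {
  t1 <- simulate_paired_binary_trial(50, 0.4, 0.3, 0.5, seed = 9)
  t2 <- simulate_paired_binary_trial(50, 0.4, 0.3, 0.5, seed = 9)
  expect_identical(t1, t2)

  # equal margins with perfect correlation leave no discordant pairs
  tp <- simulate_paired_binary_trial(200, 0.35, 0.35, 1, seed = 10)
  expect_equal(tp$n10, 0)
  expect_equal(tp$n01, 0)

  # independence: the concordant-event cell tracks p1 * p2 (law of large numbers)
  tb <- simulate_paired_binary_trial(1e5, 0.4, 0.3, 0, seed = 11)
  p11 <- tb$n11 / tb$n
  se <- sqrt(0.12 * 0.88 / 1e5)
  expect_lt(abs(p11 - 0.12), 3 * se)

  expect_warning(simulate_paired_binary_trial(100, 0.9, 0.1, 0.9, seed = 12),
                 "clamped")
})

test_that("paired continuous generator matches its moments at large n", {
  pc1 <- simulate_paired_continuous_trial(100, 0.3, 0.5, seed = 13)
  pc2 <- simulate_paired_continuous_trial(100, 0.3, 0.5, seed = 13)
  expect_identical(pc1, pc2)

  big <- simulate_paired_continuous_trial(1e5, 0, 0.5, seed = 14)
  # mean difference has SD sqrt(2(1 - rho)/n) around zero
  expect_lt(abs(big$mean_exp - big$mean_ctl), 3 * sqrt(2 * 0.5 / 1e5))
  expect_equal(big$rho, 0.5, tolerance = 0.02)
  expect_equal(big$sd_diff, sqrt(2 * (1 - 0.5)), tolerance = 0.02)
  expect_equal(big$sd_exp, 1, tolerance = 0.02)
})

test_that("dataset generation is reproducible and emits valid domain objects", {
  cfg <- simulation_config(outcome_type = "binary", seed = 15)
  m1 <- simulate_metaepi_dataset(cfg)
  m2 <- simulate_metaepi_dataset(cfg)
  expect_identical(m1, m2)
  expect_length(m1, cfg$n_meta)
  for (m in m1) {
    expect_s3_class(m, "meta_analysis_input")
    keep <- !m$trials$excluded
    expect_true(all(m$trials$variance[keep] > 0))
    expect_true(all(m$trials$scale[keep] == "log_odds_ratio"))
  }

  rec <- simulate_metaepi_dataset(cfg, output = "records")
  expect_s3_class(rec, "trial_records")
  expect_true(all(c("meta_id", "trial_id", "design", "n11") %in% names(rec)))
  sm <- rec$design == "split_mouth"
  expect_true(all(!is.na(rec$n11[sm])))
  expect_true(all(is.na(rec$n11[!sm])))
  k <- table(rec$meta_id, rec$design)
  expect_true(all(k >= cfg$trials_per_design[1] & k <= cfg$trials_per_design[2]))
})

test_that("a paper-scale synthetic run completes with finite results", {
  for (ot in c("binary", "continuous")) {
    cfg <- simulation_config(outcome_type = ot, seed = 16)
    metas <- simulate_metaepi_dataset(cfg)
    cons <- lapply(metas[vapply(metas, is_eligible, TRUE)], design_contrast)
    res <- pool_contrasts(cons)
    expect_true(is.finite(res$combined))
    expect_true(is.finite(res$p_value))
    expect_gte(res$tau2, 0)
    expect_true(res$prediction$lower < res$combined &&
                  res$combined < res$prediction$upper)
  }
})

test_that("degenerate configurations are rejected", {
  expect_error(simulation_config(n_meta = 0), "invalid")
  expect_error(simulation_config(trials_per_design = c(4, 2)), "min")
  expect_error(simulation_config(tau2_effect = -1), "non-negative")
  expect_error(simulation_config(control_risk = 1.2), "0, 1")
})
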