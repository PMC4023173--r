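make_est <- function(values, variances, scale = "smd") {
  mapply(function(y, v, i) effect_estimate(y, v, scale, trial_id = paste0("t", i)),
         values, variances, seq_along(values), SIMPLIFY = FALSE)
}

test_that("fixed-effect pooling is the inverse-variance weighted mean", {
  p <- pool_fixed(make_est(c(0, 0), c(1, 1)))
  expect_equal(p$value, 0)
  expect_equal(p$variance, 0.5)
  expect_equal(p$q_stat, 0)
  expect_equal(p$i2, 0)

  p2 <- pool_fixed(make_est(c(0.2, 0.6), c(0.04, 0.16)))
  expect_equal(p2$value, 0.28)
  expect_equal(p2$variance, 1 / 31.25)

  # a single estimate passes through unchanged, still tagged fixed
  p1 <- pool_fixed(make_est(0.7, 0.09))
  expect_equal(p1$value, 0.7)
  expect_equal(p1$variance, 0.09)
  expect_equal(p1$method, "fixed")
  expect_equal(p1$k, 1)

  expect_error(pool_fixed(list()), "effect_estimate")
})

test_that("fixed pooled value stays within the input range, weights sum to 1", {
  set.seed(51)
  for (rep in 1:15) {
    est <- random_estimates(sample(2:8, 1))
    y <- vapply(est, `[[`, 0, "value")
    v <- vapply(est, `[[`, 0, "variance")
    p <- pool_fixed(est)
    expect_gte(p$value, min(y))
    expect_lte(p$value, max(y))
    w <- (1 / v) / sum(1 / v)
    expect_equal(sum(w), 1)
    expect_equal(p$value, sum(w * y))
  }
})

test_that("heterogeneity statistics match hand computation and invariances", {
  h <- heterogeneity(make_est(c(0, 2), c(1, 1)))
  expect_equal(h$q_stat, 2)
  expect_equal(h$i2, 50)

  hh <- heterogeneity(make_est(c(0.3, 0.3, 0.3), c(0.1, 0.2, 0.3)))
  expect_equal(hh$q_stat, 0)
  expect_equal(hh$i2, 0)
  expect_equal(hh$tau2_dl, 0)

  expect_error(heterogeneity(make_est(1, 1)), "at least two")

  # Q and I^2 are invariant under scaling variances by c and effects by sqrt(c)
  set.seed(52)
  y <- rnorm(6); v <- runif(6, 0.05, 0.3); cc <- 3.7
  h1 <- heterogeneity(make_est(y, v))
  h2 <- heterogeneity(make_est(y * sqrt(cc), v * cc))
  expect_equal(h1$q_stat, h2$q_stat)
  expect_equal(h1$i2, h2$i2)
})

test_that("REML tau2 agrees with the grid-search oracle", {
  # identical estimates: no heterogeneity, reduces to the fixed result
  p0 <- pool_random_reml(make_est(c(0.4, 0.4, 0.4), c(0.1, 0.1, 0.1)))
  expect_equal(p0$tau2, 0)
  expect_equal(p0$value, 0.4)
  expect_equal(p0$variance, 0.1 / 3)

  # extreme two-point case solved independently by grid search
  p <- pool_random_reml(make_est(c(-1, 1), c(0.01, 0.01)))
  expect_lt(abs(p$tau2 - grid_reml_tau2(c(-1, 1), c(0.01, 0.01))), 1e-4)

  set.seed(53)
  for (rep in 1:10) {
    k <- sample(3:8, 1)
    y <- rnorm(k, 0, 0.7)
    v <- runif(k, 0.02, 0.3)
    p <- pool_random_reml(make_est(y, v))
    # absolute agreement within the oracle's fine-grid resolution
    expect_lt(abs(p$tau2 - grid_reml_tau2(y, v)), 5e-5)
    # random-effects pooled variance never undercuts the fixed-effect one
    expect_gte(p$variance, pool_fixed(make_est(y, v))$variance - 1e-12)
  }

  expect_warning(p1 <- pool_random_reml(make_est(0.2, 0.05)), "one estimate")
  expect_equal(p1$method, "fixed")
})

test_that("REML matches an independent reference implementation", {
  skip_if_not_installed("metafor")
  set.seed(54)
  for (rep in 1:5) {
    k <- sample(4:10, 1)
    y <- rnorm(k, 0.2, 0.6)
    v <- runif(k, 0.02, 0.25)
    p <- pool_random_reml(make_est(y, v))
    ref <- metafor::rma(yi = y, vi = v, method = "REML")
    expect_equal(p$tau2, as.numeric(ref$tau2), tolerance = 1e-5)
    expect_equal(p$value, as.numeric(ref$beta), tolerance = 1e-6)
    expect_equal(sqrt(p$variance), as.numeric(ref$se), tolerance = 1e-6)
  }
})

test_that("prediction intervals widen with tau2 and reduce to the CI at tau2 = 0", {
  p <- pooled_effect(0.3, 0.04, tau2 = 0, k = 5, method = "random_reml")
  pi0 <- prediction_interval(p)
  ci <- confint(p)
  expect_equal(pi0$lower, ci[1])
  expect_equal(pi0$upper, ci[2])

  widths <- vapply(c(0, 0.05, 0.2, 0.5), function(t2) {
    pp <- pooled_effect(0.3, 0.04, tau2 = t2, k = 5, method = "random_reml")
    pi <- prediction_interval(pp)
    pi$upper - pi$lower
  }, 0)
  expect_true(all(diff(widths) > 0))

  # t variant needs k >= 3 and is wider than z for small k
  expect_error(prediction_interval(pooled_effect(0, 0.1, 0.1, k = 2), method = "t"),
               "at least 3")
  pz <- prediction_interval(pooled_effect(0, 0.1, 0.1, k = 4), method = "z")
  pt <- prediction_interval(pooled_effect(0, 0.1, 0.1, k = 4), method = "t")
  expect_gt(pt$upper, pz$upper)
})
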