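test_that("parallel-arm log OR matches the closed form and the zero-cell rules", {
  e <- log_or_parallel(binary_arms(10, 20, 10, 20))
  expect_equal(e$value, 0)
  expect_equal(e$variance, 0.4)
  expect_equal(e$scale, "log_odds_ratio")

  # one zero cell: 0.5 added to all four cells before computing
  e0 <- log_or_parallel(binary_arms(0, 20, 5, 20))
  expect_equal(e0$value, log((0.5 * 15.5) / (20.5 * 5.5)))
  expect_equal(e0$variance, 1 / 0.5 + 1 / 20.5 + 1 / 5.5 + 1 / 15.5)

  # no events anywhere: the trial is excluded, not estimated
  edz <- log_or_parallel(binary_arms(0, 20, 0, 20))
  expect_true(edz$excluded)
  expect_equal(edz$reason, "double_zero")

  # events everywhere carry no odds-ratio information either
  expect_error(log_or_parallel(binary_arms(20, 20, 20, 20)), "all participants")
  expect_error(binary_arms(25, 20, 5, 20), "exceed")
})

test_that("marginal log OR of a paired table matches the delta-method form", {
  e <- marginal_log_or_split_mouth(paired_binary_table(30, 10, 5, 55))
  expect_equal(e$value, log((0.40 * 0.65) / (0.35 * 0.60)))
  expect_equal(e$value, 0.2135741, tolerance = 1e-6)
  expect_equal(e$variance, 0.02701465, tolerance = 1e-6)
  expect_equal(e$design, "split_mouth")

  # equal discordant cells force equal margins, so the marginal OR is 1
  e0 <- marginal_log_or_split_mouth(paired_binary_table(20, 7, 7, 66))
  expect_equal(e0$value, 0)

  # under independence the covariance term vanishes: variance reduces to the
  # sum of the two binomial logit variances
  p1 <- 0.4; p2 <- 0.3; n <- 100
  tab <- paired_binary_table(p1 * p2 * n, p1 * (1 - p2) * n,
                             (1 - p1) * p2 * n, (1 - p1) * (1 - p2) * n)
  ei <- marginal_log_or_split_mouth(tab)
  expect_equal(ei$variance,
               (1 / n) * (1 / (p1 * (1 - p1)) + 1 / (p2 * (1 - p2))))

  # double-zero and all-event tables are excluded
  expect_true(marginal_log_or_split_mouth(paired_binary_table(0, 0, 0, 40))$excluded)
  expect_true(marginal_log_or_split_mouth(paired_binary_table(40, 0, 0, 0))$excluded)
})

test_that("marginal OR value depends on the margins only", {
  set.seed(41)
  for (rep in 1:20) {
    tab <- random_paired_table(400)
    # transfer mass between concordant and discordant cells, margins fixed
    shift <- min(tab$n10 - 1, tab$n01 - 1, 3)  # keep all cells positive
    tab2 <- paired_binary_table(tab$n11 + shift, tab$n10 - shift,
                                tab$n01 - shift, tab$n00 + shift)
    e1 <- marginal_log_or_split_mouth(tab)
    e2 <- marginal_log_or_split_mouth(tab2)
    expect_equal(e1$value, e2$value)
    # stronger positive dependence shrinks the variance
    expect_lte(e2$variance, e1$variance + 1e-12)
  }
})

test_that("positive within-patient dependence shrinks the marginal OR variance", {
  set.seed(42)
  for (rep in 1:25) {
    tab <- random_paired_table(300)
    pi <- c(tab$n11, tab$n10, tab$n01, tab$n00) / tab$n
    p1 <- pi[1] + pi[2]; p2 <- pi[1] + pi[3]
    v_indep <- (1 / tab$n) * (1 / (p1 * (1 - p1)) + 1 / (p2 * (1 - p2)))
    v <- marginal_log_or_split_mouth(tab)$variance
    if (pi[1] * pi[4] > pi[2] * pi[3]) expect_lt(v, v_indep)
    expect_gt(v, 0)
  }
})

test_that("joint cells reconstructed from margins honor rho and the margins", {
  t0 <- paired_cells_from_marginals(40, 35, 100, rho = 0)
  expect_equal(c(t0$n11, t0$n10, t0$n01, t0$n00), c(14, 26, 21, 39))

  t5 <- paired_cells_from_marginals(40, 35, 100, rho = 0.5)
  expect_equal(t5$n11, (0.14 + 0.5 * sqrt(0.4 * 0.6 * 0.35 * 0.65)) * 100,
               tolerance = 1e-10)
  expect_equal(t5$n11 + t5$n10, 40)  # margins recovered exactly
  expect_equal(t5$n11 + t5$n01, 35)

  # perfect correlation with identical margins: no discordant pairs
  tp <- paired_cells_from_marginals(30, 30, 100, rho = 1)
  expect_equal(tp$n10, 0)
  expect_equal(tp$n01, 0)

  # infeasible rho is clamped with a warning, never an error
  expect_warning(tc <- paired_cells_from_marginals(90, 10, 100, rho = 0.9),
                 "clamped")
  expect_gte(min(tc$n11, tc$n10, tc$n01, tc$n00), 0)
  expect_equal(tc$n11, 10)  # Frechet upper bound min(p1, p2) * n
})

test_that("round-trip through reconstruction preserves feasible margins", {
  set.seed(43)
  for (rep in 1:20) {
    n <- sample(50:300, 1)
    e1 <- sample.int(n - 1, 1)
    e2 <- sample.int(n - 1, 1)
    p1 <- e1 / n; p2 <- e2 / n
    s <- sqrt(p1 * (1 - p1) * p2 * (1 - p2))
    lo <- (max(0, p1 + p2 - 1) - p1 * p2) / s
    hi <- (min(p1, p2) - p1 * p2) / s
    rho <- runif(1, lo, hi)
    tab <- paired_cells_from_marginals(e1, e2, n, rho)
    expect_equal(tab$n11 + tab$n10, e1, tolerance = 1e-9)
    expect_equal(tab$n11 + tab$n01, e2, tolerance = 1e-9)
    expect_equal(tab$n, n, tolerance = 1e-9)
  }
})

test_that("parallel-arm SMD is Cohen's d with the standard variance", {
  e0 <- smd_parallel(continuous_arms(1.2, 0.8, 20, 1.2, 1.1, 20))
  expect_equal(e0$value, 0)
  expect_equal(e0$variance, 0.1)

  e1 <- smd_parallel(continuous_arms(1, 1, 50, 0, 1, 50))
  expect_equal(e1$value, 1)
  expect_equal(e1$variance, 0.04 + 1 / 200)

  # swapping arms negates the effect, variance unchanged
  e2 <- smd_parallel(continuous_arms(0, 1, 50, 1, 1, 50))
  expect_equal(e2$value, -e1$value)
  expect_equal(e2$variance, e1$variance)
})

test_that("split-mouth SMD scales the paired variance by the correlation", {
  e0 <- smd_split_mouth(paired_continuous(2, 2, 1, 1, n = 30, rho = 0.4))
  expect_equal(e0$value, 0)
  expect_equal(e0$variance, 2 * (1 - 0.4) / 30)

  e1 <- smd_split_mouth(paired_continuous(0.5, 0, 1, 1, n = 25, rho = 0.5))
  expect_equal(e1$value, 0.5)
  expect_equal(e1$variance, 0.045)

  # sd_diff path with rho = 0.5 and equal site SDs implies s_within = sd_diff
  s <- 1.7
  e2 <- smd_split_mouth(paired_continuous(0.5 * s, 0, n = 25, rho = 0.5,
                                          sd_diff = s))
  expect_equal(e2$value, 0.5)
  expect_equal(e2$variance, e1$variance)

  # variance strictly decreasing in rho for fixed d and n
  vs <- vapply(seq(-0.5, 0.9, by = 0.1), function(r) {
    smd_split_mouth(paired_continuous(0.5, 0, 1, 1, n = 25, rho = r))$variance
  }, 0)
  expect_true(all(diff(vs) < 0))

  expect_error(smd_split_mouth(paired_continuous(1, 0, n = 20, rho = 1,
                                                 sd_diff = 1)),
               "rho = 1")
})

test_that("Follmann imputation of the difference SD is the quadratic form", {
  expect_equal(follmann_impute_sd_diff(2, 2, 0.5), 2)
  expect_equal(follmann_impute_sd_diff(3, 4, 0), 5)
  expect_equal(follmann_impute_sd_diff(3, 4, 0.25), sqrt(19))
  expect_error(follmann_impute_sd_diff(-1, 2, 0), "positive")
})

test_that("orientation flips higher-is-better outcomes once and only once", {
  e <- effect_estimate(0.3, 0.1, "smd", "parallel")
  hi <- orient_effect(e, "higher")
  expect_equal(hi$value, -0.3)
  expect_equal(hi$variance, e$variance)
  lo <- orient_effect(effect_estimate(-0.3, 0.1, "smd", "parallel"), "lower")
  expect_equal(lo$value, -0.3)
  # idempotent: an oriented estimate is never flipped again
  expect_equal(orient_effect(hi, "higher")$value, -0.3)
})

test_that("non-excluded estimates always carry strictly positive variances", {
  set.seed(44)
  for (rep in 1:20) {
    tab <- suppressWarnings(  # rho may be clamped for extreme margins
      simulate_paired_binary_trial(20, runif(1, 0.05, 0.6),
                                   runif(1, 0.05, 0.6), 0.5))
    e <- marginal_log_or_split_mouth(tab)
    if (!e$excluded) expect_gt(e$variance, 0)
  }
})
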