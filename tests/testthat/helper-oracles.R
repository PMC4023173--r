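# Independent oracles used across the suite.

# Empirical (Monte-Carlo) variance of the marginal log OR of a paired binary
# table: resample the joint cells from a multinomial at the observed cell
# proportions and take the variance of the recomputed log marginal OR.
mc_marginal_or_variance <- function(n11, n10, n01, n00, reps = 2e4) {
  cells <- c(n11, n10, n01, n00)
  n <- sum(cells)
  draws <- stats::rmultinom(reps, n, cells / n)
  p1 <- (draws[1, ] + draws[2, ]) / n
  p2 <- (draws[1, ] + draws[3, ]) / n
  ok <- p1 > 0 & p1 < 1 & p2 > 0 & p2 < 1
  lor <- log(p1[ok] * (1 - p2[ok]) / (p2[ok] * (1 - p1[ok])))
  stats::var(lor)
}

# Grid-search REML oracle: maximize the restricted log-likelihood of the
# normal-normal random-effects model over a tau^2 grid, coarse pass then a
# fine pass around the coarse argmax. Resolution of the fine pass: 1e-5.
grid_reml_tau2 <- function(y, v, upper = 10) {
  rll <- function(t2) {
    w <- 1 / (v + t2)
    mu <- sum(w * y) / sum(w)
    -0.5 * sum(log(v + t2)) - 0.5 * log(sum(w)) - 0.5 * sum(w * (y - mu)^2)
  }
  coarse <- seq(0, upper, by = 0.01)
  t0 <- coarse[which.max(vapply(coarse, rll, 0))]
  fine <- seq(max(0, t0 - 0.02), t0 + 0.02, by = 1e-5)
  fine[which.max(vapply(fine, rll, 0))]
}

# Random non-degenerate paired binary table with all cells >= 1.
random_paired_table <- function(n = 300) {
  repeat {
    p1 <- stats::runif(1, 0.15, 0.85)
    p2 <- stats::runif(1, 0.15, 0.85)
    lo <- (max(0, p1 + p2 - 1) - p1 * p2) /
      sqrt(p1 * (1 - p1) * p2 * (1 - p2))
    hi <- (min(p1, p2) - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
    rho <- stats::runif(1, max(lo, -0.5) * 0.9, min(hi, 0.9) * 0.9)
    tab <- simulate_paired_binary_trial(n, p1, p2, rho)
    if (min(tab$n11, tab$n10, tab$n01, tab$n00) >= 1) return(tab)
  }
}

# Random small meta-analysis inputs for pooling / pipeline property tests.
random_estimates <- function(k, scale = "smd") {
  lapply(seq_len(k), function(i) {
    effect_estimate(stats::rnorm(1, 0, 0.8),
                    stats::runif(1, 0.02, 0.4),
                    scale = scale,
                    design = sample(c("split_mouth", "parallel"), 1),
                    trial_id = paste0("t", i))
  })
}
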