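# Inverse-variance pooling: fixed effect and REML random effects, with
# Cochran's Q, I^2, DerSimonian-Laird tau^2 as a diagnostic, and z/t
# prediction intervals.

# Coerce a list of effect_estimate objects (or a data.frame with value /
# variance columns) to the internal estimate table, dropping excluded rows.
estimates_table <- function(estimates) {
  if (is.data.frame(estimates)) {
    df <- estimates
    if (!all(c("value", "variance") %in% names(df)))
      stop("estimate data frame needs `value` and `variance` columns", call. = FALSE)
    if (is.null(df$excluded)) df$excluded <- FALSE
    if (is.null(df$scale)) df$scale <- NA_character_
  } else {
    if (inherits(estimates, "effect_estimate")) estimates <- list(estimates)
    if (!length(estimates) || !all(vapply(estimates, inherits, TRUE, "effect_estimate")))
      stop("`estimates` must be effect_estimate objects or a data frame", call. = FALSE)
    df <- data.frame(
      trial_id = vapply(estimates, function(e) e$trial_id, ""),
      design = vapply(estimates, function(e) e$design, ""),
      scale = vapply(estimates, function(e) e$scale, ""),
      value = vapply(estimates, function(e) e$value, 0),
      variance = vapply(estimates, function(e) e$variance, 0),
      excluded = vapply(estimates, function(e) e$excluded, TRUE),
      stringsAsFactors = FALSE
    )
  }
  df <- df[!df$excluded, , drop = FALSE]
  sc <- unique(df$scale[!is.na(df$scale)])
  if (length(sc) > 1)
    stop("estimates mix scales (", paste(sc, collapse = ", "), ")", call. = FALSE)
  df
}

#' Construct a pooled-effect summary directly
#'
#' Mostly produced by [pool_fixed()] / [pool_random_reml()], but useful on
#' its own to rebuild a published summary (pooled value, its variance --
#' e.g. back-calculated from a reported CI -- and tau^2) so that derived
#' quantities such as [prediction_interval()] can be computed from printed
#' results.
#'
#' @param value Pooled effect on the log OR / SMD scale.
#' @param variance Variance of the pooled effect.
#' @param tau2 Between-unit variance.
#' @param k Number of units pooled.
#' @param method `"fixed"` or `"random_reml"`.
#' @param q_stat,i2 Optional heterogeneity statistics.
#' @param scale Optional effect scale tag.
#'
#' @return A `pooled_effect`.
#' @export
pooled_effect <- function(value, variance, tau2 = 0, k,
                          method = c("random_reml", "fixed"),
                          q_stat = NA_real_, i2 = NA_real_,
                          scale = NA_character_) {
  method <- match.arg(method)
  if (!is.finite(variance) || variance <= 0)
    stop("`variance` must be strictly positive", call. = FALSE)
  if (!is.finite(tau2) || tau2 < 0)
    stop("`tau2` must be non-negative", call. = FALSE)
  if (method == "fixed" && tau2 != 0)
    stop("a fixed-effect summary has tau2 = 0", call. = FALSE)
  new_pooled(value, variance, tau2, q_stat, i2, k, method, scale)
}

new_pooled <- function(value, variance, tau2, q_stat, i2, k, method,
                       scale = NA_character_) {
  structure(
    list(value = value, variance = variance, tau2 = tau2, q_stat = q_stat,
         i2 = i2, k = k, method = method, scale = scale),
    class = "pooled_effect"
  )
}

q_and_i2 <- function(y, v) {
  k <- length(y)
  w <- 1 / v
  mu <- sum(w * y) / sum(w)
  q <- sum(w * (y - mu)^2)
  i2 <- if (k >= 2 && q > 0) max(0, (q - (k - 1)) / q) * 100 else 0
  list(q = q, i2 = i2, mu = mu, w = w)
}

#' Fixed-effect inverse-variance pooling
#'
#' Weights each estimate by the reciprocal of its sampling variance. A single
#' estimate is passed through unchanged (still tagged `fixed`). Cochran's Q
#' and I^2 are reported as side outputs; `tau2` is 0 by definition.
#'
#' @param estimates A list of [effect_estimate()] objects (excluded ones are
#'   dropped) or a data frame with `value` and `variance` columns.
#'
#' @return A `pooled_effect` with fields `value`, `variance`, `tau2`,
#'   `q_stat`, `i2`, `k`, `method`.
#' @export
pool_fixed <- function(estimates) {
  df <- estimates_table(estimates)
  k <- nrow(df)
  if (k == 0)
    stop("no non-excluded estimates to pool", call. = FALSE)
  h <- q_and_i2(df$value, df$variance)
  new_pooled(value = h$mu, variance = 1 / sum(h$w), tau2 = 0,
             q_stat = h$q, i2 = h$i2, k = k, method = "fixed",
             scale = df$scale[1])
}

# REML estimation of tau^2 in the normal-normal random-effects model, by
# Fisher scoring on the restricted likelihood. Returns tau2 and iterations.
reml_tau2 <- function(y, v, tol = 1e-8, max_iter = 100) {
  k <- length(y)
  # DerSimonian-Laird start keeps iterations short on typical inputs
  w <- 1 / v
  mu <- sum(w * y) / sum(w)
  q <- sum(w * (y - mu)^2)
  t2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  for (i in seq_len(max_iter)) {
    w <- 1 / (v + t2)
    sw <- sum(w)
    mu <- sum(w * y) / sw
    r <- y - mu
    tr_p <- sw - sum(w^2) / sw
    score <- 0.5 * (sum(w^2 * r^2) - tr_p)
    tr_p2 <- sum(w^2) - 2 * sum(w^3) / sw + (sum(w^2) / sw)^2
    info <- 0.5 * tr_p2
    step <- score / info
    t2_new <- max(0, t2 + step)
    # step-halve if the restricted likelihood would not improve
    while (is.finite(step) && abs(step) > tol &&
           reml_loglik(t2_new, y, v) < reml_loglik(t2, y, v) - 1e-12) {
      step <- step / 2
      t2_new <- max(0, t2 + step)
    }
    if (!is.finite(t2_new))
      stop("REML iteration diverged (last tau2 = ", format(t2), ")", call. = FALSE)
    done <- abs(t2_new - t2) < tol
    t2 <- t2_new
    if (done) return(list(tau2 = t2, iterations = i, converged = TRUE))
  }
  stop("REML did not converge within ", max_iter,
       " iterations (last tau2 = ", format(t2), ")", call. = FALSE)
}

# restricted log-likelihood of tau^2 (constants dropped)
reml_loglik <- function(t2, y, v) {
  w <- 1 / (v + t2)
  mu <- sum(w * y) / sum(w)
  -0.5 * sum(log(v + t2)) - 0.5 * log(sum(w)) - 0.5 * sum(w * (y - mu)^2)
}

#' Random-effects pooling with REML estimation of tau^2
#'
#' Fits the standard normal-normal random-effects model: estimates the
#' between-unit variance tau^2 by restricted maximum likelihood (Fisher
#' scoring, tau^2 floored at zero) and pools with weights
#' `1/(v_i + tau^2)`. With a single estimate the fixed-effect passthrough is
#' returned with a warning. Q and I^2 are the usual fixed-weight
#' heterogeneity statistics of the inputs.
#'
#' @inheritParams pool_fixed
#' @param tol Convergence tolerance on successive tau^2 iterates.
#' @param max_iter Maximum Fisher-scoring iterations; non-convergence is an
#'   error carrying the last iterate.
#'
#' @return A `pooled_effect` with `method = "random_reml"`.
#' @export
pool_random_reml <- function(estimates, tol = 1e-8, max_iter = 100) {
  df <- estimates_table(estimates)
  k <- nrow(df)
  if (k == 0)
    stop("no non-excluded estimates to pool", call. = FALSE)
  if (k == 1) {
    warning("only one estimate: falling back to the fixed-effect passthrough",
            call. = FALSE)
    return(pool_fixed(df))
  }
  y <- df$value
  v <- df$variance
  fit <- reml_tau2(y, v, tol = tol, max_iter = max_iter)
  t2 <- fit$tau2
  w <- 1 / (v + t2)
  h <- q_and_i2(y, v)
  new_pooled(value = sum(w * y) / sum(w), variance = 1 / sum(w), tau2 = t2,
             q_stat = h$q, i2 = h$i2, k = k, method = "random_reml",
             scale = df$scale[1])
}

#' Heterogeneity statistics for a set of estimates
#'
#' Cochran's Q with fixed-effect weights, I^2 = max(0, (Q - (k-1))/Q) * 100,
#' and the DerSimonian-Laird moment estimate of tau^2 as a quick diagnostic
#' alongside the REML fit.
#'
#' @inheritParams pool_fixed
#'
#' @return A list with `q_stat`, `i2` (percent) and `tau2_dl`.
#' @export
heterogeneity <- function(estimates) {
  df <- estimates_table(estimates)
  k <- nrow(df)
  if (k < 2)
    stop("heterogeneity needs at least two estimates", call. = FALSE)
  h <- q_and_i2(df$value, df$variance)
  w <- h$w
  tau2_dl <- max(0, (h$q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  list(q_stat = h$q, i2 = h$i2, tau2_dl = tau2_dl)
}

#' Prediction interval for the true effect of a new unit
#'
#' Under the random-effects model the true effect of a new, individual unit
#' (here: a new meta-analysis's design contrast) varies around the pooled
#' mean with variance `tau^2 + var(pooled)`. The default z method uses the
#' standard normal quantile; the t variant uses `t_{k-2}` and needs at least
#' three units.
#'
#' @param pooled A `pooled_effect` from a random-effects fit.
#' @param level Coverage level in (0, 1).
#' @param method `"z"` (default) or `"t"`.
#'
#' @return A `prediction_interval` with `lower`, `upper`, `level`, `method`.
#' @export
prediction_interval <- function(pooled, level = 0.95, method = c("z", "t")) {
  method <- match.arg(method)
  if (!inherits(pooled, "pooled_effect"))
    stop("`pooled` must be a pooled_effect", call. = FALSE)
  if (!is.finite(level) || level <= 0 || level >= 1)
    stop("`level` must lie in (0, 1)", call. = FALSE)
  alpha <- 1 - level
  crit <- if (method == "z") {
    stats::qnorm(1 - alpha / 2)
  } else {
    if (pooled$k < 3)
      stop("the t-based prediction interval needs at least 3 units", call. = FALSE)
    stats::qt(1 - alpha / 2, df = pooled$k - 2)
  }
  half <- crit * sqrt(pooled$tau2 + pooled$variance)
  structure(
    list(lower = pooled$value - half, upper = pooled$value + half,
         level = level, method = method),
    class = "prediction_interval"
  )
}

#' Wald confidence interval for a pooled effect
#'
#' @param object A `pooled_effect`.
#' @param parm Ignored (single parameter).
#' @param level Coverage level.
#' @param ... Ignored.
#'
#' @return A 1x2 matrix of bounds on the log OR / SMD scale.
#' @export
confint.pooled_effect <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(object$variance)
  out <- matrix(c(object$value - half, object$value + half), nrow = 1,
                dimnames = list("value", c("lower", "upper")))
  out
}

#' @export
print.pooled_effect <- function(x, ...) {
  ci <- confint.pooled_effect(x)
  cat(sprintf("<pooled_effect> %s, k = %d\n", x$method, x$k))
  cat(sprintf("  value = %.4f [%.4f, %.4f], var = %.5f\n",
              x$value, ci[1], ci[2], x$variance))
  cat(sprintf("  tau2 = %.4f, Q = %.3f, I2 = %.1f%%\n", x$tau2, x$q_stat, x$i2))
  if (identical(x$scale, "log_odds_ratio"))
    cat(sprintf("  OR scale: %.3f [%.3f, %.3f]\n",
                exp(x$value), exp(ci[1]), exp(ci[2])))
  invisible(x)
}

#' @export
print.prediction_interval <- function(x, ...) {
  cat(sprintf("<prediction_interval> %.0f%% (%s): [%.4f, %.4f]\n",
              100 * x$level, x$method, x$lower, x$upper))
  invisible(x)
}
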