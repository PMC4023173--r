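# Two-step meta-epidemiological procedure: per-meta-analysis design
# contrasts (log ROR for binary outcomes, delta-SMD for continuous ones),
# then REML pooling of the contrasts across meta-analyses.

#' One meta-analysis containing both trial designs
#'
#' Bundles the per-trial effect estimates of a single meta-analysis together
#' with its identifier and outcome type. A meta-analysis is eligible for the
#' design contrast only if it retains at least one non-excluded trial of
#' each design.
#'
#' @param id Meta-analysis identifier.
#' @param outcome_type `"binary"` or `"continuous"`.
#' @param trials A list of [effect_estimate()] objects or an estimate data
#'   frame with columns `trial_id`, `design`, `scale`, `value`, `variance`,
#'   `excluded`.
#'
#' @return An object of class `meta_analysis_input`.
#' @export
meta_analysis_input <- function(id, outcome_type = c("binary", "continuous"),
                                trials) {
  outcome_type <- match.arg(outcome_type)
  if (!is.data.frame(trials)) {
    if (inherits(trials, "effect_estimate")) trials <- list(trials)
    if (!length(trials) || !all(vapply(trials, inherits, TRUE, "effect_estimate")))
      stop("`trials` must be effect_estimate objects or a data frame", call. = FALSE)
    trials <- data.frame(
      trial_id = vapply(trials, function(e) e$trial_id, ""),
      design = vapply(trials, function(e) e$design, ""),
      scale = vapply(trials, function(e) e$scale, ""),
      value = vapply(trials, function(e) e$value, 0),
      variance = vapply(trials, function(e) e$variance, 0),
      excluded = vapply(trials, function(e) e$excluded, TRUE),
      reason = vapply(trials, function(e) as.character(e$reason), ""),
      stringsAsFactors = FALSE
    )
  }
  need <- c("trial_id", "design", "value", "variance")
  if (!all(need %in% names(trials)))
    stop("trial table needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if (is.null(trials$excluded)) trials$excluded <- FALSE
  if (is.null(trials$scale))
    trials$scale <- if (outcome_type == "binary") "log_odds_ratio" else "smd"
  if (!all(trials$design %in% c("split_mouth", "parallel")))
    stop("trial designs must be 'split_mouth' or 'parallel'", call. = FALSE)
  sc <- unique(trials$scale[!trials$excluded])
  if (length(sc) > 1)
    stop("meta-analysis ", id, " mixes effect scales", call. = FALSE)
  structure(
    list(id = as.character(id), outcome_type = outcome_type, trials = trials,
         trial_ids = unique(trials$trial_id)),
    class = "meta_analysis_input"
  )
}

#' @export
print.meta_analysis_input <- function(x, ...) {
  keep <- !x$trials$excluded
  cat(sprintf("<meta_analysis_input> %s (%s): %d split-mouth, %d parallel (%d excluded)\n",
              x$id, x$outcome_type,
              sum(keep & x$trials$design == "split_mouth"),
              sum(keep & x$trials$design == "parallel"),
              sum(!keep)))
  invisible(x)
}

#' Is a meta-analysis eligible for the design contrast?
#'
#' @param meta A [meta_analysis_input()].
#' @return `TRUE` when at least one non-excluded trial of each design remains.
#' @export
is_eligible <- function(meta) {
  keep <- !meta$trials$excluded
  any(keep & meta$trials$design == "split_mouth") &&
    any(keep & meta$trials$design == "parallel")
}

#' Design contrast of one meta-analysis: log ROR or delta-SMD
#'
#' Pools the split-mouth and the parallel-arm trials separately within the
#' meta-analysis and contrasts the two summaries:
#' `value = summary(split-mouth) - summary(parallel)` on the log OR or SMD
#' scale, with `variance = var(split summary) + var(parallel summary)`.
#' A value below zero (ROR < 1, delta-SMD < 0) means the split-mouth trials
#' yielded the larger intervention effect. Single-trial subgroups pass
#' through as their own summary.
#'
#' @param meta A [meta_analysis_input()].
#' @param within_method Subgroup pooling: `"fixed"` (primary) or
#'   `"random_reml"` (sensitivity).
#'
#' @return A `design_contrast`, or `NULL` (with a warning naming the reason)
#'   when a design subgroup is empty after exclusions, so that callers can
#'   drop the meta-analysis.
#' @export
design_contrast <- function(meta, within_method = c("fixed", "random_reml")) {
  within_method <- match.arg(within_method)
  if (!inherits(meta, "meta_analysis_input"))
    stop("`meta` must be a meta_analysis_input", call. = FALSE)
  tr <- meta$trials[!meta$trials$excluded, , drop = FALSE]
  split <- tr[tr$design == "split_mouth", , drop = FALSE]
  para <- tr[tr$design == "parallel", , drop = FALSE]
  if (nrow(split) == 0 || nrow(para) == 0) {
    warning(sprintf("meta-analysis %s dropped: no %s trials left after exclusions",
                    meta$id,
                    if (nrow(split) == 0) "split-mouth" else "parallel-arm"),
            call. = FALSE)
    return(NULL)
  }
  pool_one <- function(df) {
    if (nrow(df) == 1 || within_method == "fixed") pool_fixed(df)
    else pool_random_reml(df)
  }
  ps <- pool_one(split)
  pp <- pool_one(para)
  structure(
    list(meta_id = meta$id, value = ps$value - pp$value,
         variance = ps$variance + pp$variance,
         k_split = nrow(split), k_parallel = nrow(para),
         scale = tr$scale[1], within_method = within_method,
         split_summary = ps, parallel_summary = pp),
    class = "design_contrast"
  )
}

#' @export
print.design_contrast <- function(x, ...) {
  lab <- if (x$scale == "log_odds_ratio") "log ROR" else "delta-SMD"
  cat(sprintf("<design_contrast> %s: %s = %.4f (var %.4f), k = %d + %d\n",
              x$meta_id, lab, x$value, x$variance, x$k_split, x$k_parallel))
  invisible(x)
}

contrasts_table <- function(contrasts) {
  if (inherits(contrasts, "design_contrast")) contrasts <- list(contrasts)
  contrasts <- Filter(Negate(is.null), contrasts)
  if (!all(vapply(contrasts, inherits, TRUE, "design_contrast")))
    stop("`contrasts` must be design_contrast objects", call. = FALSE)
  data.frame(
    meta_id = vapply(contrasts, function(x) x$meta_id, ""),
    value = vapply(contrasts, function(x) x$value, 0),
    variance = vapply(contrasts, function(x) x$variance, 0),
    scale = vapply(contrasts, function(x) x$scale, ""),
    stringsAsFactors = FALSE
  )
}

#' Pool design contrasts across meta-analyses
#'
#' The second step of the meta-epidemiological analysis: the per-meta-analysis
#' log RORs (or delta-SMDs) are combined by a REML random-effects model.
#' Reports the combined contrast with its 95% Wald CI, the 2-tailed z-test
#' p-value, tau^2 and I^2 across meta-analyses, and a z-method 95% prediction
#' interval for the contrast of a new meta-analysis.
#'
#' @param contrasts A list of `design_contrast` objects (at least two;
#'   `NULL` entries from dropped meta-analyses are ignored).
#' @param level Confidence / prediction level.
#'
#' @return A `metaepi_result`.
#' @export
pool_contrasts <- function(contrasts, level = 0.95) {
  df <- contrasts_table(contrasts)
  if (nrow(df) < 2)
    stop("pooling across meta-analyses needs at least two contrasts", call. = FALSE)
  sc <- unique(df$scale)
  if (length(sc) > 1)
    stop("contrasts mix scales; pool binary and continuous outcomes separately",
         call. = FALSE)
  pooled <- pool_random_reml(df[, c("value", "variance")])
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(pooled$variance)
  pi <- prediction_interval(pooled, level = level, method = "z")
  structure(
    list(combined = pooled$value,
         variance = pooled$variance,
         ci_lower = pooled$value - z * se,
         ci_upper = pooled$value + z * se,
         p_value = 2 * stats::pnorm(-abs(pooled$value / se)),
         tau2 = pooled$tau2, i2 = pooled$i2, q_stat = pooled$q_stat,
         prediction = pi, n_meta = nrow(df), level = level,
         scale = sc, contrasts = df),
    class = "metaepi_result"
  )
}

#' @export
print.metaepi_result <- function(x, ...) {
  ratio <- identical(x$scale, "log_odds_ratio")
  lab <- if (ratio) "ROR" else "delta-SMD"
  tf <- if (ratio) exp else identity
  cat(sprintf("<metaepi_result> %d meta-analyses\n", x$n_meta))
  cat(sprintf("  combined %s = %.3f [%.3f, %.3f], p = %.3f\n",
              lab, tf(x$combined), tf(x$ci_lower), tf(x$ci_upper), x$p_value))
  cat(sprintf("  tau2 = %.3f, I2 = %.1f%%\n", x$tau2, x$i2))
  cat(sprintf("  %.0f%% prediction interval: [%.3f, %.3f]\n",
              100 * x$prediction$level, tf(x$prediction$lower),
              tf(x$prediction$upper)))
  invisible(x)
}

#' Remove overlapping meta-analyses
#'
#' Meta-analyses sharing at least one trial are not independent; for every
#' overlapping pair the member with fewer trials is removed (ties keep the
#' earlier-listed meta-analysis), iterating until the retained collections
#' are pairwise disjoint. Input order is preserved.
#'
#' @param metas A list of [meta_analysis_input()] objects with populated
#'   `trial_ids`.
#'
#' @return The retained list, with a data frame of removals in
#'   `attr(, "dropped")` (columns `meta_id`, `overlaps_with`, `reason`).
#' @export
exclude_overlapping <- function(metas) {
  if (!all(vapply(metas, inherits, TRUE, "meta_analysis_input")))
    stop("`metas` must be meta_analysis_input objects", call. = FALSE)
  dropped <- data.frame(meta_id = character(), overlaps_with = character(),
                        reason = character(), stringsAsFactors = FALSE)
  repeat {
    removed <- FALSE
    for (i in seq_along(metas)) {
      for (j in seq_along(metas)) {
        if (j <= i) next
        shared <- intersect(metas[[i]]$trial_ids, metas[[j]]$trial_ids)
        if (!length(shared)) next
        ni <- length(metas[[i]]$trial_ids)
        nj <- length(metas[[j]]$trial_ids)
        loser <- if (ni < nj) i else j  # tie keeps the earlier-listed (i)
        keeper <- if (loser == i) j else i
        dropped <- rbind(dropped, data.frame(
          meta_id = metas[[loser]]$id, overlaps_with = metas[[keeper]]$id,
          reason = "overlap_fewer_trials", stringsAsFactors = FALSE))
        metas <- metas[-loser]
        removed <- TRUE
        break
      }
      if (removed) break
    }
    if (!removed) break
  }
  attr(metas, "dropped") <- dropped
  metas
}

#' Forest-plot table for the contrast analysis
#'
#' One row per meta-analysis (estimate, CI bounds and the random-effects
#' weight in percent), followed by the combined summary row and the
#' prediction-interval row, in the fixed column order
#' `meta_id, estimate, ci_lower, ci_upper, weight_pct, row_type`. All values
#' stay on the log OR / SMD scale; exponentiate for ratio-scale display.
#'
#' @param contrasts The contrasts that entered [pool_contrasts()].
#' @param result The corresponding `metaepi_result`.
#'
#' @return A data frame with `n_meta + 2` rows; per-meta weights sum to 100.
#' @export
forest_export <- function(contrasts, result) {
  if (!inherits(result, "metaepi_result"))
    stop("`result` must be a metaepi_result", call. = FALSE)
  df <- contrasts_table(contrasts)
  z <- stats::qnorm(1 - (1 - result$level) / 2)
  w <- 1 / (df$variance + result$tau2)
  se <- sqrt(df$variance)
  rows <- data.frame(
    meta_id = df$meta_id,
    estimate = df$value,
    ci_lower = df$value - z * se,
    ci_upper = df$value + z * se,
    weight_pct = 100 * w / sum(w),
    row_type = "meta",
    stringsAsFactors = FALSE
  )
  rows <- rbind(rows,
    data.frame(meta_id = "combined", estimate = result$combined,
               ci_lower = result$ci_lower, ci_upper = result$ci_upper,
               weight_pct = NA_real_, row_type = "summary",
               stringsAsFactors = FALSE),
    data.frame(meta_id = "prediction", estimate = NA_real_,
               ci_lower = result$prediction$lower,
               ci_upper = result$prediction$upper,
               weight_pct = NA_real_, row_type = "prediction",
               stringsAsFactors = FALSE))
  rows
}
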