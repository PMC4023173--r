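#' Log odds ratio for a parallel-arm trial
#'
#' Computes the log odds ratio and its large-sample variance
#' `1/a + 1/b + 1/c + 1/d` from the 2x2 table. When any cell is zero a
#' continuity correction (default 0.5) is added to all four cells before
#' computing. A trial with no events in either arm carries no information
#' about the odds ratio and is returned as an excluded estimate.
#'
#' @param arms A [binary_arms()] object.
#' @param correction Continuity correction added to every cell when any cell
#'   is zero.
#' @param trial_id Identifier carried through to the estimate.
#'
#' @return An [effect_estimate()] on the `log_odds_ratio` scale.
#' @examples
#' log_or_parallel(binary_arms(10, 20, 10, 20))
#' @export
log_or_parallel <- function(arms, correction = 0.5, trial_id = NA_character_) {
  if (!inherits(arms, "binary_arms"))
    stop("`arms` must be a binary_arms object", call. = FALSE)
  a <- arms$events_exp
  b <- arms$total_exp - arms$events_exp
  c_ <- arms$events_ctl
  d <- arms$total_ctl - arms$events_ctl
  if (a == 0 && c_ == 0) {
    return(effect_estimate(NA_real_, NA_real_, "log_odds_ratio", "parallel",
                           trial_id, excluded = TRUE, reason = "double_zero"))
  }
  if (b == 0 && d == 0)
    stop("all participants had events in both arms: no information about the odds ratio",
         call. = FALSE)
  if (min(a, b, c_, d) == 0) {
    a <- a + correction; b <- b + correction
    c_ <- c_ + correction; d <- d + correction
  }
  effect_estimate(
    value = log((a * d) / (b * c_)),
    variance = 1 / a + 1 / b + 1 / c_ + 1 / d,
    scale = "log_odds_ratio", design = "parallel", trial_id = trial_id
  )
}

#' Marginal log odds ratio for a split-mouth trial
#'
#' The marginal odds ratio compares the two site-level marginal event
#' probabilities `p1 = P(event at experimental site)` and
#' `p2 = P(event at control site)` of a paired design,
#' `OR = p1(1 - p2) / (p2(1 - p1))`. Its delta-method variance accounts for
#' the within-patient dependence through the covariance of the two margins:
#'
#' `var = (1/n) * (1/(p1 q1) + 1/(p2 q2) - 2 (pi11 pi00 - pi10 pi01) / (p1 q1 p2 q2))`
#'
#' with `q = 1 - p` and `pi` the joint cell proportions; the cross term
#' vanishes under site independence and shrinks the variance under the
#' positive dependence typical of split-mouth data. If any marginal count
#' is zero, or both discordant cells are zero (which makes the delta-method
#' variance degenerate), 0.5 is added to every joint cell first. A table
#' with events at no site (or at every site) is returned as excluded.
#'
#' @param table A [paired_binary_table()].
#' @param trial_id Identifier carried through to the estimate.
#'
#' @return An [effect_estimate()] on the `log_odds_ratio` scale with
#'   `design = "split_mouth"`.
#' @examples
#' marginal_log_or_split_mouth(paired_binary_table(30, 10, 5, 55))
#' @export
marginal_log_or_split_mouth <- function(table, trial_id = NA_character_) {
  if (!inherits(table, "paired_binary_table"))
    stop("`table` must be a paired_binary_table", call. = FALSE)
  cells <- c(table$n11, table$n10, table$n01, table$n00)
  ev_exp <- cells[1] + cells[2]
  ev_ctl <- cells[1] + cells[3]
  ne_exp <- cells[3] + cells[4]
  ne_ctl <- cells[2] + cells[4]
  if (ev_exp == 0 && ev_ctl == 0) {
    return(effect_estimate(NA_real_, NA_real_, "log_odds_ratio", "split_mouth",
                           trial_id, excluded = TRUE, reason = "double_zero"))
  }
  if (ne_exp == 0 && ne_ctl == 0) {
    return(effect_estimate(NA_real_, NA_real_, "log_odds_ratio", "split_mouth",
                           trial_id, excluded = TRUE, reason = "all_events"))
  }
  # correct only when the estimate or its variance is degenerate: a zero
  # marginal count, or zero discordant cells (perfectly correlated equal
  # margins, which zero the delta-method variance); other zero joint cells
  # leave both the estimate and its variance well-defined and uncorrected
  if (min(ev_exp, ev_ctl, ne_exp, ne_ctl) == 0 ||
      (cells[2] == 0 && cells[3] == 0))
    cells <- cells + 0.5
  n <- sum(cells)
  pi <- cells / n
  p1 <- pi[1] + pi[2]
  p2 <- pi[1] + pi[3]
  if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1) {
    return(effect_estimate(NA_real_, NA_real_, "log_odds_ratio", "split_mouth",
                           trial_id, excluded = TRUE, reason = "degenerate_margins"))
  }
  q1 <- 1 - p1
  q2 <- 1 - p2
  value <- log((p1 * q2) / (p2 * q1))
  covterm <- pi[1] * pi[4] - pi[2] * pi[3]  # = pi11 - p1 p2
  variance <- (1 / n) * (1 / (p1 * q1) + 1 / (p2 * q2) -
                           2 * covterm / (p1 * q1 * p2 * q2))
  effect_estimate(value, variance, "log_odds_ratio", "split_mouth", trial_id)
}

#' Reconstruct joint paired cells from marginal counts and a correlation
#'
#' When a split-mouth report gives only the marginal event counts per site,
#' the joint 2x2 cell distribution can be reconstructed from an assumed
#' within-patient correlation: `pi11 = p1 p2 + rho * sqrt(p1 q1 p2 q2)` and
#' the remaining cells by the margins. `pi11` is clamped to the Frechet
#' bounds `[max(0, p1 + p2 - 1), min(p1, p2)]`; a `rho` outside the feasible
#' range for the given margins is clamped with a warning, not an error.
#' Cells are returned as proportions times `n` without rounding, so the
#' margins of the output reproduce the inputs exactly whenever `rho` is
#' feasible.
#'
#' @param events_exp,events_ctl Marginal event counts at each site.
#' @param n Number of patients.
#' @param rho Assumed within-patient correlation.
#'
#' @return A [paired_binary_table()] with (possibly fractional) cells.
#' @examples
#' paired_cells_from_marginals(events_exp = 40, events_ctl = 35, n = 100, rho = 0.5)
#' @export
paired_cells_from_marginals <- function(events_exp, events_ctl, n, rho) {
  stop_if_not(is_count(n))
  if (n <= 0) stop("`n` must be positive", call. = FALSE)
  if (events_exp < 0 || events_ctl < 0 || events_exp > n || events_ctl > n)
    stop("event counts must lie in [0, n]", call. = FALSE)
  if (!is.finite(rho) || rho < -1 || rho > 1)
    stop("`rho` must lie in [-1, 1]", call. = FALSE)
  p1 <- events_exp / n
  p2 <- events_ctl / n
  q1 <- 1 - p1
  q2 <- 1 - p2
  s <- sqrt(p1 * q1 * p2 * q2)
  pi11 <- p1 * p2 + rho * s
  lo <- max(0, p1 + p2 - 1)
  hi <- min(p1, p2)
  if (pi11 < lo - 1e-12 || pi11 > hi + 1e-12) {
    warning(sprintf(
      "rho = %.3f infeasible for margins (p1 = %.3f, p2 = %.3f); clamped to the Frechet bounds",
      rho, p1, p2), call. = FALSE)
  }
  pi11 <- min(max(pi11, lo), hi)
  paired_binary_table(
    n11 = pi11 * n,
    n10 = (p1 - pi11) * n,
    n01 = (p2 - pi11) * n,
    n00 = (1 - p1 - p2 + pi11) * n
  )
}

#' Standardized mean difference for a parallel-arm trial
#'
#' Cohen's d: the mean difference divided by the pooled (df-weighted)
#' standard deviation, with variance
#' `(n_exp + n_ctl)/(n_exp n_ctl) + d^2 / (2 (n_exp + n_ctl))`.
#' No small-sample (Hedges) correction is applied.
#'
#' @param arms A [continuous_arms()] object.
#' @param trial_id Identifier carried through to the estimate.
#'
#' @return An [effect_estimate()] on the `smd` scale.
#' @export
smd_parallel <- function(arms, trial_id = NA_character_) {
  if (!inherits(arms, "continuous_arms"))
    stop("`arms` must be a continuous_arms object", call. = FALSE)
  n1 <- arms$n_exp
  n0 <- arms$n_ctl
  sp2 <- ((n1 - 1) * arms$sd_exp^2 + (n0 - 1) * arms$sd_ctl^2) / (n1 + n0 - 2)
  if (!is.finite(sp2) || sp2 <= 0)
    stop("pooled SD is zero or undefined", call. = FALSE)
  d <- (arms$mean_exp - arms$mean_ctl) / sqrt(sp2)
  variance <- (n1 + n0) / (n1 * n0) + d^2 / (2 * (n1 + n0))
  effect_estimate(d, variance, "smd", "parallel", trial_id)
}

#' Standardized mean difference for a split-mouth trial
#'
#' Standardizes the within-patient mean difference by the single-site
#' standard deviation so that the estimate is comparable to a parallel-arm
#' Cohen's d, and scales the paired-difference variance by the
#' within-patient correlation:
#'
#' `d = (mean_exp - mean_ctl) / s_within`,
#' `var = (1/n + d^2/(2n)) * 2 (1 - rho)`.
#'
#' `s_within` is the pooled single-site SD `sqrt((sd_exp^2 + sd_ctl^2)/2)`;
#' when the report gives the SD of the within-patient differences instead,
#' `s_within = sd_diff / sqrt(2 (1 - rho))` using the configured `rho` (the
#' inverse of the Follmann relation, see [follmann_impute_sd_diff()]). The
#' variance is strictly decreasing in `rho`: the stronger the within-patient
#' correlation, the more precise the paired design.
#'
#' @param data A [paired_continuous()] object.
#' @param rho Correlation used when the object does not carry one; default
#'   0.5 with 0 and 0.25 as conventional sensitivity settings.
#' @param trial_id Identifier carried through to the estimate.
#'
#' @return An [effect_estimate()] on the `smd` scale with
#'   `design = "split_mouth"`.
#' @export
smd_split_mouth <- function(data, rho = 0.5, trial_id = NA_character_) {
  if (!inherits(data, "paired_continuous"))
    stop("`data` must be a paired_continuous object", call. = FALSE)
  if (!is.null(data$rho)) rho <- data$rho
  if (!is.finite(rho) || rho < -1 || rho > 1)
    stop("`rho` must lie in [-1, 1]", call. = FALSE)
  if (!is.null(data$sd_diff)) {
    if (rho >= 1)
      stop("rho = 1 leaves the single-site SD undefined when only `sd_diff` is given",
           call. = FALSE)
    s_within <- data$sd_diff / sqrt(2 * (1 - rho))
  } else {
    s_within <- sqrt((data$sd_exp^2 + data$sd_ctl^2) / 2)
  }
  if (!is.finite(s_within) || s_within <= 0)
    stop("within-site SD is zero or undefined", call. = FALSE)
  d <- (data$mean_exp - data$mean_ctl) / s_within
  variance <- (1 / data$n + d^2 / (2 * data$n)) * 2 * (1 - rho)
  if (variance <= 0)
    stop("rho = 1 gives a degenerate (zero) sampling variance", call. = FALSE)
  effect_estimate(d, variance, "smd", "split_mouth", trial_id)
}

#' Impute the SD of within-patient differences from site SDs
#'
#' `sd_diff = sqrt(sd_exp^2 + sd_ctl^2 - 2 rho sd_exp sd_ctl)`, the standard
#' imputation for paired designs whose reports omit the difference SD.
#'
#' @param sd_exp,sd_ctl Site standard deviations (strictly positive).
#' @param rho Within-patient correlation in `[-1, 1]`.
#'
#' @return The imputed difference SD.
#' @examples
#' follmann_impute_sd_diff(3, 4, 0)  # 5
#' @export
follmann_impute_sd_diff <- function(sd_exp, sd_ctl, rho) {
  if (!is.finite(sd_exp) || !is.finite(sd_ctl) || sd_exp <= 0 || sd_ctl <= 0)
    stop("SDs must be strictly positive", call. = FALSE)
  if (!is.finite(rho) || rho < -1 || rho > 1)
    stop("`rho` must lie in [-1, 1]", call. = FALSE)
  sqrt(sd_exp^2 + sd_ctl^2 - 2 * rho * sd_exp * sd_ctl)
}

#' Orient an effect estimate so that negative values mean benefit
#'
#' All analyses use the convention that OR < 1 (log OR < 0) and SMD < 0
#' indicate a beneficial experimental intervention. Outcomes coded with
#' benefit in the higher direction are negated; orientation is recorded on
#' the estimate and applying it again is a no-op.
#'
#' @param estimate An [effect_estimate()].
#' @param beneficial_direction `"lower"` if the raw coding already has
#'   benefit as lower values, `"higher"` if it must be flipped.
#'
#' @return The oriented [effect_estimate()]; variance unchanged.
#' @export
orient_effect <- function(estimate, beneficial_direction = c("lower", "higher")) {
  beneficial_direction <- match.arg(beneficial_direction)
  if (!inherits(estimate, "effect_estimate"))
    stop("`estimate` must be an effect_estimate", call. = FALSE)
  if (estimate$oriented)
    return(estimate)
  if (beneficial_direction == "higher" && !estimate$excluded)
    estimate$value <- -estimate$value
  estimate$oriented <- TRUE
  estimate
}
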