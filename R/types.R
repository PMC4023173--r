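#' Arm-level binary outcome data from a parallel-arm trial
#'
#' Container for the 2x2 table of a two-arm trial with a binary outcome:
#' event counts and arm sizes for the experimental and control arms.
#'
#' @param events_exp,events_ctl Number of events in each arm.
#' @param total_exp,total_ctl Number of participants randomized to each arm.
#'
#' @return An object of class `binary_arms`.
#' @examples
#' binary_arms(events_exp = 10, total_exp = 20, events_ctl = 10, total_ctl = 20)
#' @export
binary_arms <- function(events_exp, total_exp, events_ctl, total_ctl) {
  stop_if_not(is_count(events_exp), is_count(events_ctl),
              is_count(total_exp), is_count(total_ctl))
  if (total_exp <= 0 || total_ctl <= 0)
    stop("arm totals must be positive", call. = FALSE)
  if (events_exp > total_exp || events_ctl > total_ctl)
    stop("events cannot exceed the arm total", call. = FALSE)
  structure(
    list(events_exp = events_exp, total_exp = total_exp,
         events_ctl = events_ctl, total_ctl = total_ctl),
    class = "binary_arms"
  )
}

#' Joint cell counts of a paired binary outcome from a split-mouth trial
#'
#' In a split-mouth trial each patient carries both the experimental and the
#' control site, so the binary outcome forms a joint 2x2 distribution over
#' patients. Cells may be fractional: tables reconstructed from marginal
#' counts and an assumed within-patient correlation are kept on the
#' proportion scale without rounding, since all downstream formulas consume
#' cell proportions only.
#'
#' @param n11 Patients with an event at both sites.
#' @param n10 Patients with an event at the experimental site only.
#' @param n01 Patients with an event at the control site only.
#' @param n00 Patients with an event at neither site.
#'
#' @return An object of class `paired_binary_table` with a derived total `n`.
#' @examples
#' paired_binary_table(n11 = 30, n10 = 10, n01 = 5, n00 = 55)
#' @export
paired_binary_table <- function(n11, n10, n01, n00) {
  cells <- c(n11, n10, n01, n00)
  if (length(cells) != 4L || !all(is.finite(cells)))
    stop("all four cells are required and must be finite", call. = FALSE)
  if (any(cells < 0))
    stop("cell counts must be non-negative", call. = FALSE)
  n <- sum(cells)
  if (n <= 0)
    stop("table total must be positive", call. = FALSE)
  structure(
    list(n11 = n11, n10 = n10, n01 = n01, n00 = n00, n = n),
    class = "paired_binary_table"
  )
}

#' Arm-level continuous outcome data from a parallel-arm trial
#'
#' @param mean_exp,mean_ctl Outcome means per arm, in outcome units.
#' @param sd_exp,sd_ctl Outcome standard deviations per arm (strictly positive).
#' @param n_exp,n_ctl Participants per arm.
#'
#' @return An object of class `continuous_arms`.
#' @export
continuous_arms <- function(mean_exp, sd_exp, n_exp, mean_ctl, sd_ctl, n_ctl) {
  stop_if_not(is.numeric(mean_exp), is.numeric(mean_ctl),
              is_count(n_exp), is_count(n_ctl))
  if (!is.finite(sd_exp) || !is.finite(sd_ctl) || sd_exp <= 0 || sd_ctl <= 0)
    stop("arm SDs must be strictly positive", call. = FALSE)
  if (n_exp <= 0 || n_ctl <= 0)
    stop("arm sizes must be positive", call. = FALSE)
  structure(
    list(mean_exp = mean_exp, sd_exp = sd_exp, n_exp = n_exp,
         mean_ctl = mean_ctl, sd_ctl = sd_ctl, n_ctl = n_ctl),
    class = "continuous_arms"
  )
}

#' Summary statistics of a paired continuous outcome from a split-mouth trial
#'
#' Each of the `n` patients contributes one experimental-site and one
#' control-site measurement. The within-patient dependence is carried either
#' by the correlation `rho` between the two site outcomes or, when reported,
#' by the standard deviation `sd_diff` of the within-patient differences.
#' When both are supplied, `sd_diff` takes precedence for standardization
#' and `rho` still scales the sampling variance (see
#' [smd_split_mouth()]).
#'
#' @param mean_exp,mean_ctl Site outcome means.
#' @param sd_exp,sd_ctl Site outcome standard deviations (needed when
#'   `sd_diff` is absent).
#' @param n Number of patients (pairs); must exceed 1.
#' @param rho Within-patient correlation in `[-1, 1]`.
#' @param sd_diff Optional standard deviation of within-patient differences.
#'
#' @return An object of class `paired_continuous`.
#' @export
paired_continuous <- function(mean_exp, mean_ctl, sd_exp = NULL, sd_ctl = NULL,
                              n, rho = NULL, sd_diff = NULL) {
  stop_if_not(is.numeric(mean_exp), is.numeric(mean_ctl), is_count(n))
  if (n <= 1)
    stop("a paired trial needs more than one patient", call. = FALSE)
  if (is.null(rho) && is.null(sd_diff))
    stop("one of `rho` or `sd_diff` is required", call. = FALSE)
  if (!is.null(rho) && (!is.finite(rho) || rho < -1 || rho > 1))
    stop("`rho` must lie in [-1, 1]", call. = FALSE)
  if (!is.null(sd_diff) && (!is.finite(sd_diff) || sd_diff <= 0))
    stop("`sd_diff` must be strictly positive", call. = FALSE)
  if (is.null(sd_diff) && (is.null(sd_exp) || is.null(sd_ctl)))
    stop("site SDs are required when `sd_diff` is absent", call. = FALSE)
  for (s in c(sd_exp, sd_ctl))
    if (!is.finite(s) || s <= 0)
      stop("site SDs must be strictly positive", call. = FALSE)
  structure(
    list(mean_exp = mean_exp, mean_ctl = mean_ctl,
         sd_exp = sd_exp, sd_ctl = sd_ctl,
         n = n, rho = rho, sd_diff = sd_diff),
    class = "paired_continuous"
  )
}

#' Per-trial effect estimate on the analysis scale
#'
#' The common currency of the pipeline: a log odds ratio or a standardized
#' mean difference (Cohen's d) with its sampling variance, tagged with the
#' trial design it came from. Trials that carry no information (for a binary
#' outcome, no events in either arm or at either site) are represented as
#' excluded estimates with a reason rather than dropped silently.
#'
#' @param value Effect on the log OR or SMD scale.
#' @param variance Sampling variance (strictly positive unless excluded).
#' @param scale `"log_odds_ratio"` or `"smd"`.
#' @param design `"split_mouth"` or `"parallel"`.
#' @param trial_id Trial identifier.
#' @param excluded Logical exclusion flag.
#' @param reason Machine-readable reason when excluded.
#' @param oriented Whether [orient_effect()] has already been applied.
#'
#' @return An object of class `effect_estimate`.
#' @export
effect_estimate <- function(value, variance,
                            scale = c("log_odds_ratio", "smd"),
                            design = c("parallel", "split_mouth"),
                            trial_id = NA_character_,
                            excluded = FALSE, reason = NA_character_,
                            oriented = FALSE) {
  scale <- match.arg(scale)
  design <- match.arg(design)
  if (!excluded) {
    if (!is.finite(value))
      stop("effect value must be finite", call. = FALSE)
    if (!is.finite(variance) || variance <= 0)
      stop("variance must be strictly positive", call. = FALSE)
  }
  structure(
    list(value = value, variance = variance, scale = scale, design = design,
         trial_id = as.character(trial_id), excluded = isTRUE(excluded),
         reason = reason, oriented = isTRUE(oriented)),
    class = "effect_estimate"
  )
}

#' @export
print.effect_estimate <- function(x, ...) {
  lab <- if (x$scale == "log_odds_ratio") "log OR" else "SMD"
  if (x$excluded) {
    cat(sprintf("<effect_estimate> trial %s (%s): excluded [%s]\n",
                x$trial_id, x$design, x$reason))
  } else {
    cat(sprintf("<effect_estimate> trial %s (%s): %s = %.4f (var %.4f)\n",
                x$trial_id, x$design, lab, x$value, x$variance))
  }
  invisible(x)
}

#' @export
print.paired_binary_table <- function(x, ...) {
  cat(sprintf("<paired_binary_table> n = %g\n", x$n))
  m <- matrix(c(x$n11, x$n10, x$n01, x$n00), 2, 2, byrow = TRUE,
              dimnames = list(exp = c("event", "no event"),
                              ctl = c("event", "no event")))
  print(m)
  invisible(x)
}

# internal arg checks -------------------------------------------------------

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 &&
    abs(x - round(x)) < 1e-8
}

stop_if_not <- function(...) {
  ok <- c(...)
  if (!all(ok)) {
    labs <- sapply(substitute(list(...))[-1], deparse)
    stop("invalid input: ", paste(labs[!ok], collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
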