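# Synthetic meta-epidemiological datasets with the random-effects structure
# the two-step analysis assumes: a heterogeneous true effect per
# meta-analysis, an additive design effect on the log OR / SMD scale with
# its own heterogeneity, and within-patient correlation in the split-mouth
# trials.

#' Configuration of a synthetic meta-epidemiological dataset
#'
#' Defaults mirror the descriptive scale of published oral-health
#' meta-analyses that mix both designs: around 15 meta-analyses, 2-4 trials
#' per design, parallel-arm trials of about 40 participants and split-mouth
#' trials of about half as many patients, and a within-patient correlation
#' of 0.5. The default design effect is null (`delta = 0`, `tau2_delta = 0`):
#' under the defaults the two designs estimate the same intervention effect.
#'
#' @param n_meta Number of meta-analyses.
#' @param trials_per_design Integer range `c(min, max)` of trials per design
#'   within one meta-analysis.
#' @param patients_per_trial Integer range of the total size of a
#'   parallel-arm trial (split across two arms); split-mouth trials enrol
#'   about half as many patients, each contributing both sites.
#' @param mu Mean true intervention effect across meta-analyses (log OR for
#'   binary outcomes, SMD for continuous ones).
#' @param tau2_effect Between-meta-analysis variance of the true effect.
#' @param delta True design effect: the amount added to the split-mouth
#'   trials' effect (log ROR or delta-SMD scale).
#' @param tau2_delta Between-meta-analysis variance of the design effect.
#' @param rho Within-patient correlation of the split-mouth outcomes.
#' @param control_risk Control-group event risk (binary outcomes only).
#' @param outcome_type `"binary"` or `"continuous"`.
#' @param seed Integer seed making the dataset reproducible.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_meta = 15,
                              trials_per_design = c(2, 4),
                              patients_per_trial = c(30, 60),
                              mu = -0.3,
                              tau2_effect = 0.1,
                              delta = 0,
                              tau2_delta = 0,
                              rho = 0.5,
                              control_risk = 0.3,
                              outcome_type = c("binary", "continuous"),
                              seed = 42) {
  outcome_type <- match.arg(outcome_type)
  stop_if_not(is_count(n_meta), n_meta >= 1)
  for (rng in list(trials_per_design, patients_per_trial)) {
    if (length(rng) != 2 || any(!is.finite(rng)) || rng[1] > rng[2] || rng[1] < 1)
      stop("ranges must be c(min, max) with 1 <= min <= max", call. = FALSE)
  }
  if (tau2_effect < 0 || tau2_delta < 0)
    stop("heterogeneity variances must be non-negative", call. = FALSE)
  if (!is.finite(rho) || rho < -1 || rho > 1)
    stop("`rho` must lie in [-1, 1]", call. = FALSE)
  if (control_risk <= 0 || control_risk >= 1)
    stop("`control_risk` must lie in (0, 1)", call. = FALSE)
  structure(
    list(n_meta = n_meta, trials_per_design = as.integer(trials_per_design),
         patients_per_trial = as.integer(patients_per_trial),
         mu = mu, tau2_effect = tau2_effect, delta = delta,
         tau2_delta = tau2_delta, rho = rho, control_risk = control_risk,
         outcome_type = outcome_type, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# joint cell probabilities (pi11, pi10, pi01, pi00) for margins p1, p2 and
# within-patient correlation rho, clamped to the Frechet bounds
joint_cell_probs <- function(p1, p2, rho, warn = TRUE) {
  q1 <- 1 - p1
  q2 <- 1 - p2
  pi11 <- p1 * p2 + rho * sqrt(p1 * q1 * p2 * q2)
  lo <- max(0, p1 + p2 - 1)
  hi <- min(p1, p2)
  if (warn && (pi11 < lo - 1e-12 || pi11 > hi + 1e-12))
    warning(sprintf("rho = %.3f infeasible for margins (%.3f, %.3f); clamped",
                    rho, p1, p2), call. = FALSE)
  pi11 <- min(max(pi11, lo), hi)
  c(pi11, p1 - pi11, p2 - pi11, 1 - p1 - p2 + pi11)
}

#' Simulate the joint outcome table of one split-mouth binary trial
#'
#' Draws the four joint cells from a multinomial distribution whose cell
#' probabilities follow the margins `p1` (experimental site), `p2` (control
#' site) and within-patient correlation `rho`. An infeasible `rho` is
#' clamped to the Frechet bounds with a warning.
#'
#' @param n Number of patients.
#' @param p1,p2 Marginal event probabilities at the experimental and control
#'   site.
#' @param rho Within-patient correlation.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#'
#' @return A [paired_binary_table()].
#' @export
simulate_paired_binary_trial <- function(n, p1, p2, rho, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stop_if_not(is_count(n), n >= 1)
  probs <- joint_cell_probs(p1, p2, rho)
  cells <- as.vector(stats::rmultinom(1, n, probs))
  paired_binary_table(cells[1], cells[2], cells[3], cells[4])
}

#' Simulate one split-mouth continuous trial and return its summaries
#'
#' Each patient's two site outcomes are bivariate normal with unit SDs,
#' mean difference `effect` (experimental minus control) and correlation
#' `rho`. Sample summary statistics (site means and SDs, the empirical
#' within-patient correlation and difference SD) are returned, as a trial
#' report would give them.
#'
#' @param n Number of patients.
#' @param effect True mean difference between sites, in SD units.
#' @param rho True within-patient correlation (|rho| < 1).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#'
#' @return A [paired_continuous()] carrying the sample statistics.
#' @export
simulate_paired_continuous_trial <- function(n, effect, rho, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stop_if_not(is_count(n), n >= 2)
  if (!is.finite(rho) || abs(rho) >= 1)
    stop("`rho` must satisfy |rho| < 1", call. = FALSE)
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  x_ctl <- z1
  x_exp <- effect + rho * z1 + sqrt(1 - rho^2) * z2
  paired_continuous(
    mean_exp = mean(x_exp), mean_ctl = mean(x_ctl),
    sd_exp = stats::sd(x_exp), sd_ctl = stats::sd(x_ctl),
    n = n,
    rho = stats::cor(x_exp, x_ctl),
    sd_diff = stats::sd(x_exp - x_ctl)
  )
}

#' Simulate a full meta-epidemiological dataset
#'
#' For each meta-analysis `m` a true effect `theta_m ~ N(mu, tau2_effect)`
#' and a design offset `delta_m ~ N(delta, tau2_delta)` are drawn; its
#' parallel-arm trials estimate `theta_m` and its split-mouth trials
#' `theta_m + delta_m`. Binary trials follow binomial / multinomial
#' mechanics (effects injected on the log-odds scale from the control
#' risk), continuous trials the normal generators with unit SDs. The whole
#' dataset is reproducible from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param output `"meta_inputs"` (default) for ready-to-contrast
#'   [meta_analysis_input()] objects, or `"records"` for the flat trial
#'   record table in the CSV schema of [read_trials()].
#'
#' @return A list of [meta_analysis_input()] objects, or a trial record
#'   data frame.
#' @export
simulate_metaepi_dataset <- function(config,
                                     output = c("meta_inputs", "records")) {
  output <- match.arg(output)
  if (!inherits(config, "simulation_config"))
    stop("`config` must be a simulation_config", call. = FALSE)
  set.seed(config$seed)
  records <- simulate_records(config)
  if (output == "records") return(records)
  effects <- compute_trial_effects(records, rho = config$rho)
  as_meta_inputs(effects)
}

# draw all trial records for one dataset; RNG state is taken as-is
simulate_records <- function(config) {
  nm <- config$n_meta
  tr <- config$trials_per_design
  pr <- config$patients_per_trial
  theta <- stats::rnorm(nm, config$mu, sqrt(config$tau2_effect))
  delta_m <- stats::rnorm(nm, config$delta, sqrt(config$tau2_delta))
  k_split <- sample(seq(tr[1], tr[2]), nm, replace = TRUE)
  k_para <- sample(seq(tr[1], tr[2]), nm, replace = TRUE)
  total <- sum(k_split) + sum(k_para)

  rec <- empty_records(total)
  row <- 0L
  for (m in seq_len(nm)) {
    eff_split <- theta[m] + delta_m[m]
    eff_para <- theta[m]
    for (j in seq_len(k_split[m])) {
      row <- row + 1L
      rec$meta_id[row] <- sprintf("MA%02d", m)
      rec$trial_id[row] <- sprintf("MA%02d_S%d", m, j)
      rec$design[row] <- "split_mouth"
      rec$outcome_type[row] <- config$outcome_type
      n_pat <- max(2L, round(sample(seq(pr[1], pr[2]), 1) / 2))
      if (config$outcome_type == "binary") {
        p2 <- config$control_risk
        p1 <- stats::plogis(stats::qlogis(p2) + eff_split)
        tab <- simulate_paired_binary_trial(n_pat, p1, p2, config$rho)
        rec$n11[row] <- tab$n11; rec$n10[row] <- tab$n10
        rec$n01[row] <- tab$n01; rec$n00[row] <- tab$n00
      } else {
        pc <- simulate_paired_continuous_trial(n_pat, eff_split, config$rho)
        rec$mean_exp[row] <- pc$mean_exp; rec$mean_ctl[row] <- pc$mean_ctl
        rec$sd_exp[row] <- pc$sd_exp; rec$sd_ctl[row] <- pc$sd_ctl
        rec$n_pairs[row] <- n_pat
      }
    }
    for (j in seq_len(k_para[m])) {
      row <- row + 1L
      rec$meta_id[row] <- sprintf("MA%02d", m)
      rec$trial_id[row] <- sprintf("MA%02d_P%d", m, j)
      rec$design[row] <- "parallel"
      rec$outcome_type[row] <- config$outcome_type
      n_arm <- max(2L, round(sample(seq(pr[1], pr[2]), 1) / 2))
      if (config$outcome_type == "binary") {
        p_ctl <- config$control_risk
        p_exp <- stats::plogis(stats::qlogis(p_ctl) + eff_para)
        rec$events_exp[row] <- stats::rbinom(1, n_arm, p_exp)
        rec$total_exp[row] <- n_arm
        rec$events_ctl[row] <- stats::rbinom(1, n_arm, p_ctl)
        rec$total_ctl[row] <- n_arm
      } else {
        xe <- stats::rnorm(n_arm, eff_para, 1)
        xc <- stats::rnorm(n_arm, 0, 1)
        rec$mean_exp[row] <- mean(xe); rec$sd_exp[row] <- stats::sd(xe)
        rec$n_exp[row] <- n_arm
        rec$mean_ctl[row] <- mean(xc); rec$sd_ctl[row] <- stats::sd(xc)
        rec$n_ctl[row] <- n_arm
      }
    }
  }
  rec$beneficial_direction <- rep("lower", total)
  out <- as.data.frame(rec, stringsAsFactors = FALSE)
  class(out) <- c("trial_records", class(out))
  out
}

empty_records <- function(n) {
  list(
    meta_id = character(n), trial_id = character(n), design = character(n),
    outcome_type = character(n), beneficial_direction = character(n),
    events_exp = rep(NA_real_, n), total_exp = rep(NA_real_, n),
    events_ctl = rep(NA_real_, n), total_ctl = rep(NA_real_, n),
    n11 = rep(NA_real_, n), n10 = rep(NA_real_, n),
    n01 = rep(NA_real_, n), n00 = rep(NA_real_, n),
    n_pairs = rep(NA_real_, n),
    mean_exp = rep(NA_real_, n), sd_exp = rep(NA_real_, n),
    n_exp = rep(NA_real_, n),
    mean_ctl = rep(NA_real_, n), sd_ctl = rep(NA_real_, n),
    n_ctl = rep(NA_real_, n),
    rho = rep(NA_real_, n), sd_diff = rep(NA_real_, n),
    publication_year = rep(NA_integer_, n)
  )
}
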