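# Flat CSV schema for trial records, effect computation routing, and the
# end-to-end pipeline: read -> per-trial effects -> exclusions -> design
# contrasts -> pooled contrast -> CSV/JSON reports.

schema_columns <- function(schema_version = "1") {
  if (!identical(as.character(schema_version), "1"))
    stop("unknown schema version: ", schema_version, call. = FALSE)
  c("meta_id", "trial_id", "design", "outcome_type", "beneficial_direction",
    "events_exp", "total_exp", "events_ctl", "total_ctl",
    "n11", "n10", "n01", "n00", "n_pairs",
    "mean_exp", "sd_exp", "n_exp", "mean_ctl", "sd_ctl", "n_ctl",
    "rho", "sd_diff", "publication_year")
}

#' Read trial records from the flat CSV schema
#'
#' One row per trial; the populated columns must match the trial's
#' `(design, outcome_type)` combination: arm-level 2x2 counts for parallel
#' binary trials; joint cells `n11..n00` (or marginal events plus `n_pairs`
#' and optionally `rho`) for split-mouth binary trials; arm means/SDs/sizes
#' for parallel continuous trials; site means plus `n_pairs` and site SDs
#' and/or `sd_diff` for split-mouth continuous ones. Empty cells are read as
#' missing (`NA`), distinct from zero. Unknown or missing header columns are
#' a hard error; invalid rows are reported with their line numbers and abort
#' the read unless `skip_invalid = TRUE`.
#'
#' @param path CSV file path (RFC-4180, UTF-8, `.` decimal separator).
#' @param schema_version Schema dialect; only `"1"` is defined.
#' @param skip_invalid Drop invalid rows with a warning instead of aborting.
#'
#' @return A validated `trial_records` data frame.
#' @export
read_trials <- function(path, schema_version = "1", skip_invalid = FALSE) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  cols <- schema_columns(schema_version)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  unknown <- setdiff(names(df), cols)
  missing <- setdiff(cols, names(df))
  if (length(unknown) || length(missing))
    stop("header does not match schema ", schema_version,
         if (length(unknown)) paste0("; unknown columns: ",
                                     paste(unknown, collapse = ", ")),
         if (length(missing)) paste0("; missing columns: ",
                                     paste(missing, collapse = ", ")),
         call. = FALSE)
  df <- df[, cols]
  num_cols <- setdiff(cols, c("meta_id", "trial_id", "design", "outcome_type",
                              "beneficial_direction"))
  for (cc in num_cols) df[[cc]] <- as.numeric(df[[cc]])
  for (cc in c("meta_id", "trial_id", "design", "outcome_type",
               "beneficial_direction")) df[[cc]] <- as.character(df[[cc]])

  problems <- validate_records(df)
  if (length(problems)) {
    if (skip_invalid) {
      bad <- as.integer(sub(":.*", "", names(problems)))
      warning("dropped ", length(unique(bad)), " invalid row(s):\n  ",
              paste(problems, collapse = "\n  "), call. = FALSE)
      df <- df[-unique(bad), , drop = FALSE]
    } else {
      stop("invalid rows in ", path, ":\n  ",
           paste(problems, collapse = "\n  "),
           "\n(use skip_invalid = TRUE to drop them)", call. = FALSE)
    }
  }
  class(df) <- c("trial_records", class(df))
  df
}

# returns a named character vector of row-level problems; names hold the
# data row index, messages the file line number (header = line 1)
validate_records <- function(df) {
  probs <- character()
  note <- function(i, msg) {
    p <- sprintf("line %d (trial %s): %s", i + 1L, df$trial_id[i], msg)
    names(p) <- as.character(i)
    probs <<- c(probs, p)
  }
  has <- function(i, cols) all(!is.na(unlist(df[i, cols], use.names = FALSE)))
  any_set <- function(i, cols) any(!is.na(unlist(df[i, cols], use.names = FALSE)))
  bin_cols <- c("events_exp", "total_exp", "events_ctl", "total_ctl",
                "n11", "n10", "n01", "n00")
  cont_cols <- c("mean_exp", "sd_exp", "n_exp", "mean_ctl", "sd_ctl", "n_ctl",
                 "sd_diff")
  for (i in seq_len(nrow(df))) {
    if (!df$design[i] %in% c("split_mouth", "parallel")) {
      note(i, "design must be 'split_mouth' or 'parallel'"); next
    }
    if (!df$outcome_type[i] %in% c("binary", "continuous")) {
      note(i, "outcome_type must be 'binary' or 'continuous'"); next
    }
    if (!is.na(df$beneficial_direction[i]) &&
        !df$beneficial_direction[i] %in% c("lower", "higher"))
      note(i, "beneficial_direction must be 'lower' or 'higher'")
    if (df$outcome_type[i] == "binary") {
      if (any_set(i, cont_cols))
        note(i, "continuous columns populated for a binary outcome")
      if (df$design[i] == "parallel") {
        if (!has(i, c("events_exp", "total_exp", "events_ctl", "total_ctl"))) {
          note(i, "parallel binary trials need events and totals for both arms")
        } else if (df$events_exp[i] > df$total_exp[i] ||
                   df$events_ctl[i] > df$total_ctl[i] ||
                   any(unlist(df[i, c("events_exp", "total_exp",
                                      "events_ctl", "total_ctl")]) < 0)) {
          note(i, "events must lie in [0, total]")
        }
        if (any_set(i, c("n11", "n10", "n01", "n00", "n_pairs")))
          note(i, "joint paired cells populated for a parallel trial")
      } else {
        joint <- has(i, c("n11", "n10", "n01", "n00"))
        margin <- has(i, c("events_exp", "events_ctl", "n_pairs"))
        if (!joint && !margin)
          note(i, "split-mouth binary trials need joint cells n11..n00, or marginal events with n_pairs")
        if (joint && any(unlist(df[i, c("n11", "n10", "n01", "n00")]) < 0))
          note(i, "joint cells must be non-negative")
        if (!joint && margin &&
            (df$events_exp[i] > df$n_pairs[i] || df$events_ctl[i] > df$n_pairs[i]))
          note(i, "marginal events cannot exceed n_pairs")
      }
    } else {
      if (any_set(i, c("events_exp", "events_ctl", "total_exp", "total_ctl",
                       "n11", "n10", "n01", "n00")))
        note(i, "binary columns populated for a continuous outcome")
      if (df$design[i] == "parallel") {
        if (!has(i, c("mean_exp", "sd_exp", "n_exp", "mean_ctl", "sd_ctl", "n_ctl"))) {
          note(i, "parallel continuous trials need means, SDs and sizes for both arms")
        } else if (df$sd_exp[i] <= 0 || df$sd_ctl[i] <= 0 ||
                   df$n_exp[i] <= 0 || df$n_ctl[i] <= 0) {
          note(i, "SDs and arm sizes must be positive")
        }
        if (!is.na(df$n_pairs[i]))
          note(i, "n_pairs populated for a parallel trial")
      } else {
        if (!has(i, c("mean_exp", "mean_ctl", "n_pairs"))) {
          note(i, "split-mouth continuous trials need site means and n_pairs")
        } else if (df$n_pairs[i] <= 1) {
          note(i, "n_pairs must exceed 1")
        }
        if (!(has(i, c("sd_exp", "sd_ctl")) || !is.na(df$sd_diff[i])))
          note(i, "split-mouth continuous trials need site SDs or sd_diff")
        if (any_set(i, c("n_exp", "n_ctl")))
          note(i, "arm sizes populated for a split-mouth trial; use n_pairs")
      }
    }
    if (!is.na(df$rho[i]) && (df$rho[i] < -1 || df$rho[i] > 1))
      note(i, "rho must lie in [-1, 1]")
  }
  probs
}

#' Write trial records to the flat CSV schema
#'
#' @param records A `trial_records` data frame (e.g. from
#'   [simulate_metaepi_dataset()] with `output = "records"`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(records, path) {
  cols <- schema_columns()
  if (!all(cols %in% names(records)))
    stop("records lack schema columns: ",
         paste(setdiff(cols, names(records)), collapse = ", "), call. = FALSE)
  utils::write.csv(records[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Compute per-trial effect estimates from trial records
#'
#' Routes each record to the effect measure matching its design and outcome
#' type: [log_or_parallel()], [marginal_log_or_split_mouth()] (via
#' [paired_cells_from_marginals()] when only marginal events are reported),
#' [smd_parallel()] or [smd_split_mouth()]. A record-level `rho` overrides
#' the default; a record carrying both `rho` and `sd_diff` uses `sd_diff`
#' for standardization (with a warning). Estimates are oriented so negative
#' values mean benefit, per `beneficial_direction`.
#'
#' @param records A `trial_records` data frame.
#' @param rho Default within-patient correlation for split-mouth trials
#'   whose records do not state one (0.5; conventional sensitivity values
#'   are 0 and 0.25).
#' @param correction Continuity correction for zero cells in binary tables.
#'
#' @return A data frame with one row per trial: `meta_id`, `trial_id`,
#'   `design`, `outcome_type`, `scale`, `value`, `variance`, `excluded`,
#'   `reason`.
#' @export
compute_trial_effects <- function(records, rho = 0.5, correction = 0.5) {
  n <- nrow(records)
  design <- records$design
  otype <- records$outcome_type
  dir <- records$beneficial_direction
  dir[is.na(dir)] <- "lower"
  value <- variance <- rep(NA_real_, n)
  excluded <- rep(FALSE, n)
  reason <- rep(NA_character_, n)
  scale <- ifelse(otype == "binary", "log_odds_ratio", "smd")
  r_ee <- records$events_exp; r_te <- records$total_exp
  r_ec <- records$events_ctl; r_tc <- records$total_ctl
  r_11 <- records$n11; r_10 <- records$n10
  r_01 <- records$n01; r_00 <- records$n00
  r_np <- records$n_pairs
  r_me <- records$mean_exp; r_se <- records$sd_exp; r_ne <- records$n_exp
  r_mc <- records$mean_ctl; r_sc <- records$sd_ctl; r_nc <- records$n_ctl
  r_rho <- records$rho; r_sdd <- records$sd_diff

  for (i in seq_len(n)) {
    rho_i <- if (!is.na(r_rho[i])) r_rho[i] else rho
    est <- if (otype[i] == "binary" && design[i] == "parallel") {
      log_or_parallel(binary_arms(r_ee[i], r_te[i], r_ec[i], r_tc[i]),
                      correction = correction, trial_id = records$trial_id[i])
    } else if (otype[i] == "binary") {
      tab <- if (!is.na(r_11[i])) {
        paired_binary_table(r_11[i], r_10[i], r_01[i], r_00[i])
      } else {
        paired_cells_from_marginals(r_ee[i], r_ec[i], r_np[i], rho_i)
      }
      marginal_log_or_split_mouth(tab, trial_id = records$trial_id[i])
    } else if (design[i] == "parallel") {
      smd_parallel(continuous_arms(r_me[i], r_se[i], r_ne[i],
                                   r_mc[i], r_sc[i], r_nc[i]),
                   trial_id = records$trial_id[i])
    } else {
      if (!is.na(r_sdd[i]) && !is.na(r_rho[i]))
        warning(sprintf("trial %s reports both rho and sd_diff; sd_diff wins for standardization",
                        records$trial_id[i]), call. = FALSE)
      pc <- paired_continuous(
        mean_exp = r_me[i], mean_ctl = r_mc[i],
        sd_exp = if (is.na(r_se[i])) NULL else r_se[i],
        sd_ctl = if (is.na(r_sc[i])) NULL else r_sc[i],
        n = r_np[i], rho = rho_i,
        sd_diff = if (is.na(r_sdd[i])) NULL else r_sdd[i]
      )
      smd_split_mouth(pc, trial_id = records$trial_id[i])
    }
    est <- orient_effect(est, dir[i])
    value[i] <- est$value
    variance[i] <- est$variance
    excluded[i] <- est$excluded
    reason[i] <- est$reason
  }
  data.frame(
    meta_id = records$meta_id, trial_id = records$trial_id,
    design = design, outcome_type = otype, scale = scale,
    value = value, variance = variance, excluded = excluded, reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Group per-trial effects into meta-analysis inputs
#'
#' @param effects The data frame returned by [compute_trial_effects()].
#' @return A list of [meta_analysis_input()] objects, in first-appearance
#'   order of `meta_id`.
#' @export
as_meta_inputs <- function(effects) {
  ids <- unique(effects$meta_id)
  lapply(ids, function(id) {
    sub <- effects[effects$meta_id == id, , drop = FALSE]
    meta_analysis_input(id, sub$outcome_type[1],
                        sub[, c("trial_id", "design", "scale", "value",
                                "variance", "excluded", "reason")])
  })
}

# shared core: records of one outcome type -> effects, exclusion log,
# contrasts and the pooled result
pipeline_core <- function(records, outcome_type, rho, within_method,
                          level = 0.95) {
  records <- records[records$outcome_type == outcome_type, , drop = FALSE]
  if (!nrow(records))
    stop("no ", outcome_type, " trials in the input", call. = FALSE)
  effects <- compute_trial_effects(records, rho = rho)
  exclusions <- data.frame(
    unit = effects$trial_id[effects$excluded],
    level = rep("trial", sum(effects$excluded)),
    reason = effects$reason[effects$excluded],
    stringsAsFactors = FALSE
  )
  metas <- as_meta_inputs(effects)
  metas <- exclude_overlapping(metas)
  ov <- attr(metas, "dropped")
  if (nrow(ov))
    exclusions <- rbind(exclusions, data.frame(
      unit = ov$meta_id, level = "meta_analysis", reason = ov$reason,
      stringsAsFactors = FALSE))
  keep <- vapply(metas, is_eligible, TRUE)
  if (any(!keep))
    exclusions <- rbind(exclusions, data.frame(
      unit = vapply(metas[!keep], function(m) m$id, ""),
      level = "meta_analysis", reason = "missing_design_subgroup",
      stringsAsFactors = FALSE))
  metas <- metas[keep]
  contrasts <- lapply(metas, design_contrast, within_method = within_method)
  result <- pool_contrasts(contrasts, level = level)
  list(effects = effects, exclusions = exclusions, metas = metas,
       contrasts = contrasts, result = result)
}

#' Run the full meta-epidemiological pipeline
#'
#' Reads (or takes) trial records, computes per-trial effects, applies the
#' exclusion rules (double-zero binary trials; overlapping meta-analyses;
#' meta-analyses missing a design subgroup), contrasts the designs within
#' each meta-analysis and pools the contrasts across meta-analyses. When
#' `output_dir` is given, writes `contrasts.csv`, `forest.csv`,
#' `exclusions.csv` and `summary.json` (ratio-scale entries are exact
#' `exp()` transforms of the log-scale values).
#'
#' @param input A CSV path or a `trial_records` data frame.
#' @param outcome_type `"binary"` or `"continuous"`; may be omitted when the
#'   input holds a single outcome type.
#' @param rho Default within-patient correlation (0.5).
#' @param within_method Within-meta-analysis pooling, `"fixed"` (primary) or
#'   `"random_reml"` (sensitivity).
#' @param output_dir Optional directory for the report files.
#' @param skip_invalid Passed to [read_trials()] for path input.
#' @param level Confidence / prediction level.
#'
#' @return Invisibly, a list with `result` (the `metaepi_result`),
#'   `contrasts`, `forest`, `effects`, `exclusions` and `summary`.
#' @export
run_pipeline <- function(input, outcome_type = NULL, rho = 0.5,
                         within_method = c("fixed", "random_reml"),
                         output_dir = NULL, skip_invalid = FALSE,
                         level = 0.95) {
  within_method <- match.arg(within_method)
  records <- if (is.character(input)) {
    read_trials(input, skip_invalid = skip_invalid)
  } else {
    input
  }
  if (is.null(outcome_type)) {
    types <- unique(records$outcome_type)
    if (length(types) != 1)
      stop("input mixes outcome types; set `outcome_type`", call. = FALSE)
    outcome_type <- types
  }
  core <- pipeline_core(records, outcome_type, rho, within_method, level)
  res <- core$result
  forest <- forest_export(core$contrasts, res)
  message(sprintf(
    "pipeline: %d %s trials read, %d excluded, %d meta-analyses pooled",
    sum(records$outcome_type == outcome_type), outcome_type,
    nrow(core$exclusions), res$n_meta))
  summ <- list(
    outcome_type = outcome_type, within_method = within_method, rho = rho,
    n_meta = res$n_meta, combined = res$combined,
    ci_lower = res$ci_lower, ci_upper = res$ci_upper,
    p_value = res$p_value, tau2 = res$tau2, i2 = res$i2,
    prediction_lower = res$prediction$lower,
    prediction_upper = res$prediction$upper
  )
  if (outcome_type == "binary") {
    summ$ror <- exp(res$combined)
    summ$ror_ci_lower <- exp(res$ci_lower)
    summ$ror_ci_upper <- exp(res$ci_upper)
    summ$ror_prediction_lower <- exp(res$prediction$lower)
    summ$ror_prediction_upper <- exp(res$prediction$upper)
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(contrasts_table(core$contrasts),
                     file.path(output_dir, "contrasts.csv"), row.names = FALSE)
    utils::write.csv(forest, file.path(output_dir, "forest.csv"),
                     row.names = FALSE)
    utils::write.csv(core$exclusions, file.path(output_dir, "exclusions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summ, file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(result = res, contrasts = core$contrasts, forest = forest,
                 effects = core$effects, exclusions = core$exclusions,
                 summary = summ))
}

#' Sensitivity grid over correlation values and within-pooling methods
#'
#' Re-runs the contrast pipeline for every combination of assumed
#' within-patient correlation and within-meta-analysis pooling method.
#' Records that carry their own `rho` or complete joint cell counts are
#' unaffected by the correlation setting, mirroring how reported matched
#' data override the assumption.
#'
#' @param records A `trial_records` data frame.
#' @param rho_values Correlations to assume for trials without matched data.
#' @param within_methods Within-meta-analysis pooling methods.
#' @param outcome_type As in [run_pipeline()].
#'
#' @return A data frame with one row per grid point: `rho`,
#'   `within_method`, `n_meta`, `combined`, `ci_lower`, `ci_upper`,
#'   `p_value`, `tau2`, `i2`, `pi_lower`, `pi_upper`.
#' @export
sensitivity_suite <- function(records, rho_values = c(0, 0.25, 0.5),
                              within_methods = c("fixed", "random_reml"),
                              outcome_type = NULL) {
  if (is.null(outcome_type)) {
    types <- unique(records$outcome_type)
    if (length(types) != 1)
      stop("input mixes outcome types; set `outcome_type`", call. = FALSE)
    outcome_type <- types
  }
  grid <- expand.grid(rho = rho_values, within_method = within_methods,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    core <- pipeline_core(records, outcome_type, grid$rho[g],
                          grid$within_method[g])
    r <- core$result
    data.frame(rho = grid$rho[g], within_method = grid$within_method[g],
               n_meta = r$n_meta, combined = r$combined,
               ci_lower = r$ci_lower, ci_upper = r$ci_upper,
               p_value = r$p_value, tau2 = r$tau2, i2 = r$i2,
               pi_lower = r$prediction$lower, pi_upper = r$prediction$upper,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
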