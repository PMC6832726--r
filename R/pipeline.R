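# Batch orchestration: episodes -> features -> weekly table -> variance
# components -> sample-size grid, with file I/O and logging.

#' Pipeline run configuration
#'
#' Assembles paths and parameters for [run_pipeline()]. Can be built
#' directly or loaded from a YAML file with [read_run_config()].
#'
#' @param episode_file Episode CSV
#'   (`subject,week,day,t,acc_vt,acc_ml,acc_ap`; time in s,
#'   acceleration in g).
#' @param out_dir Output directory (created if missing).
#' @param epoch_s,min_epochs,units,leg_length Feature/aggregation
#'   parameters (see [feature_config()] and [weekly_median_table()]).
#' @param axis_cols Names of the three axis columns in the episode file.
#' @param composite_weights Optional [composite_weights()]; when `NULL`
#'   an equal-weight composite standardized by cohort epoch-level
#'   means/SDs is added at the weekly stage.
#' @param d_list,r_list,alpha,power Sample-size grid parameters.
#' @param seed Seed for any stochastic stage.
#' @param log_level `"info"` or `"quiet"`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(episode_file, out_dir, epoch_s = 10, min_epochs = 10,
                       units = "ms2", leg_length = 0.9,
                       axis_cols = c("acc_vt", "acc_ml", "acc_ap"),
                       composite_weights = NULL,
                       d_list = c(0.3, 0.5, 0.8), r_list = c(0.3, 0.6, 0.9),
                       alpha = 0.05, power = 0.8, seed = 1L,
                       log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  stopifnot(epoch_s > 0, min_epochs >= 1, units %in% c("ms2", "g"),
            leg_length > 0, length(axis_cols) == 3)
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [run_config()]; unknown keys
#' raise a validation error naming the field.
#'
#' @param path YAML file.
#' @param ... Overrides applied after reading.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  do.call(run_config, raw)
}

pipe_log <- function(config, fmt, ...) {
  if (identical(config$log_level, "info")) message(sprintf(fmt, ...))
  invisible(NULL)
}

#' Run the full analysis pipeline
#'
#' Episodes are read, realigned, cut into epochs and featurised; epoch
#' rows are aggregated to weekly medians; variance components are
#' estimated per characteristic; and the sample-size grid is evaluated.
#' Every stage's output is written to `out_dir`
#' (`features.csv`, `weekly.csv`, `varcomp.json`, `power_grid.csv`) and
#' logged with row counts and exclusion reasons. Malformed or invalid
#' epochs are flagged and counted, never silently dropped; an empty
#' stage output aborts the downstream stages with an error.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the four stage outputs and the paths
#'   written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  fc <- feature_config(epoch_s = config$epoch_s, units = config$units,
                       leg_length = config$leg_length,
                       min_epochs = config$min_epochs,
                       composite = config$composite_weights)

  episodes <- read_episodes(config$episode_file, axis_cols = config$axis_cols)
  pipe_log(config, "read %d episode(s) from %s", length(episodes),
           config$episode_file)

  feats <- lapply(episodes, function(ep) {
    suppressWarnings(extract_features(ep, fc, leg_length = config$leg_length))
  })
  reports <- unlist(lapply(feats, attr, "report"))
  features <- do.call(rbind, feats)
  rownames(features) <- NULL
  n_invalid <- sum(!features$valid)
  pipe_log(config, "extracted %d epoch rows (%d valid, %d flagged invalid)",
           nrow(features), nrow(features) - n_invalid, n_invalid)
  for (r in reports) pipe_log(config, "  excluded: %s", r)
  if (nrow(features) == 0) stop("no epochs extracted; aborting")
  f_path <- file.path(config$out_dir, "features.csv")
  utils::write.csv(format_numeric(features), f_path, row.names = FALSE)

  weekly <- weekly_median_table(features, min_epochs = config$min_epochs)
  if (is.null(config$composite_weights)) {
    weekly <- add_cohort_composite(weekly)
  }
  pipe_log(config, "weekly table: %d subject-week rows", nrow(weekly))
  if (nrow(weekly) == 0) stop("weekly table is empty; aborting")
  w_path <- file.path(config$out_dir, "weekly.csv")
  utils::write.csv(format_numeric(weekly), w_path, row.names = FALSE)

  chars <- setdiff(names(weekly), c("subject", "week"))
  chars <- chars[!startsWith(chars, "n_epochs_")]
  report <- withCallingHandlers(
    varcomp_report(weekly, characteristics = chars, seed = config$seed),
    message = function(m) {
      pipe_log(config, "  %s", sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  pipe_log(config, "variance components estimated for %d characteristic(s)",
           length(report))
  if (!length(report)) stop("no characteristic yielded variance components")
  v_path <- file.path(config$out_dir, "varcomp.json")
  write_varcomp_json(report, v_path)

  grid <- sample_size_grid(report, d_list = config$d_list,
                           r_list = config$r_list, alpha = config$alpha,
                           power = config$power)
  g_path <- file.path(config$out_dir, "power_grid.csv")
  utils::write.csv(grid_to_table(grid), g_path, row.names = FALSE)
  pipe_log(config, "sample-size grid: %d cells", nrow(grid))

  invisible(list(features = features, weekly = weekly, varcomp = report,
                 power_grid = grid,
                 paths = c(features = f_path, weekly = w_path,
                           varcomp = v_path, power_grid = g_path)))
}

# Equal-weight composite standardized by the cohort's weekly-level
# means/SDs (used when no external weights are supplied).
add_cohort_composite <- function(weekly) {
  inputs <- c("stride_autocorr_vt", "dominant_amp_vt", "rms", "ih_vt")
  if (!all(inputs %in% names(weekly))) return(weekly)
  means <- vapply(inputs, function(c_) mean(weekly[[c_]], na.rm = TRUE),
                  numeric(1))
  sds <- vapply(inputs, function(c_) stats::sd(weekly[[c_]], na.rm = TRUE),
                numeric(1))
  if (any(!is.finite(sds)) || any(sds <= 0)) return(weekly)
  cw <- composite_weights(
    means = stats::setNames(means, c("regularity", "step_power", "rms",
                                     "harmonicity")),
    sds = stats::setNames(sds, c("regularity", "step_power", "rms",
                                 "harmonicity")))
  weekly$composite <- vapply(seq_len(nrow(weekly)), function(i)
    composite_score(weekly[i, ], cw), numeric(1))
  weekly
}

# 6-significant-digit numeric formatting for the written artifacts, so
# reruns with the same seed produce byte-identical files.
format_numeric <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) {
      df[[j]] <- signif(df[[j]], 6)
    }
  }
  df
}
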