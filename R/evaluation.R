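#' Molecular-timetable predictor factory
#'
#' Wraps the timetable training and prediction steps into the predictor
#' contract used by [loo_evaluate()]: calling the factory on a training
#' expression set returns a function that maps a named sample vector to a
#' list with `predicted_time_hours` and `r_at_max`.  Any predictor honouring
#' this contract can be benchmarked by the same harness.
#'
#' @inheritParams select_tigs
#' @param scale Passed through to [predict_time()].
#' @return A function `function(train_set)` returning a prediction closure.
#' @export
mtt_predictor <- function(bundle = build_cosine_bundle(),
                          mode = "LDDD_05",
                          r_cutoff = 0.5, cv_cutoff = 0.20, scale = TRUE) {
  function(train_set) {
    model <- select_tigs(train_set, bundle = bundle, mode = mode,
                         r_cutoff = r_cutoff, cv_cutoff = cv_cutoff)
    function(sample_values) {
      p <- predict_time(model, sample_values, scale = scale)
      list(predicted_time_hours = p$predicted_time_hours,
           r_at_max = p$r_at_max)
    }
  }
}

#' Leave-one-out evaluation of a physiological-time predictor
#'
#' For every sample of the reference set, the predictor is retrained from
#' scratch on all remaining samples of the same tissue (tissues are
#' evaluated independently) and asked to predict the held-out sample; the
#' signed circular difference between prediction and harvest time is
#' recorded.  Aggregates follow the calibration convention: the headline
#' error is the mean absolute difference, the dispersion is the SD of the
#' signed differences, and the precision is three times that SD.
#'
#' @param x An [expression_set()] reference (>= 3 samples per tissue).
#' @param predictor A predictor factory such as [mtt_predictor()].
#' @return List of class `evaluation_report`: `per_sample` (data frame of
#'   fold results), `mean_abs_diff_hours`, `sd_signed_diff_hours`,
#'   `precision_hours` (3 x SD), `per_tissue` breakdown, and `failures`
#'   (folds on which the predictor errored, with messages).
#' @examples
#' cfg <- simulation_config(n_genes = 12, cycler_fraction = 1,
#'                          amplitude_to_noise = Inf, replicates = 1)
#' rep <- loo_evaluate(generate_reference_timecourse(cfg)$expression)
#' rep$mean_abs_diff_hours
#' @export
loo_evaluate <- function(x, predictor = mtt_predictor()) {
  stopifnot(inherits(x, "expression_set"))
  tissues <- unique(x$samples$tissue)
  rows <- list()
  failures <- list()
  for (ts in tissues) {
    idx <- which(x$samples$tissue == ts)
    if (length(idx) < 3)
      stop("tissue '", ts, "' has fewer than 3 samples", call. = FALSE)
    for (i in idx) {
      res <- tryCatch({
        train <- subset_expression(x, samples = setdiff(idx, i))
        fit <- predictor(train)
        p <- fit(x$values[, i])
        data.frame(sample_id = x$samples$sample_id[i],
                   tissue = ts,
                   harvest_time_hours = x$samples$time_hours[i],
                   predicted_time_hours = p$predicted_time_hours,
                   r_at_max = p$r_at_max)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <-
          data.frame(sample_id = x$samples$sample_id[i], tissue = ts,
                     message = conditionMessage(res))
      } else {
        rows[[length(rows) + 1]] <- res
      }
    }
  }
  if (!length(rows))
    stop("predictor failed on every fold", call. = FALSE)
  per_sample <- do.call(rbind, rows)
  per_sample$signed_diff_hours <- circular_difference(
    per_sample$predicted_time_hours, per_sample$harvest_time_hours)

  agg <- function(d) {
    sdd <- stats::sd(d)
    c(mean_abs = mean(abs(d)), sd_signed = sdd, precision = 3 * sdd)
  }
  overall <- agg(per_sample$signed_diff_hours)
  per_tissue <- do.call(rbind, lapply(split(per_sample, per_sample$tissue),
    function(g) data.frame(tissue = g$tissue[1], n = nrow(g),
                           mean_abs_diff_hours = mean(abs(g$signed_diff_hours)),
                           sd_signed_diff_hours = stats::sd(g$signed_diff_hours))))
  rownames(per_tissue) <- NULL
  structure(list(per_sample = per_sample,
                 mean_abs_diff_hours = unname(overall["mean_abs"]),
                 sd_signed_diff_hours = unname(overall["sd_signed"]),
                 precision_hours = unname(overall["precision"]),
                 per_tissue = per_tissue,
                 failures = if (length(failures)) do.call(rbind, failures)
                            else NULL),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("leave-one-out evaluation: ", nrow(x$per_sample), " folds",
      if (!is.null(x$failures)) paste0(" (", nrow(x$failures), " failed)"),
      "\n", sep = "")
  cat(sprintf("mean |diff| = %.3f h; SD(signed) = %.3f h; precision (3 SD) = %.3f h\n",
              x$mean_abs_diff_hours, x$sd_signed_diff_hours, x$precision_hours))
  invisible(x)
}

#' Flag samples whose inferred time deviates from harvest time
#'
#' A sample is an outlier iff the absolute signed circular difference
#' strictly exceeds the threshold; the default 3.4 h is the three-SD
#' precision of the timetable method on its reference data.
#'
#' @param predictions Data frame with columns `sample_id`, `tissue` and
#'   `signed_diff_hours` (as produced by [predict_samples()] or found in an
#'   evaluation report's `per_sample`).
#' @param threshold_hours Positive flagging threshold (strict inequality).
#' @return The input with an added logical column `outlier`.
#' @examples
#' d <- data.frame(sample_id = c("a", "b"), tissue = "gut",
#'                 signed_diff_hours = c(3.4, -3.5))
#' flag_outliers(d)$outlier   # FALSE TRUE
#' @export
flag_outliers <- function(predictions, threshold_hours = 3.4) {
  if (threshold_hours <= 0) stop("threshold must be > 0", call. = FALSE)
  if (!"signed_diff_hours" %in% names(predictions))
    stop("predictions must carry a signed_diff_hours column", call. = FALSE)
  predictions$outlier <- abs(predictions$signed_diff_hours) > threshold_hours
  predictions
}

#' Detection window for a line with a deviating molecular clock
#'
#' Simulates how long, within one 24-hour day, a line whose internal clock
#' runs at a different period and/or phase remains distinguishable from the
#' reference.  A timetable model is trained on a reference time course whose
#' TIG phases tile the day; then, for every harvest time `t` on a fine grid
#' over `[0, 24)`, the line's TIG expression vector is generated at internal
#' time `tau = (24 / period) * (t + phase_offset)` and its physiological
#' time inferred.  The harvest time is flagged when the circular difference
#' between inferred and harvest time strictly exceeds the threshold; the
#' detection window is the total flagged duration.
#'
#' @param period_hours The deviating line's molecular period (hours).
#' @param phase_offset_hours Signed internal-clock advance (hours).
#' @param config A [simulation_config()] supplying amplitude, mesor and the
#'   amplitude-to-noise ratio of the simulated TIG measurements (default:
#'   noiseless).
#' @param threshold_hours Flagging threshold (default 3.4 h, the three-SD
#'   precision).
#' @param grid_step_minutes Harvest-time scan resolution (default 1 min).
#' @param n_tigs Number of time-indicating genes in the tiling reference.
#' @param bundle Cosine bundle used for training and prediction.
#' @return List of class `window_result`: `window_hours` (to 0.1 h
#'   precision in the `print` method; raw value retained), `window_rounded`
#'   (nearest hour), `flagged` and `harvest_time_hours` vectors, plus the
#'   settings.
#' @examples
#' w <- detection_window(30, 0, grid_step_minutes = 5)
#' w$window_rounded   # 7
#' @export
detection_window <- function(period_hours, phase_offset_hours = 0,
                             config = simulation_config(
                               n_genes = 12, cycler_fraction = 1,
                               amplitude_to_noise = Inf,
                               duration_hours = 24, replicates = 1),
                             threshold_hours = 3.4,
                             grid_step_minutes = 1,
                             n_tigs = NULL,
                             bundle = build_cosine_bundle()) {
  if (period_hours <= 0) stop("period_hours must be > 0", call. = FALSE)
  if (!is.null(n_tigs)) {
    config <- simulation_config(
      n_genes = n_tigs, cycler_fraction = 1,
      amplitude_to_noise = config$amplitude_to_noise,
      amplitude = config$amplitude, mesor = config$mesor,
      sampling_interval_hours = config$sampling_interval_hours,
      duration_hours = config$duration_hours, replicates = config$replicates,
      regime_schedule = config$regime_schedule, seed = config$seed)
  }
  ref <- generate_reference_timecourse(config)
  model <- select_tigs(ref$expression, bundle = bundle)

  step_h <- grid_step_minutes / 60
  t_grid <- seq(0, 24 - step_h, by = step_h)
  truth <- ref$truth[match(model$tigs$gene_id, ref$truth$gene_id), ]
  tau <- (24 / period_hours) * (t_grid + phase_offset_hours)
  # TIG expression of the deviating line at each scanned harvest time
  s <- config$mesor + config$amplitude *
    cos(outer(truth$phase_hours, tau, function(ph, tt) 2 * pi * (tt - ph) / 24))
  if (is.finite(config$amplitude_to_noise)) {
    set.seed(config$seed + 1L)
    s <- s + matrix(stats::rnorm(length(s),
                                 sd = config$amplitude / config$amplitude_to_noise),
                    nrow(s), ncol(s))
  }
  # correlate every scanned sample against the MPT-anchored candidate waves
  phis <- seq(0, 24 - bundle$increment_hours, by = bundle$increment_hours)
  waves <- outer(model$tigs$mpt_hours, phis,
                 function(m, p) cos(2 * pi * (m - p) / 24))
  r <- suppressWarnings(stats::cor(s, waves))
  r[is.na(r)] <- -Inf
  predicted <- phis[max.col(r, ties.method = "first")]
  d <- circular_difference(predicted, t_grid)
  flagged <- abs(d) > threshold_hours
  structure(list(period_hours = period_hours,
                 phase_offset_hours = phase_offset_hours,
                 anr = config$amplitude_to_noise,
                 threshold_hours = threshold_hours,
                 grid_step_minutes = grid_step_minutes,
                 harvest_time_hours = t_grid,
                 predicted_time_hours = predicted,
                 signed_diff_hours = d,
                 flagged = flagged,
                 window_hours = sum(flagged) * step_h,
                 window_rounded = round(sum(flagged) * step_h)),
            class = "window_result")
}

#' @export
print.window_result <- function(x, ...) {
  cat(sprintf(paste0("detection window: %.1f h (period %.1f h, offset %+.1f h, ",
                     "threshold %.1f h)\n"),
              x$window_hours, x$period_hours, x$phase_offset_hours,
              x$threshold_hours))
  invisible(x)
}
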