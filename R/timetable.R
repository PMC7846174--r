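#' Build a bundle of reference cosine waves
#'
#' The reference grid for rhythmicity scoring and phase inference: a family
#' of unit-amplitude cosine waves of a single period whose peak times tile
#' the period at a fixed increment.  At the canonical settings (24-hour
#' period, 10-minute increment) the bundle holds 144 waves.
#'
#' @param period_hours Wave period (hours).
#' @param increment_hours Spacing of consecutive peak times (hours); must
#'   divide the period an integer number of times.
#' @return An object of class `cosine_bundle` with elements `period_hours`,
#'   `increment_hours` and `peak_times` (strictly increasing, starting at 0).
#' @examples
#' b <- build_cosine_bundle(24, 10 / 60)
#' length(b$peak_times)   # 144
#' @export
build_cosine_bundle <- function(period_hours = 24, increment_hours = 10 / 60) {
  if (period_hours <= 0 || increment_hours <= 0)
    stop("period and increment must be > 0", call. = FALSE)
  n <- period_hours / increment_hours
  if (abs(n - round(n)) > 1e-9)
    stop("period_hours must be an integer multiple of increment_hours",
         call. = FALSE)
  n <- as.integer(round(n))
  structure(list(period_hours = period_hours,
                 increment_hours = increment_hours,
                 peak_times = (seq_len(n) - 1) * increment_hours),
            class = "cosine_bundle")
}

# Wave values of a bundle at given timestamps: times x waves matrix with
# entry cos(2*pi*(t - peak)/period).
bundle_values <- function(bundle, times) {
  outer(times, bundle$peak_times,
        function(t, p) cos(2 * pi * (t - p) / bundle$period_hours))
}

#' Rhythmicity score of a trace against a cosine bundle
#'
#' Correlates an expression trace with every wave of the bundle evaluated at
#' the trace's timestamps and records the maximum product-moment correlation
#' and the peak time of the best wave (ties broken by the smallest peak
#' time).  The best peak time is the trace's molecular peak time (MPT) when
#' the gene is retained as a time-indicating gene.
#'
#' @param values Numeric trace.
#' @param times Timestamps (hours), same length as `values`.
#' @param bundle A [build_cosine_bundle()] object.
#' @return List with `r_max` and `peak_time_hours`.
#' @examples
#' t <- seq(0, 46, by = 2)
#' rs <- rhythmicity_score(cos(2 * pi * (t - 6) / 24), t)
#' rs$peak_time_hours   # 6
#' @export
rhythmicity_score <- function(values, times, bundle = build_cosine_bundle()) {
  if (length(values) != length(times))
    stop("values and times lengths differ", call. = FALSE)
  if (length(values) < 3)
    stop("need at least 3 timepoints", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("constant trace has no rhythmicity score", call. = FALSE)
  w <- bundle_values(bundle, times)
  r <- suppressWarnings(as.numeric(stats::cor(values, w)))
  r[is.na(r)] <- -Inf     # wave constant on this time grid: never the argmax
  best <- which.max(r)    # which.max returns the first (smallest peak) tie
  list(r_max = r[best], peak_time_hours = bundle$peak_times[best])
}

# Vectorised scores for a genes x samples matrix; constant genes get NA.
rhythmicity_scores <- function(values, times, bundle) {
  keep <- apply(values, 1, stats::sd) > 0
  r_max <- rep(NA_real_, nrow(values))
  peak <- rep(NA_real_, nrow(values))
  if (any(keep)) {
    w <- bundle_values(bundle, times)
    r <- suppressWarnings(stats::cor(t(values[keep, , drop = FALSE]), w))
    r[is.na(r)] <- -Inf
    best <- max.col(r, ties.method = "first")
    r_max[keep] <- r[cbind(seq_len(nrow(r)), best)]
    peak[keep] <- bundle$peak_times[best]
  }
  data.frame(gene_id = rownames(values), r_max = r_max,
             peak_time_hours = peak, row.names = NULL)
}

#' Select time-indicating genes and build a timetable model
#'
#' The training step of the modified molecular-timetable method.  A gene is
#' a time-indicating gene (TIG) iff its maximum bundle correlation exceeds
#' `r_cutoff` (default 0.5) and its coefficient of variation on the raw
#' expression values exceeds `cv_cutoff` (default 0.20).  Its molecular peak
#' time (MPT) is the peak time of the best-correlated wave.
#'
#' Two selection modes mirror the TIG-set variants evaluated on the two-day
#' reference design:
#' * `"LDDD_05"` — the full series (LD and DD days as one unit) is scored
#'   once and both filters applied to it.
#' * `"LD_DD_05"` — both filters are applied separately within the LD and
#'   the DD samples and a gene must pass in both; its MPT is taken from the
#'   unified fit.
#'
#' @param x An [expression_set()] of the reference time course.
#' @param bundle A [build_cosine_bundle()] object.
#' @param mode `"LDDD_05"` or `"LD_DD_05"`.
#' @param r_cutoff Minimum bundle correlation (strict).
#' @param cv_cutoff Minimum coefficient of variation (strict).
#' @return An object of class `timetable_model`: list with `tigs` (data
#'   frame `gene_id`, `mpt_hours`, `r_max`, `cv`, `scale_min`, `scale_max`),
#'   the selection settings and the bundle.  At least 2 TIGs with 2 distinct
#'   MPTs are required, otherwise an error is thrown.
#' @seealso [predict_time()] for the prediction step.
#' @export
select_tigs <- function(x, bundle = build_cosine_bundle(),
                        mode = c("LDDD_05", "LD_DD_05"),
                        r_cutoff = 0.5, cv_cutoff = 0.20) {
  stopifnot(inherits(x, "expression_set"))
  mode <- match.arg(mode)
  if (r_cutoff < -1 || r_cutoff > 1)
    stop("r_cutoff must lie in [-1, 1]", call. = FALSE)
  if (cv_cutoff < 0) stop("cv_cutoff must be >= 0", call. = FALSE)

  times <- sample_times(x)
  unified <- rhythmicity_scores(x$values, times, bundle)
  gs <- gene_summary(x)
  cv_pass <- gs$cv_defined & gs$cv > cv_cutoff

  if (mode == "LDDD_05") {
    pass <- !is.na(unified$r_max) & unified$r_max > r_cutoff & cv_pass
  } else {
    regimes <- x$samples$regime
    if (length(unique(regimes)) < 2)
      stop("LD_DD_05 mode needs samples from both LD and DD regimes",
           call. = FALSE)
    pass <- cv_pass & !is.na(unified$r_max)
    for (rg in c("LD", "DD")) {
      idx <- regimes == rg
      sub <- subset_expression(x, samples = idx)
      sc <- rhythmicity_scores(sub$values, sample_times(sub), bundle)
      gss <- gene_summary(sub)
      pass <- pass & !is.na(sc$r_max) & sc$r_max > r_cutoff &
        gss$cv_defined & gss$cv > cv_cutoff
    }
  }

  tigs <- data.frame(gene_id = unified$gene_id[pass],
                     mpt_hours = unified$peak_time_hours[pass] %% 24,
                     r_max = unified$r_max[pass],
                     cv = gs$cv[pass],
                     scale_min = apply(x$values[pass, , drop = FALSE], 1, min),
                     scale_max = apply(x$values[pass, , drop = FALSE], 1, max),
                     row.names = NULL)
  if (nrow(tigs) < 2 || length(unique(tigs$mpt_hours)) < 2)
    stop("timetable unusable: need >= 2 TIGs with >= 2 distinct molecular ",
         "peak times (got ", nrow(tigs), " TIG(s))", call. = FALSE)
  structure(list(tigs = tigs, mode = mode, r_cutoff = r_cutoff,
                 cv_cutoff = cv_cutoff, bundle = bundle),
            class = "timetable_model")
}

#' @export
print.timetable_model <- function(x, ...) {
  cat("timetable_model (", x$mode, "): ", nrow(x$tigs),
      " time-indicating genes\n", sep = "")
  cat("cutoffs: r > ", x$r_cutoff, ", CV > ", x$cv_cutoff,
      "; bundle: ", length(x$bundle$peak_times), " waves, period ",
      x$bundle$period_hours, " h\n", sep = "")
  invisible(x)
}

# Timestamps used for rhythm scoring: absolute experiment time when present
# (two-day designs), otherwise harvest time.
sample_times <- function(x) {
  if ("time_abs_hours" %in% names(x$samples)) x$samples$time_abs_hours
  else x$samples$time_hours
}

#' Predict the physiological time of a single static sample
#'
#' The prediction step of the molecular-timetable method: the sample's TIG
#' expression vector is correlated, across genes, with cosine waves of
#' 24-hour period anchored on the molecular peak times, one wave per
#' candidate phase on the bundle grid.  The candidate phase of the most
#' correlated wave is the sample's physiological time; ties are broken by
#' the smallest candidate time.
#'
#' @param model A [select_tigs()] timetable model.
#' @param sample_values Named numeric vector of the sample's expression
#'   (names are gene ids; must cover at least 2 of the model's TIGs with 2
#'   distinct MPTs).
#' @param scale If `TRUE` (default), each TIG value is rescaled with the
#'   training-set min/max stored in the model before correlating, the
#'   per-gene 0-1 standardization applied during training.
#' @return List of class `phase_prediction`: `predicted_time_hours` in
#'   `[0, 24)`, `r_at_max`, `n_tigs_used`.
#' @examples
#' cfg <- simulation_config(n_genes = 12, cycler_fraction = 1,
#'                          amplitude_to_noise = Inf)
#' ref <- generate_reference_timecourse(cfg)
#' model <- select_tigs(ref$expression)
#' v <- ref$expression$values[, 13]   # a sample harvested at ZT8
#' predict_time(model, v)$predicted_time_hours
#' @export
predict_time <- function(model, sample_values, scale = TRUE) {
  stopifnot(inherits(model, "timetable_model"))
  if (is.null(names(sample_values)))
    stop("sample_values must be named by gene id", call. = FALSE)
  idx <- match(model$tigs$gene_id, names(sample_values))
  usable <- !is.na(idx)
  if (sum(usable) < 2 ||
      length(unique(model$tigs$mpt_hours[usable])) < 2)
    stop("need values for >= 2 TIGs with >= 2 distinct MPTs (",
         sum(usable), " usable)", call. = FALSE)
  v <- as.numeric(sample_values[idx[usable]])
  tig <- model$tigs[usable, , drop = FALSE]
  if (scale) {
    span <- tig$scale_max - tig$scale_min
    v <- (v - tig$scale_min) / span
  }
  if (stats::sd(v) == 0)
    stop("zero-variance sample vector across TIGs", call. = FALSE)

  phis <- seq(0, 24 - model$bundle$increment_hours,
              by = model$bundle$increment_hours)
  waves <- outer(tig$mpt_hours, phis, function(m, p) cos(2 * pi * (m - p) / 24))
  r <- suppressWarnings(as.numeric(stats::cor(v, waves)))
  r[is.na(r)] <- -Inf
  best <- which.max(r)
  structure(list(predicted_time_hours = phis[best],
                 r_at_max = r[best],
                 n_tigs_used = nrow(tig)),
            class = "phase_prediction")
}

#' Predict physiological times for every sample of an expression set
#'
#' Applies [predict_time()] column-wise and annotates each prediction with
#' the signed circular difference to the recorded harvest time.
#'
#' @inheritParams predict_time
#' @param x An [expression_set()] of static samples.
#' @return Data frame: `sample_id`, `tissue`, `harvest_time_hours`,
#'   `predicted_time_hours`, `r_at_max`, `signed_diff_hours`.
#' @export
predict_samples <- function(model, x, scale = TRUE) {
  stopifnot(inherits(x, "expression_set"))
  preds <- lapply(seq_len(ncol(x$values)), function(j)
    predict_time(model, x$values[, j], scale = scale))
  out <- data.frame(sample_id = x$samples$sample_id,
                    tissue = x$samples$tissue,
                    harvest_time_hours = x$samples$time_hours,
                    predicted_time_hours = vapply(preds, `[[`, numeric(1),
                                                  "predicted_time_hours"),
                    r_at_max = vapply(preds, `[[`, numeric(1), "r_at_max"),
                    row.names = NULL)
  out$signed_diff_hours <- circular_difference(out$predicted_time_hours,
                                               out$harvest_time_hours)
  out
}

#' Signed circular difference between two clock times
#'
#' `((a - b + 12) mod 24) - 12` mapped onto `(-12, 12]`; the absolute value
#' is the circular distance on the 24-hour clock.  Positive means `a` is
#' ahead of `b`.
#'
#' @param a,b Times in hours (vectorised, any real values; interpreted
#'   modulo 24).
#' @return Signed difference(s) in `(-12, 12]`.
#' @examples
#' circular_difference(1, 23)   # +2
#' circular_difference(12, 0)   # 12 (antipode)
#' @export
circular_difference <- function(a, b) {
  d <- (a - b) %% 24
  ifelse(d > 12, d - 24, d)
}
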