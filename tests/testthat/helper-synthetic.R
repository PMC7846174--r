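# Shared fixtures built in code.

# Minimal sample metadata for hand-built matrices; absolute times beyond one
# day go into time_abs_hours, harvest times stay on [0, 24).
make_meta <- function(n, times = seq_len(n) - 1, tissue = "gut",
                      regime = "DD", replicate = 1L, line = "w1118") {
  data.frame(sample_id = paste0("s", seq_len(n)), line_id = line,
             tissue = tissue, time_hours = times %% 24, regime = regime,
             replicate = replicate, time_abs_hours = times)
}

# Hand-built expression set from a plain matrix (genes x samples).
tiny_eset <- function(values, times = seq_len(ncol(values)) - 1, ...) {
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  meta <- make_meta(ncol(values), times = times, ...)
  colnames(values) <- meta$sample_id
  expression_set(values, meta)
}

# Closed-form drift oracle for the detection window: measure of the set
# {t in [0,24) : |wrap((24/P)(t + off) - t)| > thr}, evaluated on a fine
# grid of the analytic drift formula (independent of the predictor).
analytic_window <- function(period, offset, threshold = 3.4, step = 1e-3) {
  t <- seq(0, 24 - step, by = step)
  d <- ((24 / period) * (t + offset) - t) %% 24
  d <- ifelse(d > 12, d - 24, d)
  mean(abs(d) > threshold) * 24
}

# Noiseless reference with all genes cycling and phases tiling the day.
tiling_reference <- function(n_tigs = 12, replicates = 1, seed = 1) {
  cfg <- simulation_config(n_genes = n_tigs, cycler_fraction = 1,
                           amplitude_to_noise = Inf,
                           replicates = replicates, seed = seed)
  generate_reference_timecourse(cfg)
}
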