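#' Configuration for synthetic circadian expression data
#'
#' Bundles the design and noise parameters of the synthetic generators.  The
#' defaults reproduce the study conditions the package's evaluation assumes:
#' a reference time course sampled every 2 hours over 48 hours in
#' triplicates, one light-dark (LD) day followed by one constant-darkness
#' (DD) day, sinusoidal cyclers with an amplitude of 100 expression units,
#' and additive Gaussian noise whose standard deviation is
#' `amplitude / amplitude_to_noise`.
#'
#' @param n_genes Number of genes to simulate.
#' @param cycler_fraction Fraction of genes that cycle, in `[0, 1]`.
#' @param period_hours Reference oscillation period (hours).
#' @param amplitude Cosine amplitude, expression units.
#' @param mesor Rhythm-adjusted mean, expression units; must be positive, and
#'   at least `amplitude` unless `allow_negative = TRUE`, so that traces stay
#'   positive and the coefficient of variation is well defined.
#' @param amplitude_to_noise Amplitude-to-noise ratio (ANR).  Noise SD =
#'   `amplitude / amplitude_to_noise`; `Inf` switches noise off.
#' @param sampling_interval_hours Spacing of the reference time grid (hours).
#' @param duration_hours Total span of the reference design (hours);
#'   must be an integer multiple of `sampling_interval_hours`.
#' @param replicates Biological replicates per timepoint.
#' @param start_time_hours Clock time of the first sample, in `[0, 24)`.
#' @param regime_schedule Character vector giving the light regime of each
#'   24-hour day, e.g. `c("LD", "DD")`.
#' @param seed Integer seed; all generator randomness flows from it.
#' @param allow_negative If `TRUE`, permit `mesor < amplitude` (traces may go
#'   negative; CV-based filters become unreliable).
#'
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 60,
                              cycler_fraction = 0.25,
                              period_hours = 24,
                              amplitude = 100,
                              mesor = 150,
                              amplitude_to_noise = 4,
                              sampling_interval_hours = 2,
                              duration_hours = 48,
                              replicates = 3,
                              start_time_hours = 0,
                              regime_schedule = c("LD", "DD"),
                              seed = 1L,
                              allow_negative = FALSE) {
  cfg <- list(n_genes = as.integer(n_genes),
              cycler_fraction = cycler_fraction,
              period_hours = period_hours,
              amplitude = amplitude,
              mesor = mesor,
              amplitude_to_noise = amplitude_to_noise,
              sampling_interval_hours = sampling_interval_hours,
              duration_hours = duration_hours,
              replicates = as.integer(replicates),
              start_time_hours = start_time_hours,
              regime_schedule = regime_schedule,
              seed = as.integer(seed),
              allow_negative = isTRUE(allow_negative))
  problems <- character(0)
  if (cfg$n_genes < 1) problems <- c(problems, "n_genes must be >= 1")
  if (cfg$cycler_fraction < 0 || cfg$cycler_fraction > 1)
    problems <- c(problems, "cycler_fraction must lie in [0, 1]")
  if (cfg$period_hours <= 0) problems <- c(problems, "period_hours must be > 0")
  if (cfg$amplitude < 0) problems <- c(problems, "amplitude must be >= 0")
  if (cfg$mesor <= 0) problems <- c(problems, "mesor must be > 0")
  if (!cfg$allow_negative && cfg$mesor < cfg$amplitude)
    problems <- c(problems,
                  "mesor < amplitude would yield negative traces; set allow_negative = TRUE to permit")
  if (cfg$amplitude_to_noise <= 0)
    problems <- c(problems, "amplitude_to_noise must be > 0 (use Inf for noiseless)")
  if (cfg$sampling_interval_hours <= 0 || cfg$duration_hours <= 0)
    problems <- c(problems, "sampling interval and duration must be > 0")
  n_int <- cfg$duration_hours / cfg$sampling_interval_hours
  if (abs(n_int - round(n_int)) > 1e-9)
    problems <- c(problems,
                  "duration_hours must be an integer multiple of sampling_interval_hours")
  if (cfg$replicates < 1) problems <- c(problems, "replicates must be >= 1")
  if (cfg$start_time_hours < 0 || cfg$start_time_hours >= 24)
    problems <- c(problems, "start_time_hours must lie in [0, 24)")
  if (!all(cfg$regime_schedule %in% c("LD", "DD")))
    problems <- c(problems, "regime_schedule entries must be 'LD' or 'DD'")
  if (length(problems))
    stop("invalid simulation config:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Per-line genotype effect on the molecular clock
#'
#' Describes how one line's internal clock deviates from the reference:
#' a signed phase advance, an altered free-running period, and an optional
#' clock disruption that damps cycling amplitude (default damping 0, i.e.
#' cycling abolished).  A line with period `P` maps wall time `t` to internal
#' time `tau = (24 / P) * (t + phase_offset)`, clocks aligned at `t = 0`.
#'
#' @param line_id Line identifier.
#' @param phase_offset_hours Signed internal-clock advance (hours); positive
#'   means the line runs ahead of the reference.
#' @param period_hours The line's molecular period (hours).
#' @param disrupted If `TRUE`, cycling amplitude is multiplied by
#'   `damping`.
#' @param damping Amplitude multiplier applied when `disrupted` (default 0).
#' @return A list of class `line_effect`.
#' @export
line_effect <- function(line_id, phase_offset_hours = 0, period_hours = 24,
                        disrupted = FALSE, damping = 0) {
  if (period_hours <= 0) stop("period_hours must be > 0", call. = FALSE)
  structure(list(line_id = as.character(line_id),
                 phase_offset_hours = phase_offset_hours %% period_hours,
                 period_hours = period_hours,
                 disrupted = isTRUE(disrupted),
                 damping = damping),
            class = "line_effect")
}

# Evenly tiled cycler phases: deterministic tiling keeps the reference
# identifiable and makes noiseless phase recovery exact.
tile_phases <- function(n) (seq_len(n) - 1) * 24 / n

# Gaussian noise matrix; zero when ANR is infinite.
sim_noise <- function(nr, nc, amplitude, anr) {
  if (is.infinite(anr)) return(matrix(0, nr, nc))
  matrix(stats::rnorm(nr * nc, sd = amplitude / anr), nr, nc)
}

#' Simulate a reference circadian time course
#'
#' Generates the two-day reference design the timetable method is trained
#' on: samples every `sampling_interval_hours` over `duration_hours` with
#' `replicates` biological replicates per timepoint, the first day(s) under
#' the schedule in `regime_schedule`.  Cycling genes follow
#' `mesor + amplitude * cos(2*pi*(t - phase)/period) + noise`; the remaining
#' genes are flat (`mesor + noise`).
#'
#' @param config A [simulation_config()].
#' @param true_phases Either `"uniform"` (cycler peak phases tile `[0, 24)`
#'   evenly) or a numeric vector of peak phases in hours, one per cycler.
#' @param tissue Tissue label stamped on all samples.
#' @param line_id Line label stamped on all samples.
#'
#' @return A list with elements `expression` (an [expression_set()]; the
#'   sample table additionally carries the day index and absolute
#'   experiment time `time_abs_hours`) and `truth` (data frame: `gene_id`,
#'   `cycling`, `phase_hours`, `amplitude`, `mesor`).
#'
#' @examples
#' cfg <- simulation_config(n_genes = 20, seed = 7)
#' ref <- generate_reference_timecourse(cfg)
#' dim(ref$expression)            # 20 x 72: 24 timepoints, triplicates
#' head(ref$truth)
#' @export
generate_reference_timecourse <- function(config, true_phases = "uniform",
                                          tissue = "tissue1",
                                          line_id = "reference") {
  stopifnot(inherits(config, "sim_config"))
  n_cyc <- round(config$cycler_fraction * config$n_genes)
  if (n_cyc >= 1 && n_cyc < 2)
    stop("need at least 2 cycling genes for a usable reference", call. = FALSE)

  if (identical(true_phases, "uniform")) {
    phases <- tile_phases(n_cyc)
  } else {
    phases <- as.numeric(true_phases)
    if (length(phases) != n_cyc)
      stop("true_phases must supply one phase per cycling gene (",
           n_cyc, " needed)", call. = FALSE)
    phases <- phases %% 24
  }

  t_grid <- seq(0, config$duration_hours - config$sampling_interval_hours,
                by = config$sampling_interval_hours)
  t_abs <- rep(t_grid, each = config$replicates) + config$start_time_hours
  replicate <- rep(seq_len(config$replicates), times = length(t_grid))
  day <- floor(t_abs / 24)
  regime <- config$regime_schedule[pmin(day + 1, length(config$regime_schedule))]

  gene_ids <- sprintf("gene_%03d", seq_len(config$n_genes))
  cycling <- c(rep(TRUE, n_cyc), rep(FALSE, config$n_genes - n_cyc))
  phase_col <- c(phases, rep(NA_real_, config$n_genes - n_cyc))

  signal <- matrix(config$mesor, config$n_genes, length(t_abs))
  if (n_cyc > 0)
    signal[seq_len(n_cyc), ] <- config$mesor + config$amplitude *
      cos(outer(phases, t_abs, function(ph, t) 2 * pi * (t - ph) / config$period_hours))

  set.seed(config$seed)
  values <- signal + sim_noise(config$n_genes, length(t_abs),
                               config$amplitude, config$amplitude_to_noise)
  dimnames(values) <- list(gene_ids,
                           sprintf("%s_t%05.1f_r%d", tissue, t_abs, replicate))

  samples <- data.frame(sample_id = colnames(values),
                        line_id = line_id,
                        tissue = tissue,
                        time_hours = t_abs %% 24,
                        regime = regime,
                        replicate = replicate,
                        day = day,
                        time_abs_hours = t_abs)
  truth <- data.frame(gene_id = gene_ids,
                      cycling = cycling,
                      phase_hours = phase_col,
                      amplitude = ifelse(cycling, config$amplitude, 0),
                      mesor = config$mesor)
  list(expression = expression_set(values, samples), truth = truth)
}

#' Simulate a high-frequency static cohort
#'
#' One sample per line, harvest times forming an arithmetic sequence modulo
#' 24 h (the around-the-clock collection design, default spacing ~9 min).
#' Expression of gene `g` in line `L` harvested at wall time `t` equals the
#' reference 24-hour waveform evaluated at the line's internal time
#' `tau = (24 / period_L) * (t + phase_offset_L)`, with cycling amplitude
#' damped for disrupted lines, plus noise.
#'
#' @param config A [simulation_config()].
#' @param effects List of [line_effect()] objects, one per line.
#' @param interval_minutes Spacing between successive line harvests (min).
#' @param true_phases As in [generate_reference_timecourse()].
#' @param tissue Tissue label.
#'
#' @return List with `expression` (an [expression_set()], one column per
#'   line) and `truth` (per-line effect table joined to the per-gene truth
#'   via attributes `gene_truth`).
#'
#' @examples
#' cfg <- simulation_config(n_genes = 20, seed = 3)
#' eff <- lapply(1:10, function(i) line_effect(paste0("line", i)))
#' coh <- generate_static_cohort(cfg, eff, interval_minutes = 9.5)
#' coh$expression$samples$time_hours[1:3]
#' @export
generate_static_cohort <- function(config, effects, interval_minutes = 9,
                                   true_phases = "uniform",
                                   tissue = "tissue1") {
  stopifnot(inherits(config, "sim_config"))
  if (length(effects) == 0) stop("empty effects list", call. = FALSE)
  if (interval_minutes <= 0) stop("interval_minutes must be > 0", call. = FALSE)
  ok <- vapply(effects, inherits, logical(1), "line_effect")
  if (!all(ok)) stop("all effects must be line_effect objects", call. = FALSE)

  n_cyc <- round(config$cycler_fraction * config$n_genes)
  phases <- if (identical(true_phases, "uniform")) tile_phases(n_cyc)
            else as.numeric(true_phases) %% 24
  if (length(phases) != n_cyc)
    stop("true_phases must supply one phase per cycling gene", call. = FALSE)

  n_lines <- length(effects)
  t_harvest <- (config$start_time_hours +
                (seq_len(n_lines) - 1) * interval_minutes / 60) %% 24
  line_ids <- vapply(effects, `[[`, character(1), "line_id")
  if (anyDuplicated(line_ids))
    stop("duplicate line ids in effects", call. = FALSE)

  gene_ids <- sprintf("gene_%03d", seq_len(config$n_genes))
  values <- matrix(config$mesor, config$n_genes, n_lines)
  for (j in seq_len(n_lines)) {
    ef <- effects[[j]]
    tau <- (24 / ef$period_hours) * (t_harvest[j] + ef$phase_offset_hours)
    amp <- config$amplitude * if (ef$disrupted) ef$damping else 1
    if (n_cyc > 0)
      values[seq_len(n_cyc), j] <- config$mesor +
        amp * cos(2 * pi * (tau - phases) / 24)
  }
  set.seed(config$seed)
  values <- values + sim_noise(config$n_genes, n_lines,
                               config$amplitude, config$amplitude_to_noise)
  dimnames(values) <- list(gene_ids, line_ids)

  samples <- data.frame(sample_id = line_ids,
                        line_id = line_ids,
                        tissue = tissue,
                        time_hours = t_harvest,
                        regime = "DD",
                        replicate = 1L)
  truth <- data.frame(
    line_id = line_ids,
    phase_offset_hours = vapply(effects, `[[`, numeric(1), "phase_offset_hours"),
    period_hours = vapply(effects, `[[`, numeric(1), "period_hours"),
    disrupted = vapply(effects, `[[`, logical(1), "disrupted"),
    harvest_time_hours = t_harvest)
  attr(truth, "gene_truth") <- data.frame(
    gene_id = gene_ids,
    cycling = seq_len(config$n_genes) <= n_cyc,
    phase_hours = c(phases, rep(NA_real_, config$n_genes - n_cyc)))
  list(expression = expression_set(values, samples), truth = truth)
}

#' Simulate a single deviating circadian trace on the 10-minute day grid
#'
#' The one-gene sinusoid model used for detection-window illustration: a
#' sine wave of amplitude `config$amplitude` sampled every 10 minutes over
#' one 24-hour day (144 points, half-open grid), for a clock with the given
#' free-running period and phase advance:
#' `amplitude * sin(2*pi*(t + phase_offset)/period) + noise`.
#'
#' @param period_hours The trace's oscillation period (hours).
#' @param phase_offset_hours Signed phase advance (hours).
#' @param config A [simulation_config()]; supplies amplitude and noise.
#' @param grid_minutes Sampling step of the day grid (default 10 min).
#' @return Data frame with `time_hours` (144 rows for the default grid) and
#'   `value`.
#'
#' @examples
#' cfg <- simulation_config(amplitude_to_noise = Inf)
#' tr <- make_deviating_trace(24, 0, cfg)
#' nrow(tr)    # 144
#' @export
make_deviating_trace <- function(period_hours, phase_offset_hours = 0,
                                 config = simulation_config(),
                                 grid_minutes = 10) {
  stopifnot(inherits(config, "sim_config"))
  if (period_hours <= 0) stop("period_hours must be > 0", call. = FALSE)
  t <- seq(0, 24 - grid_minutes / 60, by = grid_minutes / 60)
  tau <- t + phase_offset_hours
  set.seed(config$seed)
  y <- config$amplitude * sin(2 * pi * tau / period_hours) +
    as.numeric(sim_noise(1, length(t), config$amplitude,
                         config$amplitude_to_noise))
  data.frame(time_hours = t, value = y)
}
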