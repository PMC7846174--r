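#' Read an expression matrix and its sample metadata from TSV
#'
#' The matrix file is tab-separated with a header row of sample ids and a
#' first column `gene_id`; the metadata file is tab-separated with one row
#' per sample (`sample_id`, `line_id`, `tissue`, `time_hours`, `regime`,
#' `replicate`, plus any extra columns, which are preserved).  Harvest times
#' outside `[0, 24)` are wrapped modulo 24 with a warning.
#'
#' @param matrix_path Path to the expression TSV.
#' @param metadata_path Path to the sample-metadata TSV.
#' @return An [expression_set()].
#' @export
read_expression_tsv <- function(matrix_path, metadata_path) {
  for (p in c(matrix_path, metadata_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene_id")
    stop("first column of ", matrix_path, " must be 'gene_id' (found '",
         names(tab)[1], "')", call. = FALSE)
  genes <- tab$gene_id
  vals <- tab[, -1, drop = FALSE]
  non_num <- !vapply(vals, is.numeric, logical(1))
  if (any(non_num))
    stop("non-numeric expression column(s): ",
         paste(names(vals)[non_num], collapse = ", "), call. = FALSE)
  m <- as.matrix(vals)
  rownames(m) <- genes
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  expression_set(m, meta)
}

#' Write an expression set to TSV files
#'
#' Emits the matrix (`<prefix>_matrix.tsv`, first column `gene_id`) and the
#' sample metadata (`<prefix>_samples.tsv`).  Values are written with full
#' precision so that a read/write round trip is bit-exact.
#'
#' @param x An [expression_set()].
#' @param prefix Output path prefix (directories must exist).
#' @return Invisibly, the two file paths.
#' @export
write_expression_set <- function(x, prefix) {
  stopifnot(inherits(x, "expression_set"))
  mat_path <- paste0(prefix, "_matrix.tsv")
  meta_path <- paste0(prefix, "_samples.tsv")
  tab <- data.frame(gene_id = rownames(x$values),
                    format(x$values, digits = 17, trim = TRUE,
                           scientific = TRUE),
                    check.names = FALSE)
  utils::write.table(tab, mat_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix = mat_path, samples = meta_path))
}

#' Write a timetable model to TSV + JSON header
#'
#' @param model A [select_tigs()] model.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_timetable <- function(model, prefix) {
  stopifnot(inherits(model, "timetable_model"))
  tig_path <- paste0(prefix, "_tigs.tsv")
  set_path <- paste0(prefix, "_settings.json")
  utils::write.table(model$tigs, tig_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(mode = model$mode, r_cutoff = model$r_cutoff,
                            cv_cutoff = model$cv_cutoff,
                            bundle_period_hours = model$bundle$period_hours,
                            bundle_increment_hours = model$bundle$increment_hours),
                       set_path, auto_unbox = TRUE, digits = NA)
  invisible(c(tigs = tig_path, settings = set_path))
}

#' Validated pipeline configuration
#'
#' Collects every tunable of the simulate/select/predict/evaluate/window
#' pipeline, validates all settings at once and reports every violation in
#' a single error.  Accepts either explicit arguments or a YAML/JSON file
#' via `load_pipeline_config()`.
#'
#' @param output_dir Directory for pipeline artifacts.
#' @param bundle_period_hours,bundle_increment_hours Cosine-bundle settings.
#' @param mode TIG selection mode (`"LDDD_05"` or `"LD_DD_05"`).
#' @param r_cutoff,cv_cutoff TIG selection cutoffs.
#' @param outlier_threshold_hours Outlier flag threshold.
#' @param window_grid_minutes Detection-window scan step.
#' @param simulation A [simulation_config()] (or argument list for one).
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir = ".",
                            bundle_period_hours = 24,
                            bundle_increment_hours = 10 / 60,
                            mode = "LDDD_05",
                            r_cutoff = 0.5,
                            cv_cutoff = 0.20,
                            outlier_threshold_hours = 3.4,
                            window_grid_minutes = 1,
                            simulation = simulation_config(),
                            seed = 1L) {
  if (is.list(simulation) && !inherits(simulation, "sim_config"))
    simulation <- do.call(simulation_config, simulation)
  problems <- character(0)
  if (!mode %in% c("LDDD_05", "LD_DD_05"))
    problems <- c(problems, "mode must be 'LDDD_05' or 'LD_DD_05'")
  if (!is.numeric(r_cutoff) || r_cutoff < -1 || r_cutoff > 1)
    problems <- c(problems, "r_cutoff must lie in [-1, 1]")
  if (!is.numeric(cv_cutoff) || cv_cutoff < 0)
    problems <- c(problems, "cv_cutoff must be >= 0")
  if (outlier_threshold_hours <= 0)
    problems <- c(problems, "outlier_threshold_hours must be > 0")
  if (window_grid_minutes <= 0)
    problems <- c(problems, "window_grid_minutes must be > 0")
  n <- bundle_period_hours / bundle_increment_hours
  if (bundle_period_hours <= 0 || bundle_increment_hours <= 0 ||
      abs(n - round(n)) > 1e-9)
    problems <- c(problems,
                  "bundle period must be a positive integer multiple of the increment")
  if (length(problems))
    stop("invalid pipeline config:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  structure(list(output_dir = output_dir,
                 bundle_period_hours = bundle_period_hours,
                 bundle_increment_hours = bundle_increment_hours,
                 mode = mode, r_cutoff = r_cutoff, cv_cutoff = cv_cutoff,
                 outlier_threshold_hours = outlier_threshold_hours,
                 window_grid_minutes = window_grid_minutes,
                 simulation = simulation,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` (requires the yaml package) or
#'   `.json` file whose keys match the arguments of [pipeline_config()];
#'   a `simulation` sub-map is passed to [simulation_config()].
#' @return A validated [pipeline_config()].
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, raw)
}

# Per-stage seeds derived from the master seed (kept below 2^31).
stage_seed <- function(seed, stage) {
  (as.integer(seed) + 1000L * match(stage, c("simulate", "evaluate",
                                             "window"))) %% .Machine$integer.max
}

#' Run the simulate / train / evaluate pipeline and write its artifacts
#'
#' Generates a reference time course from the configured simulation,
#' selects time-indicating genes, runs the leave-one-out evaluation, flags
#' outliers, and writes every artifact (matrix + metadata TSVs, TIG table,
#' per-fold predictions, JSON summary) together with a run manifest
#' recording settings, seed and package version.  Output is deterministic
#' given the config seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`reference`,
#'   `model`, `evaluation`, `outliers`) and the manifest path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)

  sim <- config$simulation
  sim$seed <- stage_seed(config$seed, "simulate")
  ref <- generate_reference_timecourse(sim)
  write_expression_set(ref$expression, out("reference"))
  utils::write.table(ref$truth, out("reference_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  bundle <- build_cosine_bundle(config$bundle_period_hours,
                                config$bundle_increment_hours)
  model <- select_tigs(ref$expression, bundle = bundle, mode = config$mode,
                       r_cutoff = config$r_cutoff,
                       cv_cutoff = config$cv_cutoff)
  write_timetable(model, out("timetable"))

  report <- loo_evaluate(ref$expression,
                         mtt_predictor(bundle = bundle, mode = config$mode,
                                       r_cutoff = config$r_cutoff,
                                       cv_cutoff = config$cv_cutoff))
  flagged <- flag_outliers(report$per_sample,
                           threshold_hours = config$outlier_threshold_hours)
  utils::write.table(flagged, out("loo_predictions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(mean_abs_diff_hours = report$mean_abs_diff_hours,
         sd_signed_diff_hours = report$sd_signed_diff_hours,
         precision_hours = report$precision_hours,
         n_folds = nrow(report$per_sample),
         n_outliers = sum(flagged$outlier)),
    out("evaluation_summary.json"), auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package = "circatime",
    version = as.character(utils::packageVersion("circatime")),
    seed = config$seed,
    settings = config[setdiff(names(config), "simulation")],
    simulation = unclass(config$simulation))
  jsonlite::write_json(manifest, out("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(reference = ref, model = model, evaluation = report,
                 outliers = flagged,
                 manifest = out("run_manifest.json")))
}
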