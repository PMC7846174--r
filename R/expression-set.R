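#' Gene-by-sample expression container with per-sample metadata
#'
#' An `expression_set` couples a numeric genes x samples matrix to a
#' sample-metadata table.  Every downstream stage (scaling, timetable
#' construction, leave-one-out evaluation, cosinor fitting) consumes this
#' container, so its invariants are enforced at construction: unique gene and
#' sample identifiers, matching dimensions, finite values, and harvest times
#' on the circadian axis `[0, 24)`.
#'
#' @param values Numeric matrix, genes as rows and samples as columns.
#'   Rownames are gene identifiers, colnames sample identifiers.
#' @param samples Data frame with one row per column of `values`, carrying at
#'   least `sample_id`, `line_id`, `tissue`, `time_hours` (harvest time,
#'   hours), `regime` (`"LD"` or `"DD"`) and `replicate`.  Harvest times
#'   outside `[0, 24)` are wrapped modulo 24 with a warning.
#'
#' @return An object of class `expression_set`: a list with elements
#'   `values` (the matrix) and `samples` (the metadata, row order matching
#'   the matrix columns).
#'
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' meta <- data.frame(sample_id = paste0("s", 1:4), line_id = "w1118",
#'                    tissue = "brain", time_hours = c(1, 3, 5, 7),
#'                    regime = "LD", replicate = 1L)
#' es <- expression_set(m, meta)
#' dim(es)
#' @export
expression_set <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  if (!all(is.finite(values)))
    stop("non-finite expression values at ",
         sum(!is.finite(values)), " cell(s)", call. = FALSE)

  samples <- as.data.frame(samples)
  required <- c("sample_id", "line_id", "tissue", "time_hours", "regime",
                "replicate")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols))
    stop("sample metadata lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!setequal(samples$sample_id, colnames(values)))
    stop("sample ids in metadata and matrix header differ: missing from ",
         "metadata: ",
         paste(setdiff(colnames(values), samples$sample_id), collapse = ", "),
         "; missing from matrix: ",
         paste(setdiff(samples$sample_id, colnames(values)), collapse = ", "),
         call. = FALSE)
  if (nrow(samples) != ncol(values))
    stop("metadata has ", nrow(samples), " rows but matrix has ",
         ncol(values), " samples", call. = FALSE)
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL

  if (!is.numeric(samples$time_hours) || !all(is.finite(samples$time_hours)))
    stop("`time_hours` must be finite numeric", call. = FALSE)
  off_axis <- samples$time_hours < 0 | samples$time_hours >= 24
  if (any(off_axis)) {
    warning(sum(off_axis), " harvest time(s) outside [0, 24) wrapped modulo 24",
            call. = FALSE)
    samples$time_hours <- samples$time_hours %% 24
  }
  bad_regime <- !samples$regime %in% c("LD", "DD")
  if (any(bad_regime))
    stop("regime must be 'LD' or 'DD' (offending sample(s): ",
         paste(samples$sample_id[bad_regime], collapse = ", "), ")",
         call. = FALSE)

  structure(list(values = values, samples = samples),
            class = "expression_set")
}

#' @export
dim.expression_set <- function(x) dim(x$values)

#' @export
print.expression_set <- function(x, ...) {
  cat("expression_set: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples\n", sep = "")
  cat("tissues: ", paste(unique(x$samples$tissue), collapse = ", "), "\n",
      sep = "")
  cat("harvest times: ", paste(range(x$samples$time_hours), collapse = " - "),
      " h; regimes: ", paste(unique(x$samples$regime), collapse = "/"),
      "\n", sep = "")
  invisible(x)
}

#' Subset an expression set by genes and/or samples
#'
#' @param x An `expression_set`.
#' @param genes Gene ids, indices or logical mask (default: all).
#' @param samples Sample ids, indices or logical mask (default: all).
#' @return A new `expression_set` restricted to the selection.
#' @export
subset_expression <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "expression_set"))
  v <- x$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  meta <- x$samples[match(colnames(v), x$samples$sample_id), , drop = FALSE]
  expression_set(v, meta)
}
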