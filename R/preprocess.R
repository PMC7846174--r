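#' Scale each gene to the unit interval
#'
#' Per gene, maps the minimum observed value to 0 and the maximum to 1
#' (`(x - min) / (max - min)`), the standardization applied before phase
#' inference.  Genes constant across samples have no defined scaling and are
#' dropped with a warning; their ids are recorded in the `dropped` attribute
#' of the result.
#'
#' @param x An [expression_set()].
#' @return An `expression_set` with scaled values, possibly fewer genes.
#' @examples
#' m <- matrix(c(2, 4, 6, 5, 5, 5), 2, 3, byrow = TRUE,
#'             dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
#' meta <- data.frame(sample_id = colnames(m), line_id = "l", tissue = "t",
#'                    time_hours = c(0, 8, 16), regime = "DD", replicate = 1L)
#' es <- suppressWarnings(scale_unit_interval(expression_set(m, meta)))
#' es$values["a", ]   # 0, 0.5, 1
#' attr(es, "dropped")
#' @export
scale_unit_interval <- function(x) {
  stopifnot(inherits(x, "expression_set"))
  rng <- t(apply(x$values, 1, range))
  constant <- rng[, 2] - rng[, 1] <= 0
  if (any(constant))
    warning("dropped ", sum(constant), " constant gene(s): ",
            paste(utils::head(rownames(x$values)[constant], 10), collapse = ", "),
            if (sum(constant) > 10) ", ..." else "", call. = FALSE)
  keep <- !constant
  v <- (x$values[keep, , drop = FALSE] - rng[keep, 1]) /
    (rng[keep, 2] - rng[keep, 1])
  out <- expression_set(v, x$samples)
  attr(out, "dropped") <- rownames(x$values)[constant]
  out
}

#' Coefficient of variation of a trace
#'
#' `sd / mean` with the sample standard deviation (n - 1 denominator).  The
#' CV is only meaningful for positive-mean traces; a non-positive mean is an
#' error.  The high-amplitude filter for time-indicating genes requires
#' CV > 0.20 on the unscaled expression values.
#'
#' @param x Numeric vector of expression values.
#' @return The coefficient of variation (dimensionless).
#' @examples
#' coefficient_of_variation(c(8, 12))  # sqrt(8)/10 ~= 0.2828
#' @export
coefficient_of_variation <- function(x) {
  if (!is.numeric(x) || length(x) < 2)
    stop("need a numeric trace of length >= 2", call. = FALSE)
  m <- mean(x)
  if (m <= 0)
    stop("coefficient of variation undefined for mean <= 0 (mean = ",
         format(m), ")", call. = FALSE)
  stats::sd(x) / m
}

#' Per-gene summary statistics
#'
#' Mean, sample SD and CV for every gene of an expression set.  Genes with
#' non-positive mean get `cv = NA` and `cv_defined = FALSE`; CV-based filters
#' must exclude them.
#'
#' @param x An [expression_set()].
#' @return Data frame: `gene_id`, `mean`, `sd`, `cv`, `cv_defined`.
#' @export
gene_summary <- function(x) {
  stopifnot(inherits(x, "expression_set"))
  mu <- rowMeans(x$values)
  sdv <- apply(x$values, 1, stats::sd)
  defined <- mu > 0
  data.frame(gene_id = rownames(x$values),
             mean = mu,
             sd = sdv,
             cv = ifelse(defined, sdv / mu, NA_real_),
             cv_defined = defined,
             row.names = NULL)
}

#' Average replicates within (line, tissue, timepoint, regime)
#'
#' Collapses biological replicates to their arithmetic mean per gene; groups
#' with differing replicate counts are averaged over whatever replicates are
#' available.  The collapsed metadata keeps one row per group with
#' `replicate = 1` and records the number averaged in `n_replicates`.
#'
#' @param x An [expression_set()].
#' @return An `expression_set` with one column per
#'   (line, tissue, time, regime) group.
#' @export
average_replicates <- function(x) {
  stopifnot(inherits(x, "expression_set"))
  s <- x$samples
  key <- paste(s$line_id, s$tissue,
               if ("time_abs_hours" %in% names(s)) s$time_abs_hours else s$time_hours,
               s$regime, sep = "\r")
  groups <- split(seq_len(nrow(s)), key)
  # preserve the original sample order via the first member of each group
  groups <- groups[order(vapply(groups, min, integer(1)))]
  v <- vapply(groups, function(idx) rowMeans(x$values[, idx, drop = FALSE]),
              numeric(nrow(x$values)))
  if (is.null(dim(v))) v <- matrix(v, nrow = nrow(x$values))
  first <- vapply(groups, `[`, integer(1), 1)
  meta <- s[first, , drop = FALSE]
  meta$replicate <- 1L
  meta$n_replicates <- lengths(groups)
  meta$sample_id <- sub("_r[0-9]+$", "", meta$sample_id)
  if (anyDuplicated(meta$sample_id))
    meta$sample_id <- make.unique(meta$sample_id, sep = "_g")
  dimnames(v) <- list(rownames(x$values), meta$sample_id)
  expression_set(v, meta)
}
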