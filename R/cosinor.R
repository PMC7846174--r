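#' Fit a single-component cosinor model to a trace
#'
#' Least-squares fit of `y = M + A * cos(2*pi*(t - phi)/period)` via the
#' linear reparameterization `y ~ cos(wt) + sin(wt)` with `w = 2*pi/period`:
#' `A = sqrt(b1^2 + b2^2)`, acrophase `phi = atan2(b2, b1)/w` mapped to
#' `[0, period)`.  Standard errors for amplitude and acrophase come from the
#' linear-model covariance via the delta method.  The period is fixed, not
#' estimated.
#'
#' @param values Numeric trace.
#' @param times Timestamps (hours), same length.
#' @param period_hours Fixed period of the fitted cosine (default 24).
#' @return List of class `cosinor_fit`: `mesor`, `amplitude`,
#'   `acrophase_hours`, their standard errors (`se_mesor`, `se_amplitude`,
#'   `se_acrophase_hours`), `sigma2` (residual variance), `n`,
#'   `period_hours`, and `p_zero_amplitude` (F-test of the cosine terms).
#' @examples
#' t <- seq(0, 46, 2)
#' f <- fit_cosinor(5 + 2 * cos(2 * pi * (t - 10) / 24), t)
#' c(f$mesor, f$amplitude, f$acrophase_hours)   # 5 2 10
#' @export
fit_cosinor <- function(values, times, period_hours = 24) {
  if (length(values) != length(times))
    stop("values and times lengths differ", call. = FALSE)
  if (length(values) < 4)
    stop("need >= 4 timepoints for a cosinor fit", call. = FALSE)
  if (diff(range(times)) <= period_hours / 2)
    stop("timestamps must span more than half a period", call. = FALSE)
  w <- 2 * pi / period_hours
  cw <- cos(w * times)
  sw <- sin(w * times)
  X <- cbind(1, cw, sw)
  if (qr(X, tol = 1e-10)$rank < 3 ||
      min(colSums(X^2)[2:3]) < 1e-12 * length(values))
    stop("rank-deficient cosinor design (timestamps congruent modulo ",
         "period/2?)", call. = FALSE)
  fit <- stats::lm(values ~ cw + sw)
  b <- stats::coef(fit)
  if (anyNA(b))
    stop("rank-deficient cosinor design (timestamps congruent modulo ",
         "period/2?)", call. = FALSE)
  V <- suppressWarnings(stats::vcov(fit))   # perfect fits are supported
  b1 <- b[["cw"]]; b2 <- b[["sw"]]
  amp <- sqrt(b1^2 + b2^2)
  acro <- (atan2(b2, b1) / w) %% period_hours

  # delta method: grad_A = (b1, b2)/A; grad_phi = (-b2, b1)/(A^2 * w)
  if (amp > 0) {
    gA <- c(b1, b2) / amp
    se_amp <- sqrt(drop(t(gA) %*% V[2:3, 2:3] %*% gA))
    gP <- c(-b2, b1) / (amp^2 * w)
    se_acro <- sqrt(drop(t(gP) %*% V[2:3, 2:3] %*% gP))
  } else {
    se_amp <- sqrt(max(diag(V)[2:3]))
    se_acro <- Inf
  }
  null_fit <- stats::lm(values ~ 1)
  # noiseless inputs fit exactly; the perfect-fit warning is expected there
  an <- suppressWarnings(stats::anova(null_fit, fit))
  p_amp <- an[["Pr(>F)"]][2]
  if (is.na(p_amp)) p_amp <- 1   # zero residual variance in both models

  structure(list(mesor = unname(b[1]),
                 amplitude = amp,
                 acrophase_hours = acro,
                 se_mesor = sqrt(V[1, 1]),
                 se_amplitude = se_amp,
                 se_acrophase_hours = se_acro,
                 sigma2 = suppressWarnings(summary(fit))$sigma^2,
                 n = length(values),
                 period_hours = period_hours,
                 p_zero_amplitude = p_amp),
            class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf("cosinor fit (period %.1f h): mesor %.4g (SE %.3g), amplitude %.4g (SE %.3g), acrophase %.3f h (SE %.3g)\n",
              x$period_hours, x$mesor, x$se_mesor, x$amplitude,
              x$se_amplitude, x$acrophase_hours, x$se_acrophase_hours))
  invisible(x)
}

#' Detect cycling genes by a cosinor zero-amplitude test
#'
#' Per gene: scale to `[0, 1]`, fit a fixed-period cosinor and test the
#' cosine terms against the mesor-only model (F test), then adjust p-values
#' across genes by Benjamini-Hochberg.  A gene cycles iff its q-value is
#' below `alpha`.  Constant genes are dropped (no defined scaling).
#'
#' @param x An [expression_set()].
#' @param period_hours Fixed test period (default 24).
#' @param alpha FDR level (default 0.05).
#' @return Data frame, one row per tested gene: `gene_id`, `mesor`,
#'   `amplitude`, `acrophase_hours`, `se_amplitude`, `se_acrophase_hours`,
#'   `p_value`, `q_value`, `cycling`.
#' @export
detect_cycling <- function(x, period_hours = 24, alpha = 0.05) {
  stopifnot(inherits(x, "expression_set"))
  scaled <- suppressWarnings(scale_unit_interval(x))
  times <- sample_times(scaled)
  fits <- lapply(seq_len(nrow(scaled$values)), function(i)
    fit_cosinor(scaled$values[i, ], times, period_hours))
  out <- data.frame(
    gene_id = rownames(scaled$values),
    mesor = vapply(fits, `[[`, numeric(1), "mesor"),
    amplitude = vapply(fits, `[[`, numeric(1), "amplitude"),
    acrophase_hours = vapply(fits, `[[`, numeric(1), "acrophase_hours"),
    se_amplitude = vapply(fits, `[[`, numeric(1), "se_amplitude"),
    se_acrophase_hours = vapply(fits, `[[`, numeric(1), "se_acrophase_hours"),
    p_value = vapply(fits, `[[`, numeric(1), "p_zero_amplitude"),
    row.names = NULL)
  out$q_value <- bh_fdr(out$p_value)
  out$cycling <- out$q_value < alpha
  attr(out, "fits") <- fits
  out
}

#' Compare the acrophases of two cosinor fits
#'
#' Wald test on the signed circular difference of acrophases with
#' delta-method standard errors.  A phase shift is called significant only
#' when both conditions hold: the absolute difference exceeds
#' `min_shift_hours` (default 2 h, dictated by the sampling frequency of
#' the underlying design) and the FDR-adjusted p-value is below
#' `fdr_alpha`.  When comparing a batch of gene pairs, compute q-values
#' across the batch with [compare_phases_batch()]; for a single standalone
#' comparison `q_value` equals `p_value`.
#'
#' @param fit_a,fit_b [fit_cosinor()] objects of the same period.
#' @param min_shift_hours Minimum absolute phase difference (strict).
#' @param fdr_alpha FDR significance level.
#' @param q_value Optional externally adjusted q-value (from a batch).
#' @return List of class `phase_comparison`: `delta_phase_hours` (signed,
#'   `a` relative to `b`), `se_delta`, `p_value`, `q_value`, `significant`.
#' @export
compare_phases <- function(fit_a, fit_b, min_shift_hours = 2,
                           fdr_alpha = 0.05, q_value = NULL) {
  stopifnot(inherits(fit_a, "cosinor_fit"), inherits(fit_b, "cosinor_fit"))
  if (fit_a$period_hours != fit_b$period_hours)
    stop("fits have different periods", call. = FALSE)
  for (f in list(fit_a, fit_b))
    if (!is.finite(f$se_acrophase_hours) ||
        (is.finite(f$se_amplitude) && f$se_amplitude > 0 &&
         f$amplitude / f$se_amplitude < 2))
      stop("amplitude not significantly above zero; phase comparison ",
           "undefined", call. = FALSE)
  p_len <- fit_a$period_hours
  d <- (fit_a$acrophase_hours - fit_b$acrophase_hours) %% p_len
  if (d > p_len / 2) d <- d - p_len
  se <- sqrt(fit_a$se_acrophase_hours^2 + fit_b$se_acrophase_hours^2)
  z <- if (se > 0) d / se else if (d == 0) 0 else sign(d) * Inf
  p <- 2 * stats::pnorm(-abs(z))
  q <- if (is.null(q_value)) p else q_value
  structure(list(delta_phase_hours = d,
                 se_delta = se,
                 p_value = p,
                 q_value = q,
                 significant = abs(d) > min_shift_hours && q < fdr_alpha),
            class = "phase_comparison")
}

#' Batch phase comparison with shared FDR adjustment
#'
#' Runs [compare_phases()] over paired lists of fits (e.g. the same genes in
#' two tissues), adjusts the p-values across the batch by
#' Benjamini-Hochberg, and applies the joint significance rule (absolute
#' shift above `min_shift_hours` and q below `fdr_alpha`).  Pairs whose
#' comparison is undefined (amplitude not above zero) are returned with
#' `NA` statistics.
#'
#' @param fits_a,fits_b Lists of [fit_cosinor()] objects, same length.
#' @param ids Optional identifiers for the pairs.
#' @inheritParams compare_phases
#' @return Data frame: `id`, `delta_phase_hours`, `se_delta`, `p_value`,
#'   `q_value`, `significant`.
#' @export
compare_phases_batch <- function(fits_a, fits_b, ids = NULL,
                                 min_shift_hours = 2, fdr_alpha = 0.05) {
  if (length(fits_a) != length(fits_b))
    stop("fit lists have different lengths", call. = FALSE)
  if (is.null(ids)) ids <- as.character(seq_along(fits_a))
  raw <- lapply(seq_along(fits_a), function(i)
    tryCatch(compare_phases(fits_a[[i]], fits_b[[i]],
                            min_shift_hours = min_shift_hours,
                            fdr_alpha = fdr_alpha),
             error = function(e) NULL))
  ok <- !vapply(raw, is.null, logical(1))
  p <- vapply(raw[ok], `[[`, numeric(1), "p_value")
  q <- bh_fdr(p)
  delta <- rep(NA_real_, length(raw)); se <- delta; pv <- delta; qv <- delta
  delta[ok] <- vapply(raw[ok], `[[`, numeric(1), "delta_phase_hours")
  se[ok] <- vapply(raw[ok], `[[`, numeric(1), "se_delta")
  pv[ok] <- p
  qv[ok] <- q
  data.frame(id = ids,
             delta_phase_hours = delta,
             se_delta = se,
             p_value = pv,
             q_value = qv,
             significant = !is.na(delta) & abs(delta) > min_shift_hours &
               !is.na(qv) & qv < fdr_alpha,
             row.names = NULL)
}

#' Compare the amplitudes of the top-N cycling genes of two conditions
#'
#' Ranks each condition's genes by fitted amplitude, takes the top `n` from
#' each, and runs a two-sided two-sample t test on the two amplitude sets —
#' the comparison used to contrast overall rhythm strength between a
#' reference and a clock-compromised line.
#'
#' @param fits_a,fits_b Data frames with an `amplitude` column (e.g. from
#'   [detect_cycling()]), or numeric amplitude vectors.
#' @param n Number of top-ranked genes per side (default 50).
#' @return The [stats::t.test()] result (class `htest`).
#' @export
compare_amplitudes_topn <- function(fits_a, fits_b, n = 50) {
  amp <- function(f) if (is.data.frame(f)) f$amplitude else as.numeric(f)
  a <- amp(fits_a); b <- amp(fits_b)
  if (n > length(a) || n > length(b))
    stop("n = ", n, " exceeds available genes (", length(a), ", ",
         length(b), ")", call. = FALSE)
  top <- function(v) sort(v, decreasing = TRUE)[seq_len(n)]
  stats::t.test(top(a), top(b), var.equal = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment of a p-value vector (delegates to
#' [stats::p.adjust()] after validating the inputs).
#'
#' @param p Numeric vector of p-values in `[0, 1]`; may be empty.
#' @return q-values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))   # all 0.04
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}
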