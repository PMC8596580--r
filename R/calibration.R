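# SiPM parameter calibration from dark-trigger data, following the
# supplementary methods of the validation experiments: the crosstalk
# parameter from the multi-peak dark-pulse integral histogram, and the
# recharge constant from the tail of the single-SPAD response.

#' Estimate the crosstalk parameter from dark-pulse integrals
#'
#' A histogram of dark-pulse integrals shows equally spaced peaks at
#' integer multiples of the single-SPAD-response (SSR) integral: a dark
#' trigger plus its crosstalk cascade fires k SPADs nearly simultaneously.
#' Events are assigned to peak k by boundaries at half-integer multiples of
#' the SSR integral, and the per-peak event fractions are fitted by the
#' Borel pmf with \eqn{\lambda} as the only parameter, weighted by
#' multinomial standard errors. Peaks with fewer than 10 events are
#' excluded and the remaining fractions renormalised.
#'
#' @param integrals Dark-pulse integrals in SSR-integral units (use the SSR
#'   integral fitted via [estimate_recharge()], not an assumed one, when
#'   working in raw units).
#' @param ssr_integral The SSR integral in the units of `integrals`
#'   (default 1, i.e. already normalised).
#' @param max_peak Highest peak index considered.
#' @return A list of class `"crosstalk_fit"` with `lambda`, `se`,
#'   `peak_fractions` (renormalised, summing to 1), `peak_counts` and
#'   `n_events`.
#' @export
estimate_crosstalk <- function(integrals, ssr_integral = 1, max_peak = 12) {
  stopifnot(length(integrals) >= 1000, ssr_integral > 0)
  k <- pmin(pmax(round(integrals / ssr_integral), 1L), max_peak + 1L)
  counts <- tabulate(k, nbins = max_peak + 1L)
  counts <- counts[seq_len(max_peak)] # overflow bin dropped
  use <- counts >= 10
  if (sum(use) < 1 || !use[1]) {
    stop("calibration error: dark-pulse peaks unresolvable (peak counts: ",
         paste(counts, collapse = ", "), ")")
  }
  n_used <- sum(counts[use])
  frac <- counts[use] / n_used
  kk <- which(use)
  # multinomial standard errors as weights; guard tiny fractions
  w <- 1 / pmax(frac * (1 - frac) / n_used, 1e-12)
  obj <- function(lam) sum(w * (frac - dborel(kk, lam))^2)
  opt <- stats::optimize(obj, c(0, 0.999), tol = 1e-9)
  lam <- opt$minimum
  # linearised LSQ standard error from the pmf sensitivity
  eps <- 1e-5
  g <- (dborel(kk, min(lam + eps, 0.999)) - dborel(kk, max(lam - eps, 0))) /
    (min(lam + eps, 0.999) - max(lam - eps, 0))
  se <- sqrt(1 / sum(w * g^2))
  structure(list(lambda = lam, se = se,
                 peak_fractions = stats::setNames(frac, kk),
                 peak_counts = stats::setNames(counts[use], kk),
                 excluded_peaks = which(!use & counts > 0),
                 n_events = length(integrals), objective = opt$objective),
            class = "crosstalk_fit")
}

#' @export
print.crosstalk_fit <- function(x, ...) {
  cat(sprintf("Crosstalk fit: lambda = %.4f +- %.4f (%d dark events, peaks %s)\n",
              x$lambda, x$se, x$n_events,
              paste(names(x$peak_fractions), collapse = ",")))
  invisible(x)
}

#' Estimate the recharge constant from the SSR tail
#'
#' Fits an exponential decay through the tail of an averaged single-SPAD
#' response by log-linear least squares, returning the recharge time
#' constant \eqn{\tau_r}. Samples at or below zero inside the fit window
#' are dropped (the window auto-shrinks); fewer than 10 usable samples is
#' an error. The fit is invariant to amplitude scaling.
#'
#' @param w The averaged SSR as a [waveform()].
#' @param fit_start_ns Start of the tail window in ns (past the initial
#'   spike region).
#' @param fit_end_ns Optional end of the window (default: end of record).
#' @return A list of class `"recharge_fit"` with `tau_r`, `se`,
#'   `ssr_integral` (trapezoid integral of the waveform) and `n_samples`.
#' @export
estimate_recharge <- function(w, fit_start_ns, fit_end_ns = NULL) {
  stopifnot(inherits(w, "sipm_waveform"), fit_start_ns >= 0)
  t <- seq_along(w$samples) * w$dt
  if (is.null(fit_end_ns)) fit_end_ns <- max(t)
  sel <- t >= fit_start_ns & t <= fit_end_ns & w$samples > 0
  if (sum(sel) < 10) {
    stop("recharge fit error: fewer than 10 positive samples in the fit ",
         "window [", fit_start_ns, ", ", fit_end_ns, "] ns")
  }
  tt <- t[sel]
  fit <- stats::lm(log(w$samples[sel]) ~ tt)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) stop("recharge fit error: tail is not decaying")
  # noiseless fixtures fit exactly; summary.lm warns about the zero residual
  se_slope <- suppressWarnings(summary(fit)$coefficients[2, 2])
  structure(list(tau_r = -1 / slope,
                 se = se_slope / slope^2,
                 ssr_integral = waveform_integral(w),
                 n_samples = sum(sel),
                 window = c(fit_start_ns, fit_end_ns)),
            class = "recharge_fit")
}

#' @export
print.recharge_fit <- function(x, ...) {
  cat(sprintf("Recharge fit: tau_r = %.3f +- %.3f ns (%d samples, SSR integral %.4g)\n",
              x$tau_r, x$se, x$n_samples, x$ssr_integral))
  invisible(x)
}
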