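#' Sampled detector waveform
#'
#' A current pulse sampled on a uniform time grid. Samples are stored at
#' times `dt, 2*dt, ..., n*dt` (ns); the pulse is zero at `t = 0`.
#' Amplitudes are in units of SSR integrals per ns, so a waveform's
#' time-integral is directly the equivalent number of fired SPADs.
#'
#' @param samples Non-negative current samples.
#' @param dt Time step in ns.
#' @return An object of class `"sipm_waveform"`.
#' @export
waveform <- function(samples, dt = 1) {
  stopifnot(is.numeric(samples), length(samples) >= 1, dt > 0)
  structure(list(samples = as.numeric(samples), dt = as.numeric(dt),
                 window = length(samples) * dt),
            class = "sipm_waveform")
}

#' @export
print.sipm_waveform <- function(x, ...) {
  cat(sprintf("Waveform: %d samples, dt = %g ns, window = %g ns, integral = %.4g\n",
              length(x$samples), x$dt, x$window, waveform_integral(x)))
  invisible(x)
}

#' @export
plot.sipm_waveform <- function(x, ...) {
  t <- seq_along(x$samples) * x$dt
  graphics::plot(c(0, t), c(0, x$samples), type = "l",
                 xlab = "time (ns)", ylab = "amplitude (SSR/ns)", ...)
  invisible(x)
}

#' Trapezoidal integral and cumulative integral of a waveform
#'
#' @param w A [waveform()].
#' @return `waveform_integral()` the total area; `waveform_cumulative()` the
#'   running trapezoid integral at each sample time.
#' @export
waveform_integral <- function(w) {
  stopifnot(inherits(w, "sipm_waveform"))
  s <- w$samples
  sum((s + c(0, s[-length(s)])) / 2) * w$dt
}

#' @rdname waveform_integral
#' @export
waveform_cumulative <- function(w) {
  stopifnot(inherits(w, "sipm_waveform"))
  s <- w$samples
  cumsum((s + c(0, s[-length(s)])) / 2) * w$dt
}
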