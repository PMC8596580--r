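#' Mean number of scintillation photon-induced triggers
#'
#' The expected number of primary SPAD triggers produced by an energy
#' deposition, \eqn{\bar n_{tr,sc} = E \cdot Y \cdot f \cdot \eta_{lc}
#' \cdot \eta_{pd}}: deposited energy times light yield, corrected by the
#' nonproportionality factor at that energy, times the fractions of photons
#' collected and detected.
#'
#' @param config A [pixel_config()].
#' @return Expected primary trigger count (linear in every factor).
#' @examples
#' cfg <- validation_config("3.0", 59.5)
#' mean_primary_triggers(cfg)  # 78.07
#' @export
mean_primary_triggers <- function(config) {
  stopifnot(inherits(config, "pixel_config"))
  f <- .energy_lookup(config$scintillator$nonprop_factor, config$energy_kev,
                      "nonproportionality factor")
  config$energy_kev * config$scintillator$light_yield * f *
    config$eta_lc * config$sipm$pde
}

#' Expected equivalent fired SPADs of one SPAD triggered i times
#'
#' A SPAD that fires again before it has fully recharged emits a partial
#' pulse, so repeated triggers deliver less than one single-SPAD response
#' (SSR) each. The expectation for a single SPAD triggered `i` times, with
#' exponentially distributed emission times (mean `tau_d`) and recharge
#' constant `tau_r`, follows the recursion
#' \deqn{\bar n_{f,eq,1}(i) = \bar n_{f,eq,1}(i-1) + 1 -
#'   \frac{(i-1)\tau_r}{(i-1)\tau_r + \tau_d}, \qquad
#'   \bar n_{f,eq,1}(1) = 1.}
#' With `tau_r = 0` no saturation occurs and the value equals `i`.
#'
#' @param i Trigger counts (non-negative integers; `i = 0` returns 0 since
#'   no trigger means no charge). Vectorised.
#' @param tau_r SPAD recharge time constant in ns (>= 0).
#' @param tau_d Scintillation decay time constant in ns (> 0).
#' @return Expected equivalent fired SPADs, strictly increasing in `i` and
#'   bounded above by `i`.
#' @export
expected_fired_single_spad <- function(i, tau_r, tau_d) {
  stopifnot(tau_r >= 0, tau_d > 0, all(i >= 0), all(i == floor(i)))
  if (!length(i)) return(numeric(0))
  imax <- max(i)
  vals <- c(0, .nf1_table(imax, tau_r, tau_d))
  vals[i + 1]
}

# cumulative recursion values n_f,eq,1(1..imax)
.nf1_table <- function(imax, tau_r, tau_d) {
  if (imax < 1) return(numeric(0))
  k <- seq_len(imax)
  cumsum(1 - (k - 1) * tau_r / ((k - 1) * tau_r + tau_d))
}

#' Analytic saturated SiPM response
#'
#' Computes the expected equivalent number of fired SPADs
#' \eqn{\bar n_{f,eq}} for a mean primary-trigger count, accounting for
#' optical crosstalk and saturation. The total trigger count is distributed
#' uniformly over the SPADs, so the per-SPAD trigger count is (approximately)
#' Poisson with mean \eqn{\bar n_{tr,tot}/N_{SPAD}};
#' \eqn{\bar n_{f,eq} = N_{SPAD} \sum_i P(i)\, \bar n_{f,eq,1}(i)}. Because
#' a partially discharged SPAD emits fewer crosstalk photons, the total
#' trigger count is itself corrected by iterating
#' \deqn{\bar n_{tr,tot,corr} = \frac{\bar n_{tr,sc}}
#'   {1 - \lambda\, \bar n_{f,eq}/\bar n_{tr,tot,corr}},}
#' starting from the uncorrected mean \eqn{\bar n_{tr,sc}/(1-\lambda)}.
#' The effective crosstalk parameter after saturation is
#' \eqn{\lambda_{corr} = \lambda\, \bar n_{f,eq} / \bar n_{tr,tot,corr}}.
#'
#' The per-SPAD Poisson sum is truncated where its cdf exceeds
#' 1 - 1e-12. The fixed-point iteration stops when the relative change
#' drops below `tol`; a damping factor of 0.5 is applied if the iterates
#' oscillate. Non-convergence is flagged, not raised.
#'
#' @param mean_primary Mean primary trigger count \eqn{\bar n_{tr,sc}} (> 0).
#' @param tau_d Scintillation decay constant (ns).
#' @param sipm A [sipm_spec()].
#' @param n_spad Number of SPADs on the pixel.
#' @param tol Relative fixed-point tolerance.
#' @param max_iter Maximum number of iterations.
#' @return A list of class `"saturated_response"` with `mean_fired`
#'   (\eqn{\bar n_{f,eq}}), `mean_total` (uncorrected), `mean_total_corr`,
#'   `lambda_corr`, `iterations` and `converged`.
#' @examples
#' cfg <- validation_config("3.0", 59.5)
#' saturated_response(mean_primary_triggers(cfg), 17, cfg$sipm, 1089)
#' @export
saturated_response <- function(mean_primary, tau_d, sipm, n_spad,
                               tol = 1e-10, max_iter = 200) {
  stopifnot(mean_primary > 0, n_spad >= 1, inherits(sipm, "sipm_spec"))
  lambda <- sipm$crosstalk
  tau_r <- sipm$recharge_ns
  n_tot0 <- mean_primary / (1 - lambda)

  nf_of <- function(total) .poisson_weighted_nfeq(total, n_spad, tau_r, tau_d)

  x <- n_tot0
  converged <- (lambda == 0)
  iters <- 0L
  prev_delta <- 0
  if (!converged) {
    for (k in seq_len(max_iter)) {
      iters <- k
      nf <- nf_of(x)
      x_new <- mean_primary / (1 - lambda * nf / x)
      delta <- x_new - x
      if (k > 1 && delta * prev_delta < 0) { # oscillation: damp the step
        x_new <- x + 0.5 * delta
        delta <- x_new - x
      }
      prev_delta <- delta
      done <- abs(delta) / x < tol
      x <- x_new
      if (done) { converged <- TRUE; break }
    }
  }
  nf <- nf_of(x)
  structure(list(
    mean_fired = nf,
    mean_primary = mean_primary,
    mean_total = n_tot0,
    mean_total_corr = x,
    lambda = lambda,
    lambda_corr = lambda * nf / x,
    iterations = iters,
    converged = converged
  ), class = "saturated_response")
}

# N_SPAD * sum_i Pois(i; total/N_SPAD) * n_f,eq,1(i), tail-truncated
.poisson_weighted_nfeq <- function(total, n_spad, tau_r, tau_d) {
  mu <- total / n_spad
  imax <- max(2, stats::qpois(1e-12, mu, lower.tail = FALSE) + 2)
  i <- seq_len(imax)
  n_spad * sum(stats::dpois(i, mu) * .nf1_table(imax, tau_r, tau_d))
}

#' @export
print.saturated_response <- function(x, ...) {
  cat(sprintf(
    "Saturated response: n_tr,sc %.4g -> n_f,eq %.4g (n_tr,tot,corr %.4g, lambda_corr %.4g)\n",
    x$mean_primary, x$mean_fired, x$mean_total_corr, x$lambda_corr))
  if (!x$converged) cat("  WARNING: fixed point not converged\n")
  invisible(x)
}

# -- response curve -----------------------------------------------------------

#' Monotone response lookup curve
#'
#' Evaluates the saturated response on a log-spaced grid of primary-trigger
#' means and builds a strictly monotone lookup mapping
#' \eqn{\bar n_{tr,sc} \leftrightarrow \bar n_{f,eq}} (monotone piecewise
#' cubic Hermite interpolation in both directions). This is the curve used
#' to backproject pulse-height observables into the primary-trigger domain.
#' Out-of-domain queries raise a domain error; the curve never extrapolates.
#'
#' @param config A [pixel_config()].
#' @param range Multiplicative span of the grid around the operating
#'   \eqn{\bar n_{tr,sc}} (default 0.2x to 5x).
#' @param points Number of grid points (>= 50; default 201).
#' @return A list of class `"response_curve"` with the grid and the two
#'   interpolants.
#' @export
response_curve <- function(config, range = c(0.2, 5), points = 201) {
  stopifnot(points >= 50, range[1] > 0, range[2] > range[1])
  ntr <- mean_primary_triggers(config)
  grid <- exp(seq(log(range[1] * ntr), log(range[2] * ntr),
                  length.out = points))
  nf <- vapply(grid, function(x) {
    saturated_response(x, config$scintillator$decay_ns, config$sipm,
                       config$n_spad)$mean_fired
  }, numeric(1))
  if (any(diff(nf) <= 0)) {
    stop("internal consistency error: response curve is not strictly ",
         "increasing; this indicates a model bug")
  }
  structure(list(
    ntr_sc = grid, nf_eq = nf,
    forward_fun = stats::splinefun(grid, nf, method = "monoH.FC"),
    inverse_fun = stats::splinefun(nf, grid, method = "monoH.FC")
  ), class = "response_curve")
}

.curve_eval <- function(curve, x, inverse = FALSE, what = "query") {
  dom <- if (inverse) range(curve$nf_eq) else range(curve$ntr_sc)
  out <- x < dom[1] | x > dom[2]
  if (any(out)) {
    stop("response curve domain error: ", what, " value ",
         format(x[which(out)[1]], digits = 6), " lies outside [",
         format(dom[1], digits = 6), ", ", format(dom[2], digits = 6),
         "]; the lookup curve does not extrapolate")
  }
  if (inverse) curve$inverse_fun(x) else curve$forward_fun(x)
}

#' Forward/backward projection through a response curve
#'
#' `curve_forward()` maps mean primary-trigger counts to mean equivalent
#' fired SPADs; `curve_backproject()` is the interpolated inverse.
#'
#' @param curve A `"response_curve"` (or a `"sipm_response"` whose curve is
#'   used).
#' @param ntr_sc,nf_eq Values to project.
#' @return Projected values.
#' @export
curve_forward <- function(curve, ntr_sc) {
  .curve_eval(.as_curve(curve), ntr_sc, inverse = FALSE, "n_tr,sc")
}

#' @rdname curve_forward
#' @export
curve_backproject <- function(curve, nf_eq) {
  .curve_eval(.as_curve(curve), nf_eq, inverse = TRUE, "n_f,eq")
}

.as_curve <- function(x) {
  if (inherits(x, "sipm_response")) {
    if (is.null(x$curve)) stop("this sipm_response was built without a curve")
    return(x$curve)
  }
  stopifnot(inherits(x, "response_curve"))
  x
}

# -- the central model object -------------------------------------------------

#' SiPM detector response model
#'
#' The central model constructor: for one pixel configuration it evaluates
#' the analytic nonproportional response (primary and total trigger
#' statistics, the saturated expected equivalent fired SPADs, the corrected
#' crosstalk parameter) and, by default, attaches the monotone response
#' lookup curve used for backprojection. The returned object supports
#' `print()`, `summary()`, `coef()`, `predict()` (forward or inverse
#' projection), `simulate()` (the Monte Carlo pulse simulator) and `plot()`.
#'
#' @param config A [pixel_config()].
#' @param curve Attach a [response_curve()]?
#' @param curve_range,curve_points Passed to [response_curve()].
#' @param tol,max_iter Passed to [saturated_response()].
#' @return An object of class `"sipm_response"`.
#' @examples
#' fit <- sipm_response(validation_config("3.0", 59.5))
#' coef(fit)
#' predict(fit, ntr_sc = 80)
#' @export
sipm_response <- function(config, curve = TRUE, curve_range = c(0.2, 5),
                          curve_points = 201, tol = 1e-10, max_iter = 200) {
  stopifnot(inherits(config, "pixel_config"))
  ntr <- mean_primary_triggers(config)
  stats <- trigger_statistics(ntr, config$sipm$crosstalk)
  sat <- saturated_response(ntr, config$scintillator$decay_ns, config$sipm,
                            config$n_spad, tol = tol, max_iter = max_iter)
  crv <- if (curve) response_curve(config, curve_range, curve_points) else NULL
  structure(list(
    config = config,
    mean_primary = ntr,
    trigger_stats = stats,
    saturation = sat,
    mean_fired = sat$mean_fired,
    lambda_corr = sat$lambda_corr,
    curve = crv,
    call = match.call()
  ), class = "sipm_response")
}

#' @export
print.sipm_response <- function(x, ...) {
  cat("SiPM scintillation detector response model\n")
  print(x$config)
  cat(sprintf("  n_tr,sc  = %.4g   n_tr,tot = %.4g (lambda = %g)\n",
              x$mean_primary, x$trigger_stats$mean_total,
              x$config$sipm$crosstalk))
  cat(sprintf("  n_f,eq   = %.4g   lambda_corr = %.4g\n",
              x$mean_fired, x$lambda_corr))
  invisible(x)
}

#' @export
summary.sipm_response <- function(object, ...) {
  s <- object$saturation
  out <- list(
    config = object$config,
    mean_primary = object$mean_primary,
    mean_total = object$trigger_stats$mean_total,
    var_total = object$trigger_stats$var_total,
    mean_fired = object$mean_fired,
    mean_total_corr = s$mean_total_corr,
    lambda_corr = s$lambda_corr,
    saturation_level = s$mean_total_corr / object$config$n_spad,
    loss_fraction = 1 - object$mean_fired / s$mean_total_corr,
    iterations = s$iterations,
    converged = s$converged,
    curve_domain = if (!is.null(object$curve)) range(object$curve$ntr_sc))
  class(out) <- "summary.sipm_response"
  out
}

#' @export
print.summary.sipm_response <- function(x, ...) {
  print(x$config)
  cat(sprintf("  primary triggers        %.4g\n", x$mean_primary))
  cat(sprintf("  total triggers          %.4g (uncorrected), %.4g corrected\n",
              x$mean_total, x$mean_total_corr))
  cat(sprintf("  equivalent fired SPADs  %.4g\n", x$mean_fired))
  cat(sprintf("  triggers per SPAD       %.3g\n", x$saturation_level))
  cat(sprintf("  charge loss to saturation %.2f%%\n", 100 * x$loss_fraction))
  cat(sprintf("  lambda_corr             %.4g (from %.4g)\n", x$lambda_corr,
              x$config$sipm$crosstalk))
  cat(sprintf("  fixed point: %d iterations, converged = %s\n",
              x$iterations, x$converged))
  invisible(x)
}

#' @export
coef.sipm_response <- function(object, ...) {
  c(ntr_sc = object$mean_primary,
    ntr_tot = object$trigger_stats$mean_total,
    ntr_tot_corr = object$saturation$mean_total_corr,
    nf_eq = object$mean_fired,
    lambda_corr = object$lambda_corr)
}

#' Project trigger counts through the fitted response
#'
#' Forward projection maps a mean primary-trigger count to mean equivalent
#' fired SPADs; with `nf_eq` given, the inverse (backprojection) is
#' returned instead.
#'
#' @param object A `"sipm_response"`.
#' @param ntr_sc Primary-trigger values to project forward.
#' @param nf_eq Equivalent-fired-SPADs values to backproject.
#' @param ... Unused.
#' @return Projected values.
#' @export
predict.sipm_response <- function(object, ntr_sc = NULL, nf_eq = NULL, ...) {
  if (is.null(ntr_sc) == is.null(nf_eq)) {
    stop("supply exactly one of 'ntr_sc' (forward) or 'nf_eq' (inverse)")
  }
  if (!is.null(ntr_sc)) curve_forward(object, ntr_sc)
  else curve_backproject(object, nf_eq)
}

#' @export
plot.sipm_response <- function(x, ...) {
  crv <- .as_curve(x)
  graphics::plot(crv$ntr_sc, crv$nf_eq, type = "l", lwd = 2,
                 xlab = "mean primary triggers n_tr,sc",
                 ylab = "mean equivalent fired SPADs n_f,eq", ...)
  graphics::abline(0, 1, lty = 3, col = "grey40")
  graphics::points(x$mean_primary, x$mean_fired, pch = 19, col = "red3")
  graphics::legend("topleft", bty = "n",
                   legend = c("response curve", "proportional", "operating point"),
                   lty = c(1, 3, NA), pch = c(NA, NA, 19),
                   col = c("black", "grey40", "red3"))
  invisible(x)
}

#' Calibrate the light collection efficiency
#'
#' Fits \eqn{\eta_{lc}} — typically the last unknown detector parameter — by
#' matching the modelled mean equivalent fired SPADs to a measured value,
#' exactly the procedure used for the validation detector (anchor: 92.7 at
#' 59.5 keV and 3.0 V overvoltage, conditions of low saturation and
#' crosstalk).
#'
#' @param config A [pixel_config()]; its `eta_lc` entry is ignored.
#' @param target_nf_eq Measured mean equivalent fired SPADs to match.
#' @param interval Search interval for \eqn{\eta_{lc}}.
#' @return The fitted \eqn{\eta_{lc}}.
#' @examples
#' fit_light_collection(validation_config("3.0", 59.5), 92.7)  # ~0.573
#' @export
fit_light_collection <- function(config, target_nf_eq,
                                 interval = c(0.05, 1)) {
  stopifnot(inherits(config, "pixel_config"), target_nf_eq > 0)
  f <- function(eta) {
    cfg <- config
    cfg$eta_lc <- eta
    saturated_response(mean_primary_triggers(cfg),
                       cfg$scintillator$decay_ns, cfg$sipm,
                       cfg$n_spad)$mean_fired - target_nf_eq
  }
  stats::uniroot(f, interval, tol = 1e-10)$root
}
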