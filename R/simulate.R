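# Monte Carlo pulse simulator.
#
# Per pulse: draw the total trigger count from the generalized Poisson
# distribution with the saturation-corrected crosstalk parameter, assign
# each trigger uniformly to a SPAD, draw i.i.d. exponential emission
# timestamps, apply the partial-pulse rule per SPAD, and sum scaled
# single-SPAD responses into the detector waveform.

#' Simulate detector output pulses
#'
#' Runs the stochastic pulse simulator for the configuration of a fitted
#' [sipm_response()]. Each simulated pulse yields an equivalent number of
#' fired SPADs \eqn{n_{f,eq}} (the pulse integral in units of the
#' single-SPAD response integral); optionally the sampled waveforms are
#' synthesised to measure per-pulse t95 durations, the ensemble mean
#' waveform, or to keep every waveform.
#'
#' The partial-pulse rule: on every trigger a SPAD discharges its currently
#' available charge, which then recovers as \eqn{1 - e^{-\Delta t/\tau_r}};
#' the emitted sub-pulse is the available charge times the unit-integral
#' exponential single-SPAD response. Equivalently (and algebraically
#' identically for the summed output), the recharge current restarts at full
#' amplitude at each trigger and the previous tail is truncated.
#'
#' Pulses are generated in fixed-size blocks with per-block RNG substreams
#' derived from `seed`, so enlarging `nsim` never reshuffles earlier pulses.
#'
#' @param object A `"sipm_response"`.
#' @param nsim Number of pulses.
#' @param seed Integer master seed (required for reproducibility contracts;
#'   drawn from the session RNG when `NULL`).
#' @param dt Sampling step in ns (default 1, i.e. 1 GS/s).
#' @param window Waveform window in ns; default `max(200, 3*tau_d + 5*tau_r)`
#'   rounded up to the step. A shorter user-supplied window warns, since
#'   truncation may bias \eqn{n_{f,eq}} and t95.
#' @param t95 Compute per-pulse t95 pulse durations (requires waveform
#'   synthesis)?
#' @param keep_waveforms Keep the full waveform matrix (rows = pulses)?
#' @param mean_waveform Accumulate the ensemble mean waveform? Implied by
#'   `t95` or `keep_waveforms`.
#' @param block_size Pulses per RNG block.
#' @param ... Unused.
#' @return An object of class `"pulse_ensemble"`: per-pulse `n_f_eq` and
#'   `n_triggers`, optional `t95`, `mean_waveform` ([waveform()]) and
#'   `waveforms` matrix, plus the configuration and seed.
#' @examples
#' fit <- sipm_response(validation_config("3.0", 59.5), curve = FALSE)
#' ens <- simulate(fit, nsim = 200, seed = 1)
#' mean(ens$n_f_eq)
#' @export
simulate.sipm_response <- function(object, nsim = 1, seed = NULL, dt = 1,
                                   window = NULL, t95 = FALSE,
                                   keep_waveforms = FALSE,
                                   mean_waveform = FALSE,
                                   block_size = 1000L, ...) {
  stopifnot(nsim >= 1)
  cfg <- object$config
  tau_d <- cfg$scintillator$decay_ns
  tau_r <- cfg$sipm$recharge_ns
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  need_wave <- t95 || keep_waveforms || mean_waveform

  min_window <- 3 * tau_d + 5 * tau_r
  if (is.null(window)) {
    window <- max(200, min_window)
  } else if (window < min_window) {
    warning("window (", window, " ns) is shorter than 3*tau_d + 5*tau_r (",
            min_window, " ns); truncation may bias n_f,eq and t95")
  }
  nb <- as.integer(ceiling(window / dt))

  gp_tab <- .gpois_table(object$mean_primary, object$lambda_corr)

  n_f_eq <- numeric(nsim)
  n_triggers <- integer(nsim)
  t95v <- if (t95) numeric(nsim)
  wsum <- if (need_wave) numeric(nb)
  wmat <- if (keep_waveforms) matrix(0, nsim, nb)

  old_rng <- .save_rng()
  on.exit(.restore_rng(old_rng))
  blocks <- split(seq_len(nsim), (seq_len(nsim) - 1L) %/% block_size)
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]
    tr <- .block_triggers(seed, b, block_size, length(idx), gp_tab,
                          cfg$n_spad, tau_d)
    pp <- .partial_amplitudes(tr$pulse, tr$spad, tr$ts, tau_r)
    n_triggers[idx] <- tr$counts
    n_f_eq[idx] <- .sum_by_pulse(pp$amp, pp$pulse, length(idx))
    if (need_wave) {
      M <- .waveform_matrix(pp$pulse, pp$ts, pp$amp, length(idx), dt, nb,
                            tau_r)
      wsum <- wsum + colSums(M)
      if (keep_waveforms) wmat[idx, ] <- M
      if (t95) t95v[idx] <- .matrix_t95(M, dt)
    }
  }

  structure(list(
    n_f_eq = n_f_eq,
    n_triggers = n_triggers,
    t95 = t95v,
    mean_waveform = if (need_wave) waveform(wsum / nsim, dt),
    waveforms = wmat,
    nsim = nsim,
    dt = dt,
    window = nb * dt,
    seed = seed,
    lambda_corr = object$lambda_corr,
    analytic = coef(object),
    config = cfg
  ), class = "pulse_ensemble")
}

#' @export
print.pulse_ensemble <- function(x, ...) {
  cat(sprintf("Pulse ensemble: %d pulses (seed %d)\n", x$nsim, x$seed))
  cat(sprintf("  mean n_f,eq = %.4g (analytic %.4g), mean triggers = %.4g\n",
              mean(x$n_f_eq), x$analytic[["nf_eq"]], mean(x$n_triggers)))
  if (!is.null(x$t95)) {
    cat(sprintf("  mean t95 = %.4g ns (window %g ns, dt %g ns)\n",
                mean(x$t95, na.rm = TRUE), x$window, x$dt))
  }
  invisible(x)
}

#' Extract one simulated waveform from an ensemble
#'
#' @param ensemble A `"pulse_ensemble"` simulated with
#'   `keep_waveforms = TRUE`.
#' @param i Pulse index.
#' @return A [waveform()].
#' @export
ensemble_waveform <- function(ensemble, i = 1) {
  stopifnot(inherits(ensemble, "pulse_ensemble"))
  if (is.null(ensemble$waveforms)) {
    stop("ensemble was simulated without keep_waveforms = TRUE")
  }
  waveform(ensemble$waveforms[i, ], ensemble$dt)
}

# -- internals ----------------------------------------------------------------

.block_seed <- function(seed, block) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(block)) %%
               2147483629)
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# draw a full block of pulses under its own substream and keep the first
# `keep`: the draw order inside a block is fixed, so the per-pulse stream is
# independent of the requested ensemble size
.block_triggers <- function(seed, block, block_size, keep, gp_tab, n_spad,
                            tau_d, slow_fraction = 0, slow_decay = 500) {
  set.seed(.block_seed(seed, block))
  tr <- .sample_block_triggers(block_size, gp_tab, n_spad, tau_d,
                               slow_fraction, slow_decay)
  if (keep < block_size) {
    sel <- tr$pulse <= keep
    tr <- list(pulse = tr$pulse[sel], spad = tr$spad[sel], ts = tr$ts[sel],
               counts = tr$counts[seq_len(keep)])
  }
  tr
}

# draw counts, SPAD assignments and emission timestamps for one block;
# draw order is fixed so earlier pulses are unaffected by later ones
.sample_block_triggers <- function(n_pulses, gp_tab, n_spad, tau_d,
                                   slow_fraction = 0, slow_decay = 500) {
  counts <- findInterval(stats::runif(n_pulses), gp_tab$cdf)
  tot <- sum(counts)
  pulse <- rep.int(seq_len(n_pulses), counts)
  spad <- if (tot) sample.int(n_spad, tot, replace = TRUE) else integer(0)
  ts <- if (tot) stats::rexp(tot, 1 / tau_d) else numeric(0)
  if (slow_fraction > 0 && tot) {
    slow <- stats::runif(tot) < slow_fraction
    ts[slow] <- stats::rexp(sum(slow), 1 / slow_decay)
  }
  list(pulse = pulse, spad = spad, ts = ts, counts = counts)
}

# partial-pulse amplitudes: available charge recovers as 1 - exp(-gap/tau_r)
# since the previous trigger on the same SPAD; first trigger delivers 1
.partial_amplitudes <- function(pulse, spad, ts, tau_r) {
  n <- length(ts)
  if (!n) return(list(pulse = pulse, spad = spad, ts = ts, amp = numeric(0)))
  o <- order(pulse, spad, ts)
  pulse <- pulse[o]; spad <- spad[o]; ts <- ts[o]
  first <- c(TRUE, pulse[-1] != pulse[-n] | spad[-1] != spad[-n])
  gap <- c(0, ts[-1] - ts[-n])
  amp <- ifelse(first, 1,
                if (tau_r > 0) 1 - exp(-gap / tau_r) else 1)
  list(pulse = pulse, spad = spad, ts = ts, amp = amp)
}

.sum_by_pulse <- function(x, pulse, n_pulses) {
  out <- numeric(n_pulses)
  if (length(x)) {
    agg <- rowsum(x, pulse)
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out
}

# sampled waveforms, one row per pulse: each trigger contributes
# amp * exp(-(t - ts)/tau_r)/tau_r for t >= ts; evaluated exactly at the
# sample times via impulse injection + a recursive one-step decay.
# Triggers beyond the window deliver no charge inside it and are dropped.
.waveform_matrix <- function(pulse, ts, amp, n_pulses, dt, nb, tau_r) {
  M <- matrix(0, n_pulses, nb)
  keep <- ts <= nb * dt
  if (any(keep)) {
    ts <- ts[keep]; amp <- amp[keep]; pulse <- pulse[keep]
    bin <- pmin(floor(ts / dt) + 1L, nb)
    if (tau_r > 0) {
      w <- amp * exp(-(bin * dt - ts) / tau_r) / tau_r
      decay <- exp(-dt / tau_r)
    } else {
      w <- amp / dt  # delta-like SSR collapses into one sample
      decay <- 0
    }
    key <- (pulse - 1) * nb + bin
    agg <- rowsum(w, key)
    k <- as.numeric(rownames(agg))
    M[cbind((k - 1) %/% nb + 1, (k - 1) %% nb + 1)] <- agg[, 1]
    if (decay > 0 && nb > 1) {
      for (j in 2:nb) M[, j] <- M[, j] + M[, j - 1] * decay
    }
  }
  M
}

# per-row t95 on the shared grid: trapezoid cumulative, linear interpolation
# within the crossing sample; rows with zero area give NA
.matrix_t95 <- function(M, dt, fraction = 0.95) {
  nb <- ncol(M)
  C <- M
  C[, 1] <- M[, 1] / 2 * dt
  for (j in 2:nb) C[, j] <- C[, j - 1] + (M[, j] + M[, j - 1]) / 2 * dt
  total <- C[, nb]
  thr <- fraction * total
  below <- rowSums(C < thr)
  i1 <- pmin(below + 1L, nb)
  i0 <- pmax(i1 - 1L, 1L)
  c0 <- ifelse(i1 == 1L, 0, C[cbind(seq_len(nrow(M)), i0)])
  t0 <- ifelse(i1 == 1L, 0, i0 * dt)
  c1 <- C[cbind(seq_len(nrow(M)), i1)]
  res <- t0 + (thr - c0) / pmax(c1 - c0, .Machine$double.xmin) * dt
  res[total <= 0] <- NA_real_
  res
}
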