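# Synthetic digitised-waveform generator emulating the validation
# acquisition chain (1 GS/s digitiser), so the spectroscopy and calibration
# operations can be exercised without measured data. On top of the pulse
# Monte Carlo it adds a slow scintillation decay component (as a
# two-exponential mixture on the trigger timestamps, keeping charge
# bookkeeping exact), additive white Gaussian noise, and a finite record
# length.

#' Acquisition model for synthetic digitised records
#'
#' @param sampling_rate_gsps Digitiser sampling rate in GS/s (default 1).
#' @param noise_rms Additive white Gaussian noise, as a fraction of the SSR
#'   peak amplitude (1/tau_r).
#' @param slow_fraction Fraction of triggers drawn from the slow decay
#'   component, in \[0, 1).
#' @param slow_decay_ns Slow decay time constant in ns.
#' @param record_length_ns Record length in ns (>= 200, the standard
#'   integration window).
#' @return A list of class `"acquisition_model"`.
#' @export
acquisition_model <- function(sampling_rate_gsps = 1, noise_rms = 0,
                              slow_fraction = 0, slow_decay_ns = 500,
                              record_length_ns = 200) {
  stopifnot(sampling_rate_gsps > 0, noise_rms >= 0,
            slow_fraction >= 0, slow_fraction < 1, slow_decay_ns > 0,
            record_length_ns >= 200)
  structure(list(sampling_rate_gsps = sampling_rate_gsps,
                 noise_rms = noise_rms,
                 slow_fraction = slow_fraction,
                 slow_decay_ns = slow_decay_ns,
                 record_length_ns = record_length_ns),
            class = "acquisition_model")
}

#' Synthetic scintillation event records
#'
#' Generates digitised event records for a pixel configuration under an
#' acquisition model. Each record is a simulated detector pulse (with an
#' optional slow emission component) sampled at the digitiser rate with
#' additive noise. Ground truth per record (trigger count and delivered
#' charge) is retained for test assertions.
#'
#' @param config A [pixel_config()].
#' @param acq An [acquisition_model()].
#' @param n Number of records.
#' @param seed Master seed.
#' @param keep_waveforms Keep the record matrix (rows = records)?
#' @return A list of class `"event_records"`: `integrals` (trapezoid record
#'   integrals, in SSR-integral units, i.e. measured \eqn{n_{f,eq}}),
#'   `true_charge` (exact delivered charge per record, untruncated),
#'   `true_triggers`, `mean_waveform`, optional `waveforms`, and the
#'   generating parameters.
#' @export
synthesize_events <- function(config, acq, n, seed, keep_waveforms = FALSE) {
  stopifnot(inherits(config, "pixel_config"),
            inherits(acq, "acquisition_model"), n >= 1)
  resp <- sipm_response(config, curve = FALSE)
  tau_r <- config$sipm$recharge_ns
  tau_d <- config$scintillator$decay_ns
  dt <- 1 / acq$sampling_rate_gsps
  nb <- as.integer(ceiling(acq$record_length_ns / dt))
  gp_tab <- .gpois_table(resp$mean_primary, resp$lambda_corr)

  old_rng <- .save_rng()
  on.exit(.restore_rng(old_rng))
  block_size <- 1000L
  integrals <- true_charge <- numeric(n)
  true_triggers <- integer(n)
  wsum <- numeric(nb)
  wmat <- if (keep_waveforms) matrix(0, n, nb)
  ssr_amp <- if (tau_r > 0) 1 / tau_r else 1 / dt
  blocks <- split(seq_len(n), (seq_len(n) - 1L) %/% block_size)
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]
    tr <- .block_triggers(seed, b, block_size, length(idx), gp_tab,
                          config$n_spad, tau_d,
                          slow_fraction = acq$slow_fraction,
                          slow_decay = acq$slow_decay_ns)
    pp <- .partial_amplitudes(tr$pulse, tr$spad, tr$ts, tau_r)
    M <- .waveform_matrix(pp$pulse, pp$ts, pp$amp, length(idx), dt, nb, tau_r)
    if (acq$noise_rms > 0) {
      M <- M + matrix(stats::rnorm(length(idx) * nb,
                                   sd = acq$noise_rms * ssr_amp),
                      length(idx), nb)
    }
    left <- cbind(0, M[, -nb, drop = FALSE])
    integrals[idx] <- rowSums((M + left) / 2) * dt
    true_charge[idx] <- .sum_by_pulse(pp$amp, pp$pulse, length(idx))
    true_triggers[idx] <- tr$counts
    wsum <- wsum + colSums(M)
    if (keep_waveforms) wmat[idx, ] <- M
  }
  structure(list(
    integrals = integrals,
    true_charge = true_charge,
    true_triggers = true_triggers,
    mean_waveform = waveform(wsum / n, dt),
    waveforms = wmat,
    dt = dt, record_length_ns = nb * dt, seed = seed,
    config = config, acq = acq
  ), class = "event_records")
}

#' @export
print.event_records <- function(x, ...) {
  cat(sprintf(
    "Synthetic event records: %d records of %g ns at %g GS/s (seed %d)\n",
    length(x$integrals), x$record_length_ns, 1 / x$dt, x$seed))
  cat(sprintf("  mean integral %.4g SSR units (true charge %.4g)\n",
              mean(x$integrals), mean(x$true_charge)))
  invisible(x)
}

#' Synthetic dark-pulse records
#'
#' Each record contains one primary dark trigger whose crosstalk cascade
#' fires Borel(\eqn{\lambda})-distributed SPADs nearly simultaneously, so
#' the record integral clusters at integer multiples of the SSR integral.
#' Used to exercise [estimate_crosstalk()] and [estimate_recharge()].
#'
#' @param sipm A [sipm_spec()].
#' @param acq An [acquisition_model()].
#' @param n Number of records.
#' @param seed Master seed.
#' @param t0_ns Trigger time inside the record.
#' @param keep_waveforms Keep the record matrix?
#' @return A list of class `"dark_records"`: `integrals` (SSR-integral
#'   units), `true_k` (cascade sizes), `mean_ssr` (mean waveform of the
#'   single-trigger records, for recharge fitting), optional `waveforms`.
#' @export
synthesize_dark_pulses <- function(sipm, acq, n, seed, t0_ns = 10,
                                   keep_waveforms = FALSE) {
  stopifnot(inherits(sipm, "sipm_spec"), inherits(acq, "acquisition_model"),
            n >= 1)
  tau_r <- sipm$recharge_ns
  dt <- 1 / acq$sampling_rate_gsps
  nb <- as.integer(ceiling(acq$record_length_ns / dt))
  old_rng <- .save_rng()
  on.exit(.restore_rng(old_rng))
  set.seed(.block_seed(seed, 2L))
  k <- rborel(n, sipm$crosstalk)
  # k distinct SPADs fire at t0: amplitudes are all full
  pulse <- rep.int(seq_len(n), k)
  ts <- rep.int(t0_ns, length(pulse))
  amp <- rep.int(1, length(pulse))
  M <- .waveform_matrix(pulse, ts, amp, n, dt, nb, tau_r)
  if (acq$noise_rms > 0) {
    ssr_amp <- if (tau_r > 0) 1 / tau_r else 1 / dt
    M <- M + matrix(stats::rnorm(n * nb, sd = acq$noise_rms * ssr_amp), n, nb)
  }
  left <- cbind(0, M[, -nb, drop = FALSE])
  integrals <- rowSums((M + left) / 2) * dt
  singles <- which(k == 1)
  mean_ssr <- if (length(singles)) {
    waveform(colMeans(M[singles, , drop = FALSE]), dt)
  }
  structure(list(
    integrals = integrals, true_k = k, mean_ssr = mean_ssr,
    waveforms = if (keep_waveforms) M,
    dt = dt, t0_ns = t0_ns, seed = seed, sipm = sipm, acq = acq
  ), class = "dark_records")
}

#' @export
print.dark_records <- function(x, ...) {
  cat(sprintf(
    "Synthetic dark records: %d records (lambda %.4g, seed %d); mean integral %.4g SSR units\n",
    length(x$integrals), x$sipm$crosstalk, x$seed, mean(x$integrals)))
  invisible(x)
}
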