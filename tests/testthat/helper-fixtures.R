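# Shared fixtures, built in code and memoised so expensive ensembles are
# simulated once per test run.

.fixture_cache <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

# light collection efficiency calibrated against the 92.7 fired-SPADs anchor
# (59.5 keV, 3.0 V), as in the validation analysis
calibrated_eta_lc <- function() {
  with_cache("eta_lc", {
    fit_light_collection(validation_config("3.0", 59.5), 92.7)
  })
}

validation_response <- function(overvoltage, energy_kev, curve = TRUE) {
  key <- sprintf("resp_%s_%s_%d", overvoltage, energy_kev, curve)
  with_cache(key, {
    sipm_response(validation_config(overvoltage, energy_kev,
                                    eta_lc = calibrated_eta_lc()),
                  curve = curve)
  })
}

validation_ensemble <- function(overvoltage, energy_kev, n = 10000,
                                seed = 101) {
  key <- sprintf("ens_%s_%s_%d_%d", overvoltage, energy_kev, n, seed)
  with_cache(key, {
    simulate(validation_response(overvoltage, energy_kev), n, seed = seed)
  })
}

# a proportional (no crosstalk, instantaneous recharge) configuration in
# which n_f,eq equals the primary trigger count exactly
proportional_config <- function(mean_triggers = 100, n_spad = 500L) {
  scint <- scintillator_spec("ideal", light_yield = 1, decay_ns = 20,
                             nonprop_factor = c("100" = 1),
                             intrinsic_resolution = c("100" = 0))
  sipm <- sipm_spec("ideal", pde = mean_triggers / 100, recharge_ns = 0,
                    crosstalk = 0, spad_pitch_um = 30)
  pixel_config(scint, sipm, pixel_mm = 1, eta_lc = 1, energy_kev = 100,
               n_spad = n_spad)
}

# small saturating test configuration with adjustable primary-trigger mean
toy_config <- function(mean_triggers, n_spad = 100L, tau_r = 20, tau_d = 17,
                       lambda = 0.15) {
  scint <- scintillator_spec("toy", light_yield = mean_triggers,
                             decay_ns = tau_d,
                             nonprop_factor = c("1" = 1),
                             intrinsic_resolution = c("1" = 0))
  sipm <- sipm_spec("toy", pde = 1, recharge_ns = tau_r, crosstalk = lambda,
                    spad_pitch_um = 30)
  pixel_config(scint, sipm, pixel_mm = 1, eta_lc = 1, energy_kev = 1,
               n_spad = n_spad)
}

# independent oracle for the Poisson-weighted saturation expectation:
# total triggers ~ Poisson, distributed multinomially over the SPADs; by
# symmetry the expectation reduces to the binomial marginal of one SPAD.
# The per-SPAD recursion is re-derived here as a plain loop.
enumerated_mean_fired <- function(mean_total, n_spad, tau_r, tau_d,
                                  tail = 1e-12) {
  nf1 <- function(i) {
    if (i == 0) return(0)
    v <- 1
    for (k in seq_len(i)[-1]) {
      v <- v + 1 - (k - 1) * tau_r / ((k - 1) * tau_r + tau_d)
    }
    v
  }
  n_max <- 0
  while (ppois(n_max, mean_total, lower.tail = FALSE) > tail) {
    n_max <- n_max + 1
  }
  total <- 0
  for (N in 0:n_max) {
    pN <- dpois(N, mean_total)
    inner <- 0
    for (i in 0:N) {
      inner <- inner + dbinom(i, N, 1 / n_spad) * nf1(i)
    }
    total <- total + pN * n_spad * inner
  }
  total
}
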