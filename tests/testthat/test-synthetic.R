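test_that("noiseless fast-only records coincide with the pulse simulator", {
  cfg <- validation_config("3.0", 59.5)
  acq <- acquisition_model(noise_rms = 0, slow_fraction = 0,
                           record_length_ns = 248)
  rec <- synthesize_events(cfg, acq, n = 200, seed = 61,
                           keep_waveforms = TRUE)
  resp <- sipm_response(cfg, curve = FALSE)
  ens <- simulate(resp, 200, seed = 61, window = 248, keep_waveforms = TRUE)
  expect_identical(rec$waveforms, ens$waveforms)
  expect_equal(rec$true_charge, ens$n_f_eq)
  # record integrals measure the delivered charge
  expect_equal(rec$integrals, rec$true_charge, tolerance = 0.01)
})

test_that("slow decay component fattens the waveform tail", {
  cfg <- validation_config("3.0", 59.5)
  fast <- synthesize_events(cfg, acquisition_model(record_length_ns = 400),
                            n = 400, seed = 62)
  slow <- synthesize_events(cfg, acquisition_model(slow_fraction = 0.2,
                                                   slow_decay_ns = 500,
                                                   record_length_ns = 400),
                            n = 400, seed = 62)
  tail_fraction <- function(rec) {
    s <- rec$mean_waveform$samples
    sum(s[101:400]) / sum(s)
  }
  expect_gt(tail_fraction(slow), tail_fraction(fast) * 1.5)
})

test_that("the 200 ns integration window captures >= 99% of fast pulses", {
  cfg <- validation_config("5.0", 59.5)  # tau_d = 17, tau_r = 35.8
  rec <- synthesize_events(cfg, acquisition_model(record_length_ns = 200),
                           n = 500, seed = 63)
  expect_gte(mean(rec$integrals) / mean(rec$true_charge), 0.99)
})

test_that("noise perturbs record integrals without biasing them", {
  cfg <- validation_config("3.0", 59.5)
  quiet <- synthesize_events(cfg, acquisition_model(record_length_ns = 248),
                             n = 300, seed = 64)
  noisy <- synthesize_events(cfg, acquisition_model(noise_rms = 0.02,
                                                    record_length_ns = 248),
                             n = 300, seed = 64)
  expect_equal(mean(noisy$integrals), mean(quiet$integrals), tolerance = 0.01)
  expect_gt(sd(noisy$integrals - quiet$integrals), 0)
})

test_that("dark records carry Borel cascade statistics", {
  sipm <- default_registry()$sipms[["NUV-HD 30 um @5.0 V (validation)"]]
  acq <- acquisition_model(record_length_ns = 400)
  dark <- synthesize_dark_pulses(sipm, acq, n = 20000, seed = 65)
  # single-trigger fraction exp(-lambda)
  expect_equal(mean(dark$true_k == 1), exp(-0.361), tolerance = 0.02)
  # mean integral 1/(1-lambda) SSR units (dark cascades do not saturate)
  expect_equal(mean(dark$integrals), 1 / (1 - 0.361), tolerance = 0.02)
  # lambda = 0: every record integrates to one SSR (up to the ~1% sampling
  # loss in the partial first bin of the 1 GS/s grid)
  nox <- synthesize_dark_pulses(sipm_spec("q", 0.4, 39.3, 0, 30), acq,
                                n = 2000, seed = 66)
  expect_true(all(abs(nox$integrals - 1) < 0.05))
  expect_equal(mean(nox$integrals), 1, tolerance = 0.02)
})
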