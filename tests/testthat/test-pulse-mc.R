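test_that("partial-pulse amplitude rule matches the recovery law", {
  # two triggers on one SPAD: second amplitude is 1 - exp(-dt/tau_r)
  for (dt in c(5, 35.8, 200)) {
    pp <- sipmct:::.partial_amplitudes(pulse = c(1L, 1L), spad = c(1L, 1L),
                                       ts = c(10, 10 + dt), tau_r = 35.8)
    expect_equal(pp$amp, c(1, 1 - exp(-dt / 35.8)), tolerance = 1e-12)
  }
  # widely separated triggers each deliver a full SSR
  pp <- sipmct:::.partial_amplitudes(c(1L, 1L), c(1L, 1L), c(0, 1e6), 35.8)
  expect_equal(sum(pp$amp), 2, tolerance = 1e-9)
  # different SPADs never see each other
  pp <- sipmct:::.partial_amplitudes(c(1L, 1L), c(1L, 2L), c(10, 10.1), 35.8)
  expect_equal(pp$amp, c(1, 1))
})

test_that("degenerate pulses behave by convention", {
  resp <- with_cache("toy_resp_50", sipm_response(toy_config(50), curve = FALSE))
  ens <- simulate(resp, 40, seed = 3, keep_waveforms = TRUE)
  # charge conservation per pulse: waveform integral equals delivered charge
  w_int <- apply(ens$waveforms, 1, function(s) {
    waveform_integral(waveform(s, ens$dt))
  })
  expect_equal(w_int, ens$n_f_eq, tolerance = 0.02)
  # a pulse with zero triggers has a zero waveform and n_f,eq = 0
  zero <- which(ens$n_triggers == 0)
  if (length(zero)) {
    expect_true(all(ens$n_f_eq[zero] == 0))
    expect_true(all(ens$waveforms[zero, ] == 0))
  }
  expect_true(all(ens$n_f_eq[ens$n_triggers == 1] == 1))
  expect_true(all(ens$n_f_eq <= ens$n_triggers + 1e-12))
})

test_that("ensembles are seed-deterministic with a stable prefix", {
  resp <- with_cache("toy_resp_50", sipm_response(toy_config(50), curve = FALSE))
  a <- simulate(resp, 500, seed = 11)
  b <- simulate(resp, 500, seed = 11)
  expect_identical(a$n_f_eq, b$n_f_eq)
  # enlarging the ensemble never reshuffles earlier pulses
  big <- simulate(resp, 1500, seed = 11)
  expect_identical(big$n_f_eq[1:500], a$n_f_eq)
  expect_false(identical(simulate(resp, 500, seed = 12)$n_f_eq, a$n_f_eq))
})

test_that("ensemble mean tracks the analytic model across saturation levels", {
  # primary-trigger means spanning ~0.01 to 1.5 triggers per SPAD
  for (ntr in c(1, 10, 50, 100, 150)) {
    resp <- sipm_response(toy_config(ntr), curve = FALSE)
    ens <- simulate(resp, 20000, seed = 21)
    expect_equal(mean(ens$n_f_eq), resp$mean_fired,
                 tolerance = 0.02, info = paste("ntr", ntr))
  }
})

test_that("proportional regime reproduces the primary trigger statistics", {
  resp <- sipm_response(proportional_config(80), curve = FALSE)
  ens <- simulate(resp, 20000, seed = 5)
  expect_equal(mean(ens$n_f_eq), 80, tolerance = 3.5 * sqrt(80 / 20000) / 80)
  expect_identical(ens$n_f_eq, as.numeric(ens$n_triggers))
})

test_that("waveform synthesis integrates the sampled pulse correctly", {
  # a single trigger reproduces a unit-integral SSR
  resp <- with_cache("toy_resp_50", sipm_response(toy_config(50), curve = FALSE))
  M <- sipmct:::.waveform_matrix(pulse = 1L, ts = 0, amp = 1, n_pulses = 1L,
                                 dt = 1, nb = 400L, tau_r = 20)
  w <- waveform(M[1, ], 1)
  # the 1 ns grid under-integrates the partial first bin by ~dt/(2*tau_r)
  expect_equal(waveform_integral(w), 1, tolerance = 0.03)
  expect_equal(pulse_t95(w), -20 * log(0.05), tolerance = 0.6)
  # sampled values are exact at the sample points
  expect_equal(M[1, c(1, 10, 100)],
               exp(-c(1, 10, 100) / 20) / 20, tolerance = 1e-12)
  # finer sampling converges to the exact unit integral
  Mf <- sipmct:::.waveform_matrix(1L, 0, 1, 1L, dt = 0.05, nb = 8000L,
                                  tau_r = 20)
  expect_equal(waveform_integral(waveform(Mf[1, ], 0.05)), 1,
               tolerance = 2e-3)
  # a short window warns about truncation bias
  expect_warning(simulate(resp, 5, seed = 1, window = 50, t95 = TRUE),
                 "truncation")
})
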