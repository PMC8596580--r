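test_that("mean primary triggers is the product of the chain factors", {
  expect_equal(mean_primary_triggers(validation_config("3.0", 59.5)),
               59.5 * 5.7 * 0.985 * 0.57 * 0.410, tolerance = 1e-12)
  expect_equal(mean_primary_triggers(validation_config("3.0", 59.5)), 78.07,
               tolerance = 1e-4)
  expect_equal(mean_primary_triggers(validation_config("3.0", 662)), 881.8,
               tolerance = 1e-4)
  cfg <- validation_config("3.0", 59.5)
  cfg$eta_lc <- 0.5 * cfg$eta_lc   # linear in each factor
  expect_equal(mean_primary_triggers(cfg), 78.07 / 2, tolerance = 1e-4)
})

test_that("single-SPAD recursion obeys its boundary and limit cases", {
  expect_equal(expected_fired_single_spad(1, 35.8, 17), 1)
  expect_equal(expected_fired_single_spad(1, 0.01, 500), 1)
  # instantaneous recharge: no saturation
  expect_equal(expected_fired_single_spad(5, 0, 17), 5)
  # second-trigger increment 1 - tau_r/(tau_r + tau_d)
  expect_equal(expected_fired_single_spad(2, 35.8, 17),
               1 + 1 - 35.8 / (35.8 + 17), tolerance = 1e-12)
  expect_equal(expected_fired_single_spad(2, 35.8, 17), 1.32197,
               tolerance = 1e-5)
  expect_equal(expected_fired_single_spad(0, 35.8, 17), 0)
  # strictly increasing in i, bounded above by i
  v <- expected_fired_single_spad(1:50, 39.3, 17)
  expect_true(all(diff(v) > 0))
  expect_true(all(v <= 1:50))
})

test_that("proportional regime passes through unchanged", {
  sipm0 <- sipm_spec("ideal", pde = 1, recharge_ns = 0, crosstalk = 0,
                     spad_pitch_um = 30)
  s <- saturated_response(50, 17, sipm0, 1000)
  expect_equal(s$mean_fired, 50, tolerance = 1e-9)
  expect_equal(s$mean_total_corr, 50, tolerance = 1e-9)
  expect_equal(s$lambda_corr, 0)
  expect_true(s$converged)
})

test_that("analytic model reproduces the validation means", {
  eta <- calibrated_eta_lc()
  expect_equal(round(eta, 2), 0.57)
  r1 <- validation_response("3.0", 59.5, curve = FALSE)
  expect_equal(r1$mean_fired, 92.7, tolerance = 0.5 / 92.7)
  r2 <- validation_response("3.0", 662, curve = FALSE)
  expect_equal(r2$mean_fired, 765, tolerance = 0.02)
  # corrected crosstalk never exceeds the raw parameter
  expect_lte(r2$lambda_corr, r2$config$sipm$crosstalk)
  expect_lte(r1$lambda_corr, r1$config$sipm$crosstalk)
  # supra-proportionality cap: n_f,eq below the uncorrected total
  expect_lte(r1$mean_fired, r1$trigger_stats$mean_total)
  expect_lte(r2$mean_fired, r2$trigger_stats$mean_total)
})

test_that("Poisson-weighted expectation matches brute-force enumeration", {
  cases <- expand.grid(n_spad = c(2L, 3L, 5L), mean_total = c(2, 5, 10),
                       tau_r = c(0, 20, 39.3))
  sipm0 <- function(tau_r) sipm_spec("enum", pde = 1, recharge_ns = tau_r,
                                     crosstalk = 0, spad_pitch_um = 30)
  for (k in seq_len(nrow(cases))) {
    cs <- cases[k, ]
    got <- saturated_response(cs$mean_total, 17, sipm0(cs$tau_r),
                              cs$n_spad)$mean_fired
    want <- enumerated_mean_fired(cs$mean_total, cs$n_spad, cs$tau_r, 17)
    expect_equal(got, want, tolerance = 1e-8,
                 info = paste(unlist(cs), collapse = "/"))
  }
})

test_that("saturated response is monotone in its drivers", {
  sipm_at <- function(tau_r) sipm_spec("m", pde = 1, recharge_ns = tau_r,
                                       crosstalk = 0.15, spad_pitch_um = 30)
  # increasing in the primary-trigger mean
  nf <- vapply(c(10, 50, 100, 200, 400),
               function(x) saturated_response(x, 17, sipm_at(25),
                                              150)$mean_fired, 0)
  expect_true(all(diff(nf) > 0))
  # decreasing in tau_r at fixed tau_d
  nf_tau <- vapply(c(0, 5, 20, 60),
                   function(tr) saturated_response(150, 17, sipm_at(tr),
                                                   150)$mean_fired, 0)
  expect_true(all(diff(nf_tau) < 0))
  # increasing in the number of SPADs
  nf_spad <- vapply(c(50, 100, 400, 1000),
                    function(ns) saturated_response(150, 17, sipm_at(25),
                                                    ns)$mean_fired, 0)
  expect_true(all(diff(nf_spad) > 0))
  # lambda_corr approaches lambda as saturation vanishes
  loose <- saturated_response(1, 17, sipm_at(25), 1e5)
  expect_equal(loose$lambda_corr, 0.15, tolerance = 1e-3)
})

test_that("response curve is monotone with an exact interpolated inverse", {
  resp <- validation_response("3.0", 662)
  crv <- resp$curve
  expect_true(all(diff(crv$nf_eq) > 0))
  # inverse property on interior points
  y <- seq(0.3 * resp$mean_fired, 2 * resp$mean_fired, length.out = 25)
  expect_equal(curve_forward(resp, curve_backproject(resp, y)), y,
               tolerance = 1e-6)
  # consistency with the direct saturation computation
  expect_equal(curve_forward(resp, resp$mean_primary), resp$mean_fired,
               tolerance = 1e-6)
  # out-of-domain queries refuse to extrapolate
  expect_error(curve_forward(resp, max(crv$ntr_sc) * 1.01), "domain")
  expect_error(curve_backproject(resp, 0), "domain")
})

test_that("identity regime yields the identity curve", {
  resp <- sipm_response(proportional_config())
  x <- seq(30, 300, by = 30)
  expect_equal(predict(resp, ntr_sc = x), x, tolerance = 1e-9)
  expect_equal(predict(resp, nf_eq = x), x, tolerance = 1e-9)
  expect_error(predict(resp), "exactly one")
})

test_that("light collection calibration inverts the response model", {
  cfg <- validation_config("3.0", 59.5, eta_lc = 0.99)
  eta <- fit_light_collection(cfg, 92.7)
  cfg$eta_lc <- eta
  got <- saturated_response(mean_primary_triggers(cfg), 17, cfg$sipm,
                            1089)$mean_fired
  expect_equal(got, 92.7, tolerance = 1e-7)
})
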