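test_that("Gaussian fit of an exact Gaussian histogram is exact", {
  mids <- seq(60, 140, by = 0.5)
  h <- structure(list(breaks = c(mids - 0.25, max(mids) + 0.25),
                      mids = mids,
                      counts = 1000 * exp(-(mids - 100)^2 / (2 * 10^2)),
                      n_events = 60000), class = "nfeq_histogram")
  pk <- fit_photopeak(h)
  expect_equal(pk$mean, 100, tolerance = 1e-6)
  expect_equal(pk$sigma, 10, tolerance = 1e-6)
  expect_equal(observed_resolution(pk), 2 * sqrt(2 * log(2)) * 10, # 23.55%
               tolerance = 1e-6)
  expect_equal(observed_resolution(pk), 23.55, tolerance = 1e-4)
})

test_that("Gaussian fit recovers sampled peaks within statistical error", {
  set.seed(31)
  for (rep in 1:3) {
    mu <- runif(1, 80, 600)
    sg <- mu * runif(1, 0.02, 0.1)
    x <- rnorm(1e4, mu, sg)
    pk <- fit_photopeak(x)
    expect_lt(abs(pk$mean - mu), 3 * sg / sqrt(1e4) * 2)
    expect_lt(abs(pk$sigma - sg), 3 * sg / sqrt(2 * 1e4) * 2)
  }
})

test_that("constrained double-Gaussian fit recovers generating parameters", {
  set.seed(32)
  m_fe <- 700; s_fe <- 20
  m_ke <- 0.918 * m_fe
  s_ke <- 1.3 * s_fe / m_fe * m_ke  # KE relative width 1.3x the FE one
  x <- c(rnorm(4e4, m_fe, s_fe), rnorm(1.6e4, m_ke, s_ke))
  pk <- fit_double_gaussian(x, e_full = 662, e_escape_loss = 54)
  expect_equal(pk$mean_ratio_bound, (662 - 54) / 662, tolerance = 1e-12)
  expect_equal(round(pk$mean_ratio_bound, 3), 0.918)
  expect_equal(pk$mean, m_fe, tolerance = 0.02)
  expect_equal(pk$sigma, s_fe, tolerance = 0.02)
  expect_equal(pk$escape$mean, m_ke, tolerance = 0.02)
  expect_equal(pk$escape$sigma, s_ke, tolerance = 0.02)
  # amplitude ratio reflects the event split and the width ratio
  expect_equal(pk$escape$amplitude / pk$amplitude,
               (1.6e4 / 4e4) * (s_fe / s_ke), tolerance = 0.05)
  # constraints satisfied on the fitted values
  expect_gte(pk$escape$mean / pk$mean, 0.918 * (1 - 1e-9))
  expect_gte(pk$escape$fwhm / pk$escape$mean, pk$fwhm / pk$mean * (1 - 1e-9))
  expect_lte(pk$escape$amplitude, pk$amplitude * (1 + 1e-9))
})

test_that("double fit degrades gracefully when the escape peak is absent", {
  set.seed(33)
  x <- rnorm(2e4, 700, 25)
  pk <- fit_double_gaussian(x, 662, 54)
  expect_lt(pk$escape$amplitude / pk$amplitude, 0.06)
  expect_equal(pk$mean, 700, tolerance = 0.02)
})

test_that("resolution corrections are exact on the identity curve", {
  resp <- with_cache("prop_resp", sipm_response(proportional_config(100)))
  ens <- simulate(resp, 8000, seed = 41)
  pk <- fit_photopeak(ens)
  r_obs <- observed_resolution(pk)
  expect_equal(corrected_resolution(pk, resp), r_obs, tolerance = 1e-6)
  expect_equal(observed_with_intrinsic(pk, 0, resp), r_obs, tolerance = 1e-6)
  # Poisson statistics: R ~ 2.355/sqrt(100) = 23.55%
  expect_equal(r_obs, 23.55, tolerance = 0.05)
})

test_that("saturation degrades the corrected resolution but flatters R_obs", {
  r_obs <- r_corr <- numeric(0)
  for (ntr in c(20, 80, 150)) {  # ~0.2 to 1.5 triggers per SPAD
    resp <- sipm_response(toy_config(ntr))
    pk <- fit_photopeak(simulate(resp, 8000, seed = 42))
    r_obs <- c(r_obs, observed_resolution(pk) * sqrt(ntr))
    r_corr <- c(r_corr, corrected_resolution(pk, resp) * sqrt(ntr))
  }
  # scaled by sqrt(ntr) to remove the 1/sqrt(N) statistics trend:
  # the residual corrected resolution worsens with saturation while the
  # observed one misleadingly improves
  expect_true(all(diff(r_corr) > 0))
  expect_true(all(diff(r_obs) < 0))
  # R_corr exceeds R_obs for a saturating (convex) response
  resp <- validation_response("3.0", 662)
  pk <- fit_photopeak(validation_ensemble("3.0", 662))
  expect_gt(corrected_resolution(pk, resp), observed_resolution(pk))
})

test_that("intrinsic combination is Pythagorean and symmetric", {
  expect_equal(combine_resolution(3, 4), 5)
  expect_equal(combine_resolution(7.3, 0), 7.3)
  expect_equal(combine_resolution(4, 3), combine_resolution(3, 4))
  expect_error(combine_resolution(-1, 3))
})

test_that("out-of-domain backprojection names the offending point", {
  resp <- validation_response("3.0", 662)
  pk <- list(mean = max(resp$curve$nf_eq) * 1.5, fwhm = 10)
  class(pk) <- "peak_fit"
  expect_error(corrected_resolution(pk, resp), "domain")
})
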