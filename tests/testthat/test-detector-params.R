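test_that("SPAD counting conventions match the device and design rules", {
  expect_identical(n_spads(1.0, 30, "per-side-floor"), 1089L)
  expect_identical(n_spads(1.0, 1000, "per-side-floor"), 1L)
  expect_identical(n_spads(1.0, 1000, "area-ratio-round"), 1L)
  expect_identical(n_spads(0.4, 15, "area-ratio-round"), 711L)
  expect_identical(n_spads(0.333, 15, "area-ratio-round"), 493L)
  expect_error(n_spads(0.02, 30), "invalid geometry")
  expect_error(n_spads(-1, 30), "positive")
})

test_that("n_spads is monotone in pitch and pixel side for both conventions", {
  sides <- c(0.2, 0.25, 0.333, 0.4, 0.5, 1.0)
  pitches <- c(10, 15, 30, 50)
  for (conv in c("per-side-floor", "area-ratio-round")) {
    for (d in sides) {
      counts <- vapply(pitches, function(p) n_spads(d, p, conv), 1L)
      expect_true(all(diff(counts) <= 0), info = paste(conv, "pitch", d))
    }
    for (p in pitches) {
      counts <- vapply(sides, function(d) n_spads(d, p, conv), 1L)
      expect_true(all(diff(counts) >= 0), info = paste(conv, "side", p))
    }
  }
})

test_that("built-in registry reproduces the published parameter tables", {
  reg <- default_registry()

  luap <- reg$scintillators[["LuAP:Ce (validation)"]]
  expect_equal(luap$light_yield, 5.7)
  expect_equal(luap$decay_ns, 17)
  expect_equal(unname(luap$nonprop_factor[c("59.5", "662")]), c(0.985, 1.000))
  expect_equal(unname(luap$intrinsic_resolution[c("59.5", "662")]),
               c(8.5, 2.8))

  v3 <- reg$sipms[["NUV-HD 30 um @3.0 V (validation)"]]
  expect_equal(c(v3$pde, v3$recharge_ns, v3$crosstalk), c(0.410, 39.3, 0.184))
  v5 <- reg$sipms[["NUV-HD 30 um @5.0 V (validation)"]]
  expect_equal(c(v5$pde, v5$recharge_ns, v5$crosstalk), c(0.455, 35.8, 0.361))

  s15 <- reg$sipms[["NUV-HD 15 um @7.0 V"]]
  expect_equal(c(s15$pde, s15$recharge_ns, s15$crosstalk),
               c(0.28, 7.0, 0.1235))
  s30 <- reg$sipms[["NUV-HD 30 um @3.0 V"]]
  expect_equal(c(s30$pde, s30$recharge_ns, s30$crosstalk),
               c(0.41, 55, 0.1235))

  expect_equal(reg$scintillators[["LYSO:Ce"]]$light_yield, 33)
  expect_equal(reg$scintillators[["LYSO:Ce"]]$decay_ns, 36)
  expect_equal(unname(reg$scintillators[["LYSO:Ce"]]$nonprop_factor["60"]),
               0.845)
  expect_equal(reg$scintillators[["LaBr3:Ce"]]$light_yield, 63)
  expect_equal(reg$scintillators[["LaBr3:Ce"]]$decay_ns, 16)
  expect_equal(
    unname(reg$scintillators[["LaBr3:Ce"]]$intrinsic_resolution["60"]), 8.0)
  expect_equal(reg$scintillators[["LuAP:Ce"]]$light_yield, 15)
})

test_that("registry YAML round trip is the identity on values", {
  reg <- default_registry()
  path <- withr::local_tempfile(fileext = ".yaml")
  save_registry(reg, path)
  reg2 <- load_registry(path)
  expect_equal(reg2, reg)
})

test_that("constructors reject out-of-range parameters with named errors", {
  expect_error(sipm_spec("bad", pde = 0, recharge_ns = 10, crosstalk = 0.1,
                         spad_pitch_um = 30), "pde")
  expect_error(sipm_spec("bad", pde = 0.3, recharge_ns = 10, crosstalk = 1,
                         spad_pitch_um = 30), "crosstalk")
  expect_error(scintillator_spec("bad", light_yield = -1, decay_ns = 17,
                                 nonprop_factor = c("60" = 1),
                                 intrinsic_resolution = c("60" = 8)),
               "light_yield")
  expect_error(scintillator_spec("bad", light_yield = 5, decay_ns = 17,
                                 nonprop_factor = c("60" = 1),
                                 intrinsic_resolution = c("60" = 120)),
               "intrinsic_resolution")
  scint <- default_registry()$scintillators[["LaBr3:Ce"]]
  sipm <- default_registry()$sipms[["NUV-HD 15 um @7.0 V"]]
  expect_error(pixel_config(scint, sipm, 0.4, eta_lc = 1.5, energy_kev = 60),
               "eta_lc")
  # energies are looked up exactly, never interpolated
  expect_error(pixel_config(scint, sipm, 0.4, eta_lc = 0.75,
                            energy_kev = 123), "tabulated")
})

test_that("a registry file with a missing field fails loudly", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("scintillators:",
               "- name: broken",
               "  decay_ns: 17",
               "  nonprop_factor_by_kev: {'60': 1.0}",
               "  intrinsic_resolution_pct_by_kev: {'60': 8.0}",
               "sipms: []"), path)
  expect_error(load_registry(path), "light_yield_ph_per_kev")
})
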