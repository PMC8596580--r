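#' Built-in parameter registry
#'
#' Returns the published parameter sets the package ships with: the LuAP:Ce
#' crystal and tuned 30 um-pitch NUV-HD SiPM used in the validation
#' experiments (at 3.0 V and 5.0 V overvoltage), and the LYSO:Ce, LuAP:Ce
#' and LaBr3:Ce scintillators and NUV-HD 30 um / 15 um SiPM operating points
#' used for the design study.
#'
#' @return A list with elements `scintillators` and `sipms`, each a named
#'   list of specification objects; class `"sipm_registry"`.
#' @examples
#' reg <- default_registry()
#' names(reg$sipms)
#' reg$scintillators[["LaBr3:Ce"]]
#' @export
default_registry <- function() {
  scint <- list(
    # validation crystal: fast-component yield 5.7 ph/keV (80% of 7.1),
    # slow component ~20% of the light with tau in the order of 500 ns
    scintillator_spec(
      name = "LuAP:Ce (validation)",
      light_yield = 5.7, decay_ns = 17,
      nonprop_factor = c("59.5" = 0.985, "662" = 1.000),
      intrinsic_resolution = c("59.5" = 8.5, "662" = 2.8),
      slow_fraction = 0.2, slow_decay_ns = 500),
    scintillator_spec(
      name = "LYSO:Ce",
      light_yield = 33, decay_ns = 36,
      nonprop_factor = c("59.5" = 0.845, "60" = 0.845),
      intrinsic_resolution = c("59.5" = 22, "60" = 22)),
    scintillator_spec(
      name = "LuAP:Ce",
      light_yield = 15, decay_ns = 17,
      nonprop_factor = c("59.5" = 0.985, "60" = 0.985),
      intrinsic_resolution = c("59.5" = 8.5, "60" = 8.5)),
    scintillator_spec(
      name = "LaBr3:Ce",
      light_yield = 63, decay_ns = 16,
      nonprop_factor = c("59.5" = 0.980, "60" = 0.980),
      intrinsic_resolution = c("59.5" = 8.0, "60" = 8.0))
  )
  sipm <- list(
    # tuned quenching resistors on the validation device shorten tau_r
    sipm_spec("NUV-HD 30 um @3.0 V (validation)",
              pde = 0.410, recharge_ns = 39.3, crosstalk = 0.184,
              spad_pitch_um = 30),
    sipm_spec("NUV-HD 30 um @5.0 V (validation)",
              pde = 0.455, recharge_ns = 35.8, crosstalk = 0.361,
              spad_pitch_um = 30),
    sipm_spec("NUV-HD 30 um @3.0 V",
              pde = 0.41, recharge_ns = 55, crosstalk = 0.1235,
              spad_pitch_um = 30),
    sipm_spec("NUV-HD 30 um @7.0 V",
              pde = 0.48, recharge_ns = 50, crosstalk = 0.5753,
              spad_pitch_um = 30),
    sipm_spec("NUV-HD 15 um @3.0 V",
              pde = 0.21, recharge_ns = 9.0, crosstalk = 0.0128,
              spad_pitch_um = 15),
    sipm_spec("NUV-HD 15 um @7.0 V",
              pde = 0.28, recharge_ns = 7.0, crosstalk = 0.1235,
              spad_pitch_um = 15)
  )
  structure(list(
    scintillators = stats::setNames(scint, vapply(scint, `[[`, "", "name")),
    sipms = stats::setNames(sipm, vapply(sipm, `[[`, "", "name"))
  ), class = "sipm_registry")
}

#' Look up a registry entry by name
#'
#' @param registry A registry from [default_registry()] or [load_registry()].
#' @param name Exact entry name.
#' @param type `"scintillator"` or `"sipm"`.
#' @return The specification object.
#' @export
registry_get <- function(registry, name, type = c("scintillator", "sipm")) {
  type <- match.arg(type)
  pool <- if (type == "scintillator") registry$scintillators else registry$sipms
  if (!name %in% names(pool)) {
    stop("no ", type, " named '", name, "' in registry (available: ",
         paste(names(pool), collapse = ", "), ")")
  }
  pool[[name]]
}

#' Read and write parameter registries as YAML
#'
#' The on-disk format is human-readable YAML with units spelled out in the
#' key names (`light_yield_ph_per_kev`, `decay_ns`, `spad_pitch_um`, ...),
#' since unit slips are the most likely user mistake. `load_registry()`
#' validates every entry and raises a named error on a missing field or
#' out-of-range value; `save_registry()` followed by `load_registry()` is
#' the identity on values.
#'
#' @param path File path.
#' @param registry A registry list as returned by [default_registry()].
#' @return `load_registry()` returns a `"sipm_registry"`;
#'   `save_registry()` returns `path` invisibly.
#' @export
load_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  need <- function(entry, field, where) {
    if (is.null(entry[[field]])) {
      stop("registry entry '", where, "' is missing field '", field, "'")
    }
    entry[[field]]
  }
  scint <- lapply(raw$scintillators, function(e) {
    nm <- e$name %||% "?"
    scintillator_spec(
      name = need(e, "name", nm),
      light_yield = need(e, "light_yield_ph_per_kev", nm),
      decay_ns = need(e, "decay_ns", nm),
      nonprop_factor = unlist(need(e, "nonprop_factor_by_kev", nm)),
      intrinsic_resolution = unlist(need(e, "intrinsic_resolution_pct_by_kev",
                                         nm)),
      slow_fraction = e$slow_fraction %||% 0,
      slow_decay_ns = e$slow_decay_ns %||% 500)
  })
  sipm <- lapply(raw$sipms, function(e) {
    nm <- e$name %||% "?"
    sipm_spec(
      name = need(e, "name", nm),
      pde = need(e, "pde", nm),
      recharge_ns = need(e, "recharge_ns", nm),
      crosstalk = need(e, "crosstalk_lambda", nm),
      spad_pitch_um = need(e, "spad_pitch_um", nm))
  })
  structure(list(
    scintillators = stats::setNames(scint, vapply(scint, `[[`, "", "name")),
    sipms = stats::setNames(sipm, vapply(sipm, `[[`, "", "name"))
  ), class = "sipm_registry")
}

#' @rdname load_registry
#' @export
save_registry <- function(registry, path) {
  as_list_scint <- function(s) list(
    name = s$name,
    light_yield_ph_per_kev = s$light_yield,
    decay_ns = s$decay_ns,
    nonprop_factor_by_kev = as.list(s$nonprop_factor),
    intrinsic_resolution_pct_by_kev = as.list(s$intrinsic_resolution),
    slow_fraction = s$slow_fraction,
    slow_decay_ns = s$slow_decay_ns)
  as_list_sipm <- function(s) list(
    name = s$name,
    pde = s$pde,
    recharge_ns = s$recharge_ns,
    crosstalk_lambda = s$crosstalk,
    spad_pitch_um = s$spad_pitch_um)
  yaml::write_yaml(list(
    scintillators = unname(lapply(registry$scintillators, as_list_scint)),
    sipms = unname(lapply(registry$sipms, as_list_sipm))
  ), path, precision = 15)
  invisible(path)
}

#' @export
print.sipm_registry <- function(x, ...) {
  cat("Parameter registry:", length(x$scintillators), "scintillators,",
      length(x$sipms), "SiPMs\n")
  cat("  scintillators:", paste(names(x$scintillators), collapse = ", "), "\n")
  cat("  sipms:        ", paste(names(x$sipms), collapse = ", "), "\n")
  invisible(x)
}

#' Validation-experiment pixel configuration
#'
#' Convenience constructor for the single-pixel validation detector: a
#' 1 x 1 mm2, 1089-SPAD tuned NUV-HD SiPM coupled to the LuAP:Ce validation
#' crystal, at a given overvoltage and photon energy.
#'
#' @param overvoltage `"3.0"` or `"5.0"` (volts above breakdown).
#' @param energy_kev 59.5 (Am-241) or 662 (Cs-137).
#' @param eta_lc Light collection efficiency; the published value fitted at
#'   59.5 keV / 3.0 V is 0.57 (see [fit_light_collection()]).
#' @return A [pixel_config()].
#' @export
validation_config <- function(overvoltage = c("3.0", "5.0"),
                              energy_kev = 59.5, eta_lc = 0.57) {
  overvoltage <- match.arg(overvoltage)
  reg <- default_registry()
  pixel_config(
    scintillator = reg$scintillators[["LuAP:Ce (validation)"]],
    sipm = reg$sipms[[sprintf("NUV-HD 30 um @%s V (validation)", overvoltage)]],
    pixel_mm = 1.0, eta_lc = eta_lc, energy_kev = energy_kev,
    n_spad = 1089L, convention = "per-side-floor")
}
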