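#' Scintillator specification
#'
#' Bundles the scintillator properties entering the detector response model:
#' the light yield \eqn{Y} (photons/keV, referenced to 662 keV), the
#' energy-dependent nonproportionality factor \eqn{f} (ratio of the yield at
#' the energy of interest to the yield at 662 keV), the scintillation decay
#' time constant \eqn{\tau_d} (ns), and the energy-dependent intrinsic
#' resolution \eqn{R_{intr}} (% FWHM), which collects the nonproportionality,
#' inhomogeneity and light-transport contributions that cannot be computed
#' from counting statistics.
#'
#' `nonprop_factor` and `intrinsic_resolution` are stored as per-energy maps
#' (named numeric vectors keyed by energy in keV) and looked up exactly; no
#' interpolation across energies is performed, because reference values exist
#' only at a few energies.
#'
#' @param name Scintillator name.
#' @param light_yield Light yield \eqn{Y} in photons/keV at 662 keV
#'   (for materials with a slow decay component, the yield of the fast
#'   component that contributes to the pulse).
#' @param decay_ns Decay time constant \eqn{\tau_d} in ns.
#' @param nonprop_factor Named numeric vector, names are energies in keV,
#'   values the dimensionless factor \eqn{f}.
#' @param intrinsic_resolution Named numeric vector, names are energies in
#'   keV, values \eqn{R_{intr}} in percent FWHM.
#' @param slow_fraction Fraction of emitted light in a slow decay component,
#'   in \[0, 1). Used only by the synthetic waveform generator; the response
#'   model itself considers the fast component.
#' @param slow_decay_ns Decay time constant of the slow component in ns.
#' @return An object of class `"scintillator_spec"`.
#' @seealso [sipm_spec()], [pixel_config()], [default_registry()]
#' @export
scintillator_spec <- function(name, light_yield, decay_ns, nonprop_factor,
                              intrinsic_resolution, slow_fraction = 0,
                              slow_decay_ns = 500) {
  obj <- structure(list(
    name = as.character(name),
    light_yield = as.numeric(light_yield),
    decay_ns = as.numeric(decay_ns),
    nonprop_factor = .as_energy_map(nonprop_factor, "nonprop_factor"),
    intrinsic_resolution = .as_energy_map(intrinsic_resolution,
                                          "intrinsic_resolution"),
    slow_fraction = as.numeric(slow_fraction),
    slow_decay_ns = as.numeric(slow_decay_ns)
  ), class = "scintillator_spec")
  validate_spec(obj)
  obj
}

#' SiPM specification
#'
#' Properties of a silicon photomultiplier at a fixed operating point:
#' photodetection efficiency \eqn{\eta_{pd}} (fraction of photons reaching
#' the sensor that trigger an avalanche), recharge time constant
#' \eqn{\tau_r} (ns) of the single-SPAD response, optical crosstalk
#' parameter \eqn{\lambda} (mean number of directly succeeding triggers per
#' trigger; Borel branching parameter) and the SPAD pitch in micrometres.
#'
#' @param name SiPM name (typically technology, pitch and overvoltage).
#' @param pde Photodetection efficiency \eqn{\eta_{pd}}, in (0, 1].
#' @param recharge_ns Recharge time constant \eqn{\tau_r} in ns (>= 0).
#' @param crosstalk Crosstalk parameter \eqn{\lambda}, in \[0, 1).
#' @param spad_pitch_um SPAD pitch in micrometres.
#' @return An object of class `"sipm_spec"`.
#' @export
sipm_spec <- function(name, pde, recharge_ns, crosstalk, spad_pitch_um) {
  obj <- structure(list(
    name = as.character(name),
    pde = as.numeric(pde),
    recharge_ns = as.numeric(recharge_ns),
    crosstalk = as.numeric(crosstalk),
    spad_pitch_um = as.numeric(spad_pitch_um)
  ), class = "sipm_spec")
  validate_spec(obj)
  obj
}

#' Detector pixel configuration
#'
#' One detector pixel: a scintillation crystal one-to-one coupled to an SiPM,
#' together with the pixel side length \eqn{d} (mm), the light collection
#' efficiency \eqn{\eta_{lc}}, the deposited X-ray energy \eqn{E} (keV) and
#' the number of SPADs on the pixel.
#'
#' `n_spad` is an explicit field, never silently derived: the physical
#' 1 x 1 mm2 validation device has 1089 (= 33^2) SPADs, obtained by the
#' `"per-side-floor"` convention, whereas design-study pixels use the
#' pixel-area / pitch-squared rule (`"area-ratio-round"`). If `n_spad` is
#' `NULL` it is computed from `pixel_mm`, the SiPM pitch and `convention`
#' via [n_spads()].
#'
#' @param scintillator A [scintillator_spec()].
#' @param sipm A [sipm_spec()].
#' @param pixel_mm Pixel side length \eqn{d} in mm.
#' @param eta_lc Light collection efficiency \eqn{\eta_{lc}}, in (0, 1].
#' @param energy_kev Deposited energy \eqn{E} in keV. Must have an entry in
#'   the scintillator's nonproportionality map.
#' @param n_spad Number of SPADs (positive integer), or `NULL` to derive.
#' @param convention SPAD-count convention passed to [n_spads()].
#' @return An object of class `"pixel_config"`.
#' @export
pixel_config <- function(scintillator, sipm, pixel_mm, eta_lc, energy_kev,
                         n_spad = NULL,
                         convention = c("area-ratio-round", "per-side-floor")) {
  stopifnot(inherits(scintillator, "scintillator_spec"),
            inherits(sipm, "sipm_spec"))
  convention <- match.arg(convention)
  if (is.null(n_spad)) {
    n_spad <- n_spads(pixel_mm, sipm$spad_pitch_um, convention)
  }
  obj <- structure(list(
    scintillator = scintillator,
    sipm = sipm,
    pixel_mm = as.numeric(pixel_mm),
    eta_lc = as.numeric(eta_lc),
    energy_kev = as.numeric(energy_kev),
    n_spad = as.integer(n_spad),
    convention = convention
  ), class = "pixel_config")
  validate_spec(obj)
  obj
}

#' Number of SPADs on a square pixel
#'
#' Two conventions are implemented. `"per-side-floor"` packs whole SPADs
#' along each side, `floor(side/pitch)^2`; this reproduces the 1089 SPADs of
#' a 1 x 1 mm2 device with 30 um pitch. `"area-ratio-round"` rounds the
#' pixel area divided by the SPAD pitch squared, the assumption used for
#' design-study pixels whose side is not a pitch multiple.
#'
#' @param pixel_mm Pixel side length in mm.
#' @param spad_pitch_um SPAD pitch in micrometres; must not exceed the side.
#' @param convention Which counting convention to use.
#' @return A positive integer count.
#' @examples
#' n_spads(1.0, 30, "per-side-floor")    # 1089
#' n_spads(0.333, 15)                    # 493
#' @export
n_spads <- function(pixel_mm, spad_pitch_um,
                    convention = c("area-ratio-round", "per-side-floor")) {
  convention <- match.arg(convention)
  if (!is.numeric(pixel_mm) || !is.numeric(spad_pitch_um) ||
      pixel_mm <= 0 || spad_pitch_um <= 0) {
    stop("pixel side and SPAD pitch must be positive")
  }
  side_um <- pixel_mm * 1000
  if (spad_pitch_um > side_um) {
    stop("invalid geometry: SPAD pitch (", spad_pitch_um,
         " um) exceeds pixel side (", side_um, " um)")
  }
  ratio <- side_um / spad_pitch_um
  n <- switch(convention,
              "per-side-floor" = floor(ratio)^2,
              "area-ratio-round" = round(ratio^2))
  as.integer(max(1, n))
}

# -- validation ---------------------------------------------------------------

.as_energy_map <- function(x, what) {
  x <- unlist(x)
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop(what, " must be a named vector keyed by energy in keV")
  }
  if (anyNA(suppressWarnings(as.numeric(names(x))))) {
    stop(what, " names must be numeric energies in keV")
  }
  storage.mode(x) <- "double"
  x
}

.energy_lookup <- function(map, energy_kev, what) {
  key <- which(abs(as.numeric(names(map)) - energy_kev) < 1e-9)
  if (length(key) != 1) {
    stop("no ", what, " tabulated at ", energy_kev,
         " keV (available: ", paste(names(map), collapse = ", "),
         " keV); energy-dependent factors are looked up exactly, not ",
         "interpolated")
  }
  unname(map[key])
}

#' Validate a specification object
#'
#' Checks the physical invariants of a [scintillator_spec()], [sipm_spec()]
#' or [pixel_config()] and fails with a named validation error when one is
#' violated. Called by the constructors and by [load_registry()].
#'
#' @param x Specification object.
#' @return `x`, invisibly, if valid.
#' @export
validate_spec <- function(x) {
  fail <- function(field, msg) {
    stop("invalid ", class(x)[1], " ('", x$name %||% "?", "'): ",
         field, " ", msg, call. = FALSE)
  }
  if (inherits(x, "scintillator_spec")) {
    if (!isTRUE(x$light_yield > 0)) fail("light_yield", "must be > 0")
    if (!isTRUE(x$decay_ns > 0)) fail("decay_ns", "must be > 0")
    if (any(x$nonprop_factor <= 0)) fail("nonprop_factor", "must be > 0")
    if (any(x$intrinsic_resolution < 0 | x$intrinsic_resolution >= 100)) {
      fail("intrinsic_resolution", "must be in [0, 100) percent")
    }
    if (!isTRUE(x$slow_fraction >= 0 && x$slow_fraction < 1)) {
      fail("slow_fraction", "must be in [0, 1)")
    }
  } else if (inherits(x, "sipm_spec")) {
    if (!isTRUE(x$pde > 0 && x$pde <= 1)) fail("pde", "must be in (0, 1]")
    if (!isTRUE(x$recharge_ns >= 0)) fail("recharge_ns", "must be >= 0")
    if (!isTRUE(x$crosstalk >= 0 && x$crosstalk < 1)) {
      fail("crosstalk", "must be in [0, 1)")
    }
    if (!isTRUE(x$spad_pitch_um > 0)) fail("spad_pitch_um", "must be > 0")
  } else if (inherits(x, "pixel_config")) {
    if (!isTRUE(x$pixel_mm > 0)) fail("pixel_mm", "must be > 0")
    if (!isTRUE(x$eta_lc > 0 && x$eta_lc <= 1)) {
      fail("eta_lc", "must be in (0, 1]")
    }
    if (!isTRUE(x$energy_kev > 0)) fail("energy_kev", "must be > 0")
    if (!isTRUE(x$n_spad >= 1)) fail("n_spad", "must be >= 1")
    .energy_lookup(x$scintillator$nonprop_factor, x$energy_kev,
                   "nonproportionality factor")
  } else {
    stop("not a specification object")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scintillator_spec <- function(x, ...) {
  cat("Scintillator:", x$name, "\n")
  cat(sprintf("  light yield     %g photons/keV (at 662 keV)\n", x$light_yield))
  cat(sprintf("  decay constant  %g ns\n", x$decay_ns))
  cat("  f:             ",
      paste(sprintf("%s keV -> %g", names(x$nonprop_factor), x$nonprop_factor),
            collapse = "; "), "\n")
  cat("  R_intr (%):    ",
      paste(sprintf("%s keV -> %g", names(x$intrinsic_resolution),
                    x$intrinsic_resolution), collapse = "; "), "\n")
  if (x$slow_fraction > 0) {
    cat(sprintf("  slow component  %g%% of light, tau = %g ns\n",
                100 * x$slow_fraction, x$slow_decay_ns))
  }
  invisible(x)
}

#' @export
print.sipm_spec <- function(x, ...) {
  cat("SiPM:", x$name, "\n")
  cat(sprintf("  eta_pd = %g, tau_r = %g ns, lambda = %g, pitch = %g um\n",
              x$pde, x$recharge_ns, x$crosstalk, x$spad_pitch_um))
  invisible(x)
}

#' @export
print.pixel_config <- function(x, ...) {
  cat(sprintf("Pixel: %g x %g mm2 %s on %s\n", x$pixel_mm, x$pixel_mm,
              x$scintillator$name, x$sipm$name))
  cat(sprintf("  E = %g keV, eta_lc = %g, N_SPAD = %d (%s)\n",
              x$energy_kev, x$eta_lc, x$n_spad, x$convention))
  invisible(x)
}
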