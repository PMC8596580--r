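#' Read a pixel configuration from a YAML file
#'
#' The file names a scintillator and an SiPM (built-in registry names, or
#' entries of a registry file given alongside) plus the pixel geometry:
#'
#' ```yaml
#' scintillator: "LaBr3:Ce"
#' sipm: "NUV-HD 15 um @7.0 V"
#' pixel_mm: 0.4
#' eta_lc: 0.75
#' energy_kev: 60
#' # n_spad: 711        # optional; derived from the convention otherwise
#' # convention: area-ratio-round
#' ```
#'
#' @param path YAML file path.
#' @param registry Registry resolving the names.
#' @return A [pixel_config()].
#' @export
load_pixel_config <- function(path, registry = default_registry()) {
  y <- yaml::read_yaml(path)
  for (field in c("scintillator", "sipm", "pixel_mm", "eta_lc", "energy_kev")) {
    if (is.null(y[[field]])) {
      stop("pixel config '", path, "' is missing field '", field, "'")
    }
  }
  pixel_config(
    scintillator = registry_get(registry, y$scintillator, "scintillator"),
    sipm = registry_get(registry, y$sipm, "sipm"),
    pixel_mm = y$pixel_mm,
    eta_lc = y$eta_lc,
    energy_kev = y$energy_kev,
    n_spad = y$n_spad,
    convention = y$convention %||% "area-ratio-round")
}
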