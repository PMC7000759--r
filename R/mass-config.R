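#' Monitored-isotope configuration for calibration and quantification
#'
#' Describes the isotope masses monitored during a run: labels, atomic masses
#' of the corresponding elements, reference concentrations in the external
#' calibration glass (NIST-612) and in the carbonate QC standard (MACS-3),
#' the internal-standard label, and the assumed Ca mass fraction of vertebral
#' bioapatite used to place calibrated signals on an absolute ppm scale.
#' Element:Ca ratios do not depend on the Ca mass fraction assumption.
#'
#' The standard concentrations here are working defaults shared between the
#' synthetic generator and the reducer, not certificate values: the pipeline
#' is self-consistent as long as both sides use the same configuration.
#'
#' @param isotopes data.frame with columns `label`, `atomic_mass` (g/mol),
#'   `nist612_ppm`, `macs3_ppm`. Defaults to 13 monitored masses
#'   (12 trace masses plus the Ca43 internal standard).
#' @param internal_standard label of the internal-standard mass (`"Ca43"`).
#' @param ca_mass_fraction assumed Ca mass fraction of the ablated vertebral
#'   matrix (default 0.399), configurable because the true index of a given
#'   skeleton is unknown.
#' @return object of class `mass_config`.
#' @export
#' @examples
#' cfg <- mass_config()
#' cfg$isotopes$label
mass_config <- function(isotopes = default_isotopes(),
                        internal_standard = "Ca43",
                        ca_mass_fraction = 0.399) {
  stopifnot(is.data.frame(isotopes),
            all(c("label", "atomic_mass", "nist612_ppm", "macs3_ppm") %in%
                  names(isotopes)))
  if (!internal_standard %in% isotopes$label) {
    stop("internal standard '", internal_standard,
         "' is not among the monitored isotopes")
  }
  if (any(isotopes$atomic_mass <= 0)) stop("atomic masses must be > 0")
  if (any(isotopes$nist612_ppm < 0) || any(isotopes$macs3_ppm < 0)) {
    stop("standard concentrations must be >= 0")
  }
  if (anyDuplicated(isotopes$label)) stop("duplicate isotope labels")
  if (!(ca_mass_fraction > 0 && ca_mass_fraction < 1)) {
    stop("ca_mass_fraction must be in (0, 1)")
  }
  structure(list(isotopes = isotopes,
                 internal_standard = internal_standard,
                 ca_mass_fraction = ca_mass_fraction),
            class = "mass_config")
}

#' Default monitored-isotope table
#'
#' Twelve trace masses routinely retained in vertebral microchemistry plus
#' the Ca43 internal standard. Atomic masses are standard atomic weights of
#' the elements; standard concentrations are plausible working values for a
#' trace-doped silicate glass and a carbonate pellet.
#'
#' @return data.frame with one row per monitored mass.
#' @export
default_isotopes <- function() {
  data.frame(
    label       = c("Li7", "Mg24", "Ca43", "Mn55", "Fe57", "Co59", "Cu63",
                    "Rb85", "Sr88", "Y89", "Ba137", "Pb208", "U238"),
    atomic_mass = c(6.94, 24.305, 40.078, 54.938, 55.845, 58.933, 63.546,
                    85.468, 87.62, 88.906, 137.327, 207.2, 238.029),
    nist612_ppm = c(40, 68, 85050, 38, 51, 35, 37,
                    31, 78, 38, 39, 39, 37),
    macs3_ppm   = c(10, 1500, 380000, 550, 11000, 60, 120,
                    5, 6700, 30, 60, 60, 1.5),
    stringsAsFactors = FALSE
  )
}

#' @export
print.mass_config <- function(x, ...) {
  cat("Mass configuration:", nrow(x$isotopes), "monitored masses\n")
  cat("  internal standard:", x$internal_standard,
      "| assumed Ca mass fraction:", x$ca_mass_fraction, "\n")
  cat("  masses:", paste(x$isotopes$label, collapse = ", "), "\n")
  invisible(x)
}

#' Assumed internal-standard concentration (ppm) of the sample matrix
#' @keywords internal
ca_ppm <- function(config) config$ca_mass_fraction * 1e6
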