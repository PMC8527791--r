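# Internal validation helpers. All user-facing errors funnel through these so
# messages carry the offending value.

stop_schema <- function(...) {
  stop(structure(class = c("spectratraits_schema_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_validation <- function(...) {
  stop(structure(class = c("spectratraits_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_validation(name, " must be a single finite number")
  invisible(x)
}

#' Canonical trait names
#'
#' The ten physiological traits predicted by the package, in the fixed column
#' order used by every trait table and predictions CSV: leaf dry mass per area
#' (LMA, g m^-2), nitrogen per area (Narea, g N m^-2), SPAD chlorophyll index,
#' nitrogen per dry mass (Nmass, mg N g^-1), maximum Rubisco carboxylation rate
#' (Vcmax) and its 25 degree C normalisation (Vcmax25), electron transport rate
#' (J), CO2 assimilation rate (A) (all umol m^-2 s^-1), stomatal conductance
#' (gs, mol m^-2 s^-1), and Vcmax25 per unit nitrogen (Vcmax25/Narea,
#' umol CO2 s^-1 (g N)^-1).
#'
#' @return Character vector of length 10.
#' @export
#' @examples
#' trait_names()
trait_names <- function() {
  c("LMA", "Narea", "SPAD", "Nmass", "Vcmax", "Vcmax25", "J", "A", "gs",
    "Vcmax25/Narea")
}

# Reference location/spread and per-trait sample counts (out of 1013 spectra)
# for the wheat field/glasshouse population the models target. Used as the
# synthetic generator's default trait marginals and missingness rates.
trait_reference_moments <- function() {
  data.frame(
    trait  = trait_names(),
    n      = c(525L, 1013L, 614L, 615L, 488L, 488L, 488L, 488L, 488L, 488L),
    mean   = c(59.32, 2.59, 48.5, 42.89, 170.36, 148.02, 218.17, 24.99, 0.48, 59.95),
    median = c(60.24, 2.70, 49.75, 43.84, 159.16, 151.02, 222.80, 26.58, 0.45, 59.68),
    sd     = c(12.54, 0.77, 8.27, 8.60, 65.78, 40.10, 56.20, 6.40, 0.21, 14.04),
    stringsAsFactors = FALSE
  )
}
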