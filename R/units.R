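#' Unit conversions between SI hydraulic units and clinical units
#'
#' All internal computation uses SI hydraulic units: pressure in Pa, flow in
#' m^3/s, volume in m^3, resistance in Pa.s/m^3, compliance in m^3/Pa,
#' inertance in Pa.s^2/m^3, elastance in Pa/m^3. Clinical reporting uses
#' mmHg, mL and mL/s (1 mmHg = 133.322 Pa, 1 mL = 1e-6 m^3).
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
mmhg_to_pa <- function(x) x * 133.322

#' @rdname units
#' @export
pa_to_mmhg <- function(x) x / 133.322

#' @rdname units
#' @export
ml_to_m3 <- function(x) x * 1e-6

#' @rdname units
#' @export
m3_to_ml <- function(x) x * 1e6

# resistance mmHg.s/mL -> Pa.s/m^3
rc_to_si <- function(x) x * 133.322 / 1e-6
# compliance mL/mmHg -> m^3/Pa
cc_to_si <- function(x) x * 1e-6 / 133.322
# elastance mmHg/mL -> Pa/m^3
ec_to_si <- function(x) x * 133.322 / 1e-6
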