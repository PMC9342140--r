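#' Fractional decline of maximal oxygen uptake with altitude
#'
#' Curvilinear decline fitted through zero at sea level:
#' 0.007·km^2 + 0.03·km. The supported range is 0-8 km, the domain of the
#' underlying meta-analysis; beyond it the quadratic extrapolates towards
#' full attenuation and is refused rather than evaluated.
#'
#' @param km Altitude above sea level, kilometres, in \[0, 8\].
#' @return Fractional decline in \[0, 1); 0 at sea level, strictly
#'   increasing in `km`.
#' @examples
#' altitude_attenuation(c(0, 4, 5))
#' @export
altitude_attenuation <- function(km) {
  if (any(km < 0)) stop("'km' must be non-negative", call. = FALSE)
  if (any(km > 8))
    stop("altitude above 8 km is outside the supported range", call. = FALSE)
  0.007 * km^2 + 0.03 * km
}

#' Arteriovenous oxygen difference at altitude
#'
#' Hypobaric hypoxia lowers the oxygen extraction available at the muscle.
#' Resting and maximal extraction are both scaled by (1 - attenuation),
#' and the instantaneous sea-level extraction at the requested uptake is
#' linearly remapped between these altitude-modulated endpoints. The
#' sea-level extraction itself is the Fick quotient vo2 / basic CO at that
#' uptake.
#'
#' @param basic A [basic_cardio()] object.
#' @param vo2 Oxygen uptake, L·min^-1 (>= resting uptake).
#' @param km Altitude, km, in \[0, 8\].
#' @return Whole-body arteriovenous oxygen difference, L O2 per L blood.
#' @export
avo2diff_at_altitude <- function(basic, vo2, km) {
  stopifnot(inherits(basic, "cvr_basic"))
  att <- altitude_attenuation(km)
  span <- basic$avo2diff_max - basic$avo2diff_rest
  if (span <= 0)
    stop("degenerate extraction span: avo2diff_max must exceed avo2diff_rest",
         call. = FALSE)
  sea <- vo2 / basic_response(basic, vo2_reserve_fraction(vo2, basic))$co
  pos <- (sea - basic$avo2diff_rest) / span
  rest_alt <- (1 - att) * basic$avo2diff_rest
  max_alt <- (1 - att) * basic$avo2diff_max
  pos * (max_alt - rest_alt) + rest_alt
}

#' Cardiac output required at altitude
#'
#' With extraction attenuated, maintaining a given absolute oxygen uptake
#' requires proportionally more blood flow: CO(altitude) = vo2 divided by
#' the altitude-modulated extraction. Equals the basic cardiac output at
#' sea level and exceeds it at any positive altitude.
#'
#' @inheritParams avo2diff_at_altitude
#' @return Cardiac output, L·min^-1.
#' @examples
#' b <- basic_cardio(cvr_profile(25, 75, 175, "male", 4.0))
#' cardiac_output_at_altitude(b, vo2 = 2.0, km = 5)
#' @export
cardiac_output_at_altitude <- function(basic, vo2, km) {
  vo2 / avo2diff_at_altitude(basic, vo2, km)
}
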