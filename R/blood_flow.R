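#' Fraction of cardiac output directed to the core
#'
#' Quadratic in the relative cardiac demand FCO = CO / CO_max:
#' 0.86·FCO^2 - 1.79·FCO + 1.06, strictly decreasing over (0, 1]. The
#' constant term exceeds 1, so the unclamped extrapolation at FCO = 0
#' would direct more than the whole output to the core; the model never
#' operates there (resting FCO is about 0.2) and the form is kept
#' unclamped.
#'
#' @param fco Cardiac output as a fraction of the environment-modulated
#'   maximum (>= 0).
#' @return Fraction of cardiac output perfusing viscera and major organs.
#' @examples
#' core_flow_fraction(c(0, 0.2, 1))
#' @export
core_flow_fraction <- function(fco) {
  if (any(fco < 0)) stop("'fco' must be non-negative", call. = FALSE)
  0.86 * fco^2 - 1.79 * fco + 1.06
}

#' Core blood flow
#'
#' The environment-modulated cardiac output times the core flow fraction
#' evaluated at the relative cardiac demand.
#'
#' @param co_env Cardiac output modulated for heat, dehydration and
#'   altitude, L·min^-1 (> 0).
#' @param co_max_env Environment-modulated maximal cardiac output,
#'   L·min^-1 (> 0).
#' @return Core blood flow, L·min^-1.
#' @export
core_blood_flow <- function(co_env, co_max_env) {
  if (any(co_max_env <= 0))
    stop("'co_max_env' must be positive", call. = FALSE)
  if (any(co_env <= 0)) stop("'co_env' must be positive", call. = FALSE)
  co_env * core_flow_fraction(co_env / co_max_env)
}

#' Skin blood flow
#'
#' A thermoneutral baseline of 5% of the basic resting cardiac output,
#' plus the heat-excess cardiac output - the difference between the
#' heat-and-altitude-modulated output and the altitude-only output at the
#' same workload. In a coupled thermoregulatory model this value is
#' better treated as a constraint on the skin flow the thermal model
#' requests than as a direct substitution; standalone, it is reported
#' as-is so a coupling layer can apply it as a cap.
#'
#' @param co_rest_basic Basic resting cardiac output, L·min^-1.
#' @param co_env Heat-and-altitude-modulated cardiac output, L·min^-1.
#' @param co_altitude Altitude-only cardiac output at the same workload,
#'   L·min^-1.
#' @return Skin blood flow, L·min^-1.
#' @export
skin_blood_flow <- function(co_rest_basic, co_env, co_altitude) {
  0.05 * co_rest_basic + (co_env - co_altitude)
}

#' Partition cardiac output into core, skin and muscle flows
#'
#' Muscle flow is the remainder after core and skin flows, so the three
#' flows sum to the total output exactly by construction. Active-muscle
#' oxygen extraction is the above-resting uptake divided by muscle flow;
#' at resting uptake it is defined as 0. A non-positive muscle flow
#' (possible under extreme strain at rest) or an extraction above
#' 1 L O2 per L blood is reported with `domain_ok = FALSE` rather than
#' clamped, since clamping would silently break conservation.
#'
#' @param co_env Heat-and-altitude-modulated cardiac output, L·min^-1.
#' @param co_max_env Environment-modulated maximal cardiac output,
#'   L·min^-1.
#' @param co_rest_basic Basic resting cardiac output, L·min^-1.
#' @param co_altitude Altitude-only cardiac output at the same workload,
#'   L·min^-1.
#' @param vo2 Oxygen uptake at this timestep, L·min^-1.
#' @param vo2rest Resting oxygen uptake, L·min^-1.
#' @return A list of class `cvr_bloodflow` with fields `core_bf`,
#'   `skin_bf`, `muscle_bf` (L·min^-1), `fco` (fraction of the modulated
#'   maximum), `active_muscle_avo2diff` (L O2 per L blood) and
#'   `domain_ok`.
#' @export
partition_blood_flow <- function(co_env, co_max_env, co_rest_basic,
                                 co_altitude, vo2, vo2rest) {
  core <- core_blood_flow(co_env, co_max_env)
  skin <- skin_blood_flow(co_rest_basic, co_env, co_altitude)
  muscle <- co_env - skin - core
  above_rest <- vo2 - vo2rest
  domain_ok <- muscle > 0
  extraction <- if (above_rest <= 0) 0 else above_rest / muscle
  if (is.finite(extraction) && extraction > 1) domain_ok <- FALSE
  structure(
    list(core_bf = core, skin_bf = skin, muscle_bf = muscle,
         fco = co_env / co_max_env,
         active_muscle_avo2diff = extraction,
         domain_ok = domain_ok),
    class = "cvr_bloodflow"
  )
}
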