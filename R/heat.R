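#' Thermal and hydration state of the body
#'
#' Mean body temperature is the mass-weighted combination
#' 0.2·T_skin + 0.8·T_core unless supplied directly via `t_body` (useful
#' when only a mean body temperature is reported). The elevation above the
#' thermoneutral reference of 36.54 degC is floored at zero: the heat
#' strain index was developed for heat strain, and a hypothermic body
#' temperature must not generate negative strain.
#'
#' @param t_core Core temperature, degC.
#' @param t_skin Mean skin temperature, degC.
#' @param dehydration_pct Body-mass loss as a percentage of body mass
#'   (>= 0).
#' @param t_body Mean body temperature, degC; overrides the weighted
#'   combination when given.
#' @return An object of class `cvr_thermal` with fields `t_body`
#'   and `delta_t_body` (degC, floored at 0) alongside the inputs.
#' @examples
#' thermal_state(t_core = 38.5, t_skin = 35, dehydration_pct = 1.5)
#' thermal_state(t_body = 39, dehydration_pct = 2)
#' @export
thermal_state <- function(t_core = NULL, t_skin = NULL,
                          dehydration_pct = 0, t_body = NULL) {
  if (is.null(t_body)) {
    if (is.null(t_core) || is.null(t_skin))
      stop("supply either 't_body' or both 't_core' and 't_skin'",
           call. = FALSE)
    t_body <- 0.2 * t_skin + 0.8 * t_core
  }
  if (dehydration_pct < 0)
    stop("'dehydration_pct' must be non-negative", call. = FALSE)
  structure(
    list(t_core = t_core, t_skin = t_skin, t_body = t_body,
         delta_t_body = max(0, t_body - 36.54),
         dehydration_pct = dehydration_pct),
    class = "cvr_thermal"
  )
}

#' Progressive dehydration by linear interpolation
#'
#' When only the total mass loss over an exercise bout is known, the
#' instantaneous dehydration percentage is approximated by linear
#' interpolation over elapsed exercise time. The clock counts exercise
#' time only; rest phases accrue nothing. Elapsed time past the stated
#' total is clamped at the total loss.
#'
#' @param elapsed_exercise_min Exercise time elapsed so far, minutes.
#' @param total_exercise_min Total exercise time of the bout, minutes.
#' @param total_mass_loss_kg Body mass lost by the end of the bout, kg.
#' @param mass_kg Pre-exposure body mass, kg.
#' @return Dehydration, percent of body mass.
#' @examples
#' dehydration_percent(30, 60, total_mass_loss_kg = 1.5, mass_kg = 75)
#' @export
dehydration_percent <- function(elapsed_exercise_min, total_exercise_min,
                                total_mass_loss_kg, mass_kg) {
  if (any(elapsed_exercise_min < 0) || total_mass_loss_kg < 0)
    stop("times and mass loss must be non-negative", call. = FALSE)
  if (total_exercise_min == 0) {
    if (any(elapsed_exercise_min > 0))
      stop("elapsed exercise time with zero total exercise time",
           call. = FALSE)
    return(rep(0, length(elapsed_exercise_min)))
  }
  frac <- pmin(elapsed_exercise_min / total_exercise_min, 1)
  frac * total_mass_loss_kg / mass_kg * 100
}

#' Cardiac heat strain index
#'
#' A dimensionless, degC-equivalent index combining body-temperature
#' elevation and dehydration that scales the heat modulation of stroke
#' volume and cardiac output. Two variants are provided:
#' \describe{
#'   \item{additive}{0.5·D + 0.5·dT; equal, independent contributions.
#'     The default, as it predicted heterogeneous validation groups best.}
#'   \item{synergistic}{0.433·D + 0.091·dT + 0.125·D·dT; includes the
#'     dehydration-by-hyperthermia interaction observed in
#'     endurance-trained runners.}
#' }
#' where D is dehydration (% body mass) and dT the body-temperature
#' elevation above 36.54 degC. An index of 3.9 is scaled to equal the
#' effect of a 3.9 degC rise in mean body temperature; the index is not
#' capped above that anchor. Negative values cannot arise because both
#' inputs are floored at zero.
#'
#' @param thermal A [thermal_state()].
#' @param variant `"additive"` (default) or `"synergistic"`.
#' @return An object of class `cvr_chsi` with fields `value` and
#'   `variant`.
#' @examples
#' chsi(thermal_state(t_body = 39, dehydration_pct = 2))
#' @export
chsi <- function(thermal, variant = c("additive", "synergistic")) {
  stopifnot(inherits(thermal, "cvr_thermal"))
  variant <- match.arg(variant)
  value <- chsi_index(thermal$dehydration_pct, thermal$delta_t_body, variant)
  structure(list(value = value, variant = variant), class = "cvr_chsi")
}

#' Heat strain index kernel
#'
#' The raw polynomial behind [chsi()], exposed for direct evaluation at
#' chosen dehydration and temperature-elevation values.
#'
#' @param dehydration_pct Dehydration, percent of body mass (>= 0).
#' @param delta_t_body Mean body-temperature elevation above 36.54 degC
#'   (>= 0; callers flooring at zero should do so before the call).
#' @param variant `"additive"` or `"synergistic"`.
#' @return Index value (dimensionless, >= 0).
#' @examples
#' chsi_index(1, 0, "synergistic")
#' @export
chsi_index <- function(dehydration_pct, delta_t_body,
                       variant = c("additive", "synergistic")) {
  variant <- match.arg(variant)
  if (any(dehydration_pct < 0) || any(delta_t_body < 0))
    stop("dehydration and temperature elevation must be non-negative",
         call. = FALSE)
  v <- switch(variant,
    additive = 0.5 * dehydration_pct + 0.5 * delta_t_body,
    synergistic = 0.433 * dehydration_pct + 0.091 * delta_t_body +
      0.125 * dehydration_pct * delta_t_body
  )
  pmax(0, v)
}

#' Heat sensitivity coefficients
#'
#' Relative change of each resting/maximal quantity per unit of heat
#' strain index. The `"published"` set is the rounded summary of the
#' source meta-analyses (resting SV +2.5%, resting CO +31.3%, maximal SV
#' and CO -8.3% per index unit). The `"adjusted"` preset scales the
#' sensitivities by 1.5 (to -0.125, -0.125, 0.038, 0.47) and raises the
#' resting heart-rate intercept by 10 beats·min^-1, an exploratory
#' recalibration that removes the systematic heart-rate underestimation
#' observed against heterogeneous heat-exposure data.
#'
#' @param calibration `"published"` (default) or `"adjusted"`.
#' @return A list with components `sv_max`, `co_max`, `sv_rest`,
#'   `co_rest` (per index unit) and `hr_rest_intercept` (beats·min^-1).
#' @export
heat_sensitivities <- function(calibration = c("published", "adjusted")) {
  calibration <- match.arg(calibration)
  switch(calibration,
    published = list(sv_max = -0.083, co_max = -0.083,
                     sv_rest = 0.025, co_rest = 0.313,
                     hr_rest_intercept = 90.93),
    adjusted = list(sv_max = -0.125, co_max = -0.125,
                    sv_rest = 0.038, co_rest = 0.47,
                    hr_rest_intercept = 100.93)
  )
}

#' Modulate the basic cardiovascular constants for heat and altitude
#'
#' Heat strain (via the index) lowers maximal stroke volume and cardiac
#' output and raises their resting values; maximal heart rate is not
#' modulated, so the decline in maximal cardiac output is carried
#' entirely by stroke volume, and a new resting heart rate follows from
#' the resting quotient. Altitude enters only through the attenuated
#' maximal extraction in the environment-limited maximal oxygen uptake;
#' the modulated stroke-volume/cardiac-output fields themselves carry no
#' altitude term (the field's "(heat, altitude)" naming notwithstanding,
#' altitude acts through the required cardiac output at a workload, not
#' through these constants).
#'
#' @param basic A [basic_cardio()] object.
#' @param strain A [chsi()] object or a single non-negative number.
#' @param km Altitude, km, used for the environment-limited maximal
#'   oxygen uptake. Default 0.
#' @param calibration Sensitivity preset, see [heat_sensitivities()].
#' @return An object of class `cvr_env` with fields `sv_max_env`,
#'   `sv_rest_env` (mL·beat^-1), `co_max_env`, `co_rest_env` (L·min^-1),
#'   `hr_rest_env` (beats·min^-1), `vo2max_env` (L·min^-1), plus the
#'   `chsi`, `km` and `domain_ok` bookkeeping fields. `domain_ok` is
#'   `FALSE` when the strain is so large that the modulated maximal
#'   cardiac output no longer exceeds the modulated resting value.
#' @examples
#' b <- basic_cardio(cvr_profile(25, 75, 175, "male", 4.0))
#' modulate_cardio(b, chsi(thermal_state(t_body = 39, dehydration_pct = 2)))
#' @export
modulate_cardio <- function(basic, strain, km = 0,
                            calibration = c("published", "adjusted")) {
  stopifnot(inherits(basic, "cvr_basic"))
  s <- heat_sensitivities(calibration)
  value <- if (inherits(strain, "cvr_chsi")) strain$value else strain
  if (!is.numeric(value) || length(value) != 1L || value < 0)
    stop("'strain' must be a cvr_chsi object or a single non-negative number",
         call. = FALSE)
  sv_max_env <- (1 + value * s$sv_max) * basic$sv_max
  co_max_env <- (1 + value * s$co_max) * basic$co_max
  sv_rest_env <- (1 + value * s$sv_rest) * basic$sv_rest
  co_rest_env <- (1 + value * s$co_rest) * basic$co_rest
  hr_rest_env <- co_rest_env / sv_rest_env * 1000
  vo2max_env <- (1 - altitude_attenuation(km)) * basic$avo2diff_max *
    co_max_env
  structure(
    list(sv_max_env = sv_max_env, sv_rest_env = sv_rest_env,
         co_max_env = co_max_env, co_rest_env = co_rest_env,
         hr_rest_env = hr_rest_env, vo2max_env = vo2max_env,
         chsi = value, km = km,
         domain_ok = co_max_env > co_rest_env),
    class = "cvr_env"
  )
}

#' Resting heart rate under environmental strain
#'
#' The modulated resting cardiac output divided by the modulated resting
#' stroke volume, with the explicit L-to-mL conversion. Always at or
#' above the basic resting heart rate for non-negative strain, because
#' resting cardiac output rises much faster with heat than resting
#' stroke volume does.
#'
#' @param env A [modulate_cardio()] object.
#' @return Resting heart rate, beats·min^-1.
#' @export
resting_hr_env <- function(env) {
  stopifnot(inherits(env, "cvr_env"))
  if (env$sv_rest_env <= 0)
    stop("modulated resting stroke volume must be positive", call. = FALSE)
  env$co_rest_env / env$sv_rest_env * 1000
}

#' Cardiac reserve fraction under heat and altitude
#'
#' The fraction of the cardiac reserve consumed by a workload once heat
#' has lowered the maximal cardiac output and altitude has raised the
#' required cardiac output. The basic resting cardiac output appears in
#' both numerator and denominator - deliberately not the heat-modulated
#' resting value - so that at zero strain and sea level the fraction
#' reduces exactly to the oxygen-uptake reserve fraction. Values above 1
#' denote unsustainable demand and are returned unclamped.
#'
#' @param basic A [basic_cardio()] object.
#' @param env A [modulate_cardio()] object.
#' @param co_altitude Required cardiac output at the current altitude and
#'   workload, L·min^-1; see [cardiac_output_at_altitude()].
#' @return Dimensionless reserve fraction.
#' @export
reserve_fraction_env <- function(basic, env, co_altitude) {
  stopifnot(inherits(basic, "cvr_basic"), inherits(env, "cvr_env"))
  denom <- env$co_max_env - basic$co_rest
  if (denom <= 0)
    stop("modulated maximal cardiac output does not exceed resting ",
         "cardiac output; strain outside model domain", call. = FALSE)
  (co_altitude - basic$co_rest) / denom
}

#' Exercise response under heat, dehydration and altitude
#'
#' Heart rate interpolates linearly from the strain-elevated resting
#' value to the unmodulated maximum; cardiac output from the
#' strain-elevated resting value to the strain-lowered maximum; stroke
#' volume follows from the cardiac-output principle. At fixed absolute
#' uptake, rising strain therefore raises heart rate (cardiovascular
#' drift) while squeezing stroke volume.
#'
#' @param basic A [basic_cardio()] object.
#' @param env A [modulate_cardio()] object.
#' @param fraction Cardiac reserve fraction (>= 0); see
#'   [reserve_fraction_env()].
#' @return A list with components `hr` (beats·min^-1), `co` (L·min^-1)
#'   and `sv` (mL·beat^-1). Vectorised over `fraction`.
#' @export
exercise_response_env <- function(basic, env, fraction) {
  stopifnot(inherits(basic, "cvr_basic"), inherits(env, "cvr_env"))
  if (any(fraction < 0)) stop("'fraction' must be >= 0", call. = FALSE)
  hr <- (basic$hr_max - env$hr_rest_env) * fraction + env$hr_rest_env
  co <- (env$co_max_env - env$co_rest_env) * fraction + env$co_rest_env
  list(hr = hr, co = co, sv = co / hr * 1000)
}

#' Environment-limited maximal oxygen uptake
#'
#' The Fick product of the altitude-attenuated maximal extraction and the
#' heat-attenuated maximal cardiac output. Neither reduction is
#' compensated by maximal heart rate, so their product bounds aerobic
#' capacity in the environment.
#'
#' @param basic A [basic_cardio()] object.
#' @param env A [modulate_cardio()] object.
#' @param km Altitude, km; defaults to the altitude stored in `env`.
#' @return Maximal oxygen uptake in the environment, L·min^-1.
#' @export
vo2max_env <- function(basic, env, km = env$km) {
  stopifnot(inherits(basic, "cvr_basic"), inherits(env, "cvr_env"))
  (1 - altitude_attenuation(km)) * basic$avo2diff_max * env$co_max_env
}
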