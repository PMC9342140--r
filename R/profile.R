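#' Create an individual profile
#'
#' Bundles the immutable anthropometric and fitness characteristics of one
#' simulated person. These are the only per-individual inputs the model
#' needs: everything else is derived.
#'
#' @param age Age in years (> 0).
#' @param mass Body mass in kg (> 0), measured pre-exposure.
#' @param height Stature in cm (> 0).
#' @param sex `"male"` or `"female"`; selects the sex-specific constant of
#'   the resting energy-expenditure equation.
#' @param vo2max Baseline (sea-level, thermoneutral, euhydrated) maximal
#'   oxygen uptake in L·min^-1 (> 0).
#' @param rer Respiratory exchange ratio used when converting resting
#'   energy expenditure to oxygen uptake; dimensionless, in \[0.7, 1\].
#'   Default 0.7, the resting fat-dominant value.
#'
#' @return An object of class `cvr_profile`.
#' @examples
#' cvr_profile(age = 25, mass = 75, height = 175, sex = "male", vo2max = 4.0)
#' @export
cvr_profile <- function(age, mass, height, sex = c("male", "female"),
                        vo2max, rer = 0.7) {
  sex <- match.arg(sex)
  for (nm in c("age", "mass", "height", "vo2max", "rer")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (age <= 0) stop("'age' must be positive", call. = FALSE)
  if (mass <= 0) stop("'mass' must be positive", call. = FALSE)
  if (height <= 0) stop("'height' must be positive", call. = FALSE)
  if (vo2max <= 0) stop("'vo2max' must be positive", call. = FALSE)
  if (rer < 0.7 || rer > 1)
    stop("'rer' must lie in [0.7, 1]", call. = FALSE)
  structure(
    list(age = age, mass = mass, height = height, sex = sex,
         vo2max = vo2max, rer = rer),
    class = "cvr_profile"
  )
}

#' @export
print.cvr_profile <- function(x, ...) {
  cat("Individual profile\n")
  cat(sprintf("  %s, %g yr, %g kg, %g cm\n", x$sex, x$age, x$mass, x$height))
  cat(sprintf("  VO2max %g L/min (%.1f mL/kg/min), RER %g\n",
              x$vo2max, x$vo2max / x$mass * 1000, x$rer))
  invisible(x)
}

#' Read an individual profile from a YAML file
#'
#' Expects top-level keys `age`, `mass`, `height`, `sex`, `vo2max` and
#' optionally `rer`, with the units of [cvr_profile()].
#'
#' @param path Path to a YAML file.
#' @return A `cvr_profile`.
#' @export
read_profile <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("age", "mass", "height", "sex", "vo2max")
  miss <- setdiff(need, names(y))
  if (length(miss))
    stop("profile file is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cvr_profile(age = y$age, mass = y$mass, height = y$height, sex = y$sex,
              vo2max = y$vo2max, rer = if (is.null(y$rer)) 0.7 else y$rer)
}

#' Resting oxygen uptake from anthropometrics
#'
#' Estimates resting energy expenditure with the Mifflin-St Jeor equation
#' (kcal·day^-1) and converts it to oxygen uptake (L·min^-1) by dividing by
#' 1440 min·day^-1 and an oxygen energy equivalent.
#'
#' Two energy-equivalent conventions are supported. The default, `"weir"`,
#' uses the Weir form 3.941 + 1.106·RER kcal·L^-1, giving a physiologically
#' typical resting uptake of roughly 0.25 L·min^-1 for a 75-kg adult male.
#' `"literal"` divides by 5.05·RER instead, an alternative reading of the
#' same conversion that yields a substantially higher resting uptake; it is
#' retained so either convention can be reproduced explicitly.
#'
#' @param profile A [cvr_profile()].
#' @param divisor `"weir"` (default) or `"literal"`; see Details.
#' @return Resting oxygen uptake, L·min^-1.
#' @examples
#' p <- cvr_profile(25, 75, 175, "male", 4.0)
#' resting_vo2(p)
#' @export
resting_vo2 <- function(profile, divisor = c("weir", "literal")) {
  stopifnot(inherits(profile, "cvr_profile"))
  divisor <- match.arg(divisor)
  ree <- mifflin_st_jeor(profile$mass, profile$height, profile$age,
                         profile$sex)
  kcal_per_L <- switch(divisor,
    weir = 3.941 + 1.106 * profile$rer,
    literal = 5.05 * profile$rer
  )
  ree / 1440 / kcal_per_L
}

# Mifflin-St Jeor resting energy expenditure, kcal/day.
mifflin_st_jeor <- function(mass, height, age, sex) {
  base <- 10 * mass + 6.25 * height - 5 * age
  base + if (sex == "male") 5 else -161
}

#' Maximal stroke volume from maximal oxygen uptake
#'
#' Linear relation between absolute maximal oxygen uptake and maximal
#' stroke volume, pooled over heterogeneous adult groups. Absolute (not
#' mass-relative) uptake is the predictor because maximal stroke volume
#' scales with body size as well as fitness.
#'
#' @param vo2max Maximal oxygen uptake, L·min^-1 (>= 0; zero is allowed as
#'   an analytic probe of the intercept).
#' @return Maximal stroke volume, mL·beat^-1.
#' @examples
#' max_stroke_volume(4.0)
#' @export
max_stroke_volume <- function(vo2max) {
  if (any(vo2max < 0)) stop("'vo2max' must be non-negative", call. = FALSE)
  40.59 + 24.81 * vo2max
}

#' Resting stroke volume
#'
#' A fixed population-mean value is used because resting stroke volume
#' shows no usable relation with fitness across pooled study groups.
#'
#' @return Resting stroke volume, 85.1 mL·beat^-1, for every individual.
#' @export
resting_stroke_volume <- function() 85.1

#' Maximal heart rate from age
#'
#' @param age Age in years (>= 0; zero probes the intercept).
#' @return Maximal heart rate, beats·min^-1, decreasing 0.7 beats per year.
#' @examples
#' max_heart_rate(25)
#' @export
max_heart_rate <- function(age) {
  if (any(age < 0)) stop("'age' must be non-negative", call. = FALSE)
  208 - 0.7 * age
}

#' Resting heart rate from relative fitness
#'
#' The predictor is mass-relative maximal oxygen uptake in
#' mL·kg^-1·min^-1; the conversion from the absolute value lives here.
#' The intercept is exposed because an alternative calibration raises it
#' by 10 beats·min^-1 (see [heat_sensitivities()]).
#'
#' @param vo2max Maximal oxygen uptake, L·min^-1 (>= 0).
#' @param mass Body mass, kg (> 0).
#' @param intercept Regression intercept, beats·min^-1 (default 90.93).
#' @return Resting heart rate, beats·min^-1.
#' @examples
#' resting_heart_rate(4.0, 75)
#' @export
resting_heart_rate <- function(vo2max, mass, intercept = 90.93) {
  if (any(vo2max < 0)) stop("'vo2max' must be non-negative", call. = FALSE)
  if (any(mass <= 0)) stop("'mass' must be positive", call. = FALSE)
  intercept - 0.64 * (vo2max / mass * 1000)
}

#' Derive the basic (environment-independent) cardiovascular constants
#'
#' Chains the resting/maximal stroke-volume and heart-rate relations into
#' resting and maximal cardiac output, and closes the Fick principle to
#' obtain resting and maximal whole-body arteriovenous oxygen difference.
#' "Basic" means not yet modulated for heat, dehydration or altitude.
#'
#' @param profile A [cvr_profile()].
#' @param divisor Resting-uptake energy-equivalent convention, passed to
#'   [resting_vo2()].
#' @param hr_rest_intercept Intercept of the resting heart-rate relation,
#'   beats·min^-1.
#' @return An object of class `cvr_basic` with fields `vo2rest`, `vo2max`
#'   (L·min^-1), `sv_rest`, `sv_max` (mL·beat^-1), `hr_rest`, `hr_max`
#'   (beats·min^-1), `co_rest`, `co_max` (L·min^-1), `avo2diff_rest`,
#'   `avo2diff_max` (L O2 per L blood).
#' @examples
#' basic_cardio(cvr_profile(25, 75, 175, "male", 4.0))
#' @export
basic_cardio <- function(profile, divisor = c("weir", "literal"),
                         hr_rest_intercept = 90.93) {
  stopifnot(inherits(profile, "cvr_profile"))
  vo2rest <- resting_vo2(profile, divisor)
  if (vo2rest >= profile$vo2max)
    stop("resting oxygen uptake (", signif(vo2rest, 4),
         ") is not below vo2max; profile outside model domain",
         call. = FALSE)
  sv_max <- max_stroke_volume(profile$vo2max)
  sv_rest <- resting_stroke_volume()
  hr_max <- max_heart_rate(profile$age)
  hr_rest <- resting_heart_rate(profile$vo2max, profile$mass,
                                hr_rest_intercept)
  if (hr_rest >= hr_max)
    stop("resting heart rate (", signif(hr_rest, 4),
         ") is not below maximal heart rate (", signif(hr_max, 4),
         "); age/fitness combination outside model domain", call. = FALSE)
  co_max <- sv_max / 1000 * hr_max
  co_rest <- sv_rest / 1000 * hr_rest
  structure(
    list(
      vo2rest = vo2rest, vo2max = profile$vo2max,
      sv_rest = sv_rest, sv_max = sv_max,
      hr_rest = hr_rest, hr_max = hr_max,
      co_rest = co_rest, co_max = co_max,
      avo2diff_rest = vo2rest / co_rest,
      avo2diff_max = profile$vo2max / co_max
    ),
    class = "cvr_basic"
  )
}

#' @export
print.cvr_basic <- function(x, ...) {
  cat("Basic cardiovascular constants (no environmental modulation)\n")
  cat(sprintf("  VO2:  rest %.4f  max %.3f L/min\n", x$vo2rest, x$vo2max))
  cat(sprintf("  SV:   rest %.1f   max %.1f mL/beat\n", x$sv_rest, x$sv_max))
  cat(sprintf("  HR:   rest %.1f   max %.1f beats/min\n", x$hr_rest, x$hr_max))
  cat(sprintf("  CO:   rest %.2f   max %.2f L/min\n", x$co_rest, x$co_max))
  cat(sprintf("  AVO2diff: rest %.4f  max %.4f L/L\n",
              x$avo2diff_rest, x$avo2diff_max))
  invisible(x)
}

#' Workload as a fraction of the oxygen-uptake reserve
#'
#' Expresses an absolute oxygen uptake as its position between resting
#' uptake (0) and maximal uptake (1). Values above 1 denote supramaximal
#' demand; they are returned unclamped and adjudicated downstream by the
#' feasibility check.
#'
#' @param vo2 Oxygen uptake, L·min^-1 (>= resting uptake).
#' @param basic A [basic_cardio()] object.
#' @return Dimensionless reserve fraction.
#' @export
vo2_reserve_fraction <- function(vo2, basic) {
  stopifnot(inherits(basic, "cvr_basic"))
  if (any(vo2 < basic$vo2rest - 1e-12))
    stop("'vo2' below resting uptake: sub-resting workload is undefined",
         call. = FALSE)
  (vo2 - basic$vo2rest) / (basic$vo2max - basic$vo2rest)
}

#' Basic graded-exercise response
#'
#' Heart rate and cardiac output rise linearly with the reserve fraction
#' between their resting and maximal values; stroke volume follows from
#' the cardiac-output principle SV = CO/HR·1000 and is therefore
#' deliberately nonlinear.
#'
#' @param basic A [basic_cardio()] object.
#' @param fraction Oxygen-uptake reserve fraction (>= 0); see
#'   [vo2_reserve_fraction()].
#' @return A list with components `hr` (beats·min^-1), `co` (L·min^-1)
#'   and `sv` (mL·beat^-1). Vectorised over `fraction`.
#' @examples
#' b <- basic_cardio(cvr_profile(25, 75, 175, "male", 4.0))
#' basic_response(b, c(0, 0.5, 1))
#' @export
basic_response <- function(basic, fraction) {
  stopifnot(inherits(basic, "cvr_basic"))
  if (any(fraction < 0)) stop("'fraction' must be >= 0", call. = FALSE)
  hr <- (basic$hr_max - basic$hr_rest) * fraction + basic$hr_rest
  co <- (basic$co_max - basic$co_rest) * fraction + basic$co_rest
  list(hr = hr, co = co, sv = co / hr * 1000)
}
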