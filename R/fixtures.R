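#' Reference profile for graded-test simulations
#'
#' The simulated individuals of the graded-test figures: 25 years, 75 kg,
#' 175 cm, male, with a maximal oxygen uptake of 4.0 L·min^-1 ("fit") or
#' 2.5 L·min^-1 ("unfit").
#'
#' @param fit_level `"fit"` or `"unfit"`.
#' @return A [cvr_profile()].
#' @export
graded_test_profile <- function(fit_level = c("fit", "unfit")) {
  fit_level <- match.arg(fit_level)
  cvr_profile(age = 25, mass = 75, height = 175, sex = "male",
              vo2max = if (fit_level == "fit") 4.0 else 2.5)
}

#' Graded exercise test scenario
#'
#' A rest row followed by exercise at 20% to 100% of baseline maximal
#' oxygen uptake in steps of 10% per 2 minutes, under a constant
#' environment preset: `"thermoneutral"` and `"sea_level"` are mean body
#' temperature 36.6 degC with 0.25 kg mass loss at 0 km; `"heated"` is
#' 39 degC with 1.5 kg mass loss at 0 km; `"high_altitude"` is the
#' thermoneutral state at 5 km. The environment applies to every row,
#' including rest (resting in the heat is passive heat strain).
#'
#' @param fit_level `"fit"` or `"unfit"` (selects the matching
#'   [graded_test_profile()]; the scenario itself is profile-free).
#' @param environment One of `"thermoneutral"`, `"heated"`,
#'   `"sea_level"`, `"high_altitude"`.
#' @return A 10-row scenario data frame for [simulate_cvr()].
#' @examples
#' fixture_graded_test("fit", "heated")
#' @export
fixture_graded_test <- function(fit_level = c("fit", "unfit"),
                                environment = c("thermoneutral", "heated",
                                                "sea_level",
                                                "high_altitude")) {
  fit_level <- match.arg(fit_level)
  environment <- match.arg(environment)
  env <- switch(environment,
    thermoneutral = list(t_body = 36.6, loss = 0.25, km = 0),
    sea_level = list(t_body = 36.6, loss = 0.25, km = 0),
    heated = list(t_body = 39.0, loss = 1.5, km = 0),
    high_altitude = list(t_body = 36.6, loss = 0.25, km = 5)
  )
  frac <- seq(0.2, 1.0, by = 0.1)
  data.frame(
    time_min = c(0, seq(2, by = 2, length.out = length(frac))),
    phase = c("rest", rep("exercise", length(frac))),
    frac_vo2max = c(NA, frac),
    t_body_C = env$t_body,
    altitude_km = env$km,
    mass_loss_kg = env$loss,
    stringsAsFactors = FALSE
  )
}

ramp <- function(from, to, n) if (n == 1) to else seq(from, to, length.out = n)

rest_exercise_rows <- function(rest_min, blocks, step_min) {
  # blocks: list of list(duration, frac or vo2)
  times <- seq(0, rest_min, by = step_min)
  phase <- rep("rest", length(times))
  frac <- rep(NA_real_, length(times))
  t0 <- rest_min
  for (b in blocks) {
    bt <- seq(t0 + step_min, t0 + b$duration, by = step_min)
    times <- c(times, bt)
    phase <- c(phase, rep("exercise", length(bt)))
    frac <- c(frac, rep(b$frac, length(bt)))
    t0 <- t0 + b$duration
  }
  data.frame(time_min = times, phase = phase, frac_vo2max = frac,
             stringsAsFactors = FALSE)
}

#' Rest-plus-exercise protocol skeletons
#'
#' Scenario skeletons mirroring common validation protocols: 30 minutes
#' of seated rest in the experimental climate followed by 60 minutes of
#' exercise, sampled every 5 minutes. Thermal trajectories are linear
#' ramps over the exercise period (rest rows hold the starting values)
#' and cumulative mass loss accrues linearly over exercise time only -
#' simple but physiologically shaped defaults for harness testing, not
#' measured traces.
#'
#' Protocols:
#' \describe{
#'   \item{fixed_load_heat}{60 min of fixed low-intensity work (default
#'     1.0 L·min^-1, roughly 60 W cycling) in a warm-humid climate.}
#'   \item{graded_climates}{30 min at 25% then 30 min at 45% of maximal
#'     uptake; `climate` selects cool / warm-humid / hot-dry thermal
#'     ramps.}
#'   \item{altitude_absolute}{30 min at 35% then 30 min at 50% of
#'     baseline (sea-level) maximal uptake at 4 km - the equivalent
#'     altitude of breathing 12.7% oxygen - in a cool climate.}
#'   \item{altitude_relative}{the same rows, intended to be run with
#'     `cvr_config(workload_relative = "environment")` so the fractions
#'     are taken of the altitude-reduced maximum.}
#' }
#'
#' @param protocol One of `"fixed_load_heat"`, `"graded_climates"`,
#'   `"altitude_absolute"`, `"altitude_relative"`.
#' @param climate For `graded_climates`: `"warm_humid"` (default),
#'   `"cool"` or `"hot_dry"`.
#' @param vo2_fixed Absolute workload for `fixed_load_heat`, L·min^-1.
#' @param total_mass_loss_kg Body mass lost over the full exercise
#'   period, kg; overrides the protocol default.
#' @return A scenario data frame for [simulate_cvr()].
#' @examples
#' head(fixture_rest_exercise("fixed_load_heat"))
#' @export
fixture_rest_exercise <- function(protocol = c("fixed_load_heat",
                                               "graded_climates",
                                               "altitude_absolute",
                                               "altitude_relative"),
                                  climate = c("warm_humid", "cool",
                                              "hot_dry"),
                                  vo2_fixed = 1.0,
                                  total_mass_loss_kg = NULL) {
  protocol <- match.arg(protocol)
  climate <- match.arg(climate)
  step <- 5
  clim <- switch(climate,
    cool = list(t_skin = 31.0, t_core0 = 36.8, t_core1 = 37.4,
                loss = 0.3),
    warm_humid = list(t_skin = 35.0, t_core0 = 36.8, t_core1 = 38.0,
                      loss = 1.0),
    hot_dry = list(t_skin = 36.0, t_core0 = 36.8, t_core1 = 38.3,
                   loss = 1.2)
  )
  if (protocol %in% c("altitude_absolute", "altitude_relative"))
    clim <- list(t_skin = 31.0, t_core0 = 36.8, t_core1 = 37.4,
                 loss = 0.5)
  if (!is.null(total_mass_loss_kg)) clim$loss <- total_mass_loss_kg

  blocks <- switch(protocol,
    fixed_load_heat = list(list(duration = 60, frac = NA_real_)),
    graded_climates = list(list(duration = 30, frac = 0.25),
                           list(duration = 30, frac = 0.45)),
    altitude_absolute = ,
    altitude_relative = list(list(duration = 30, frac = 0.35),
                             list(duration = 30, frac = 0.50))
  )
  sc <- rest_exercise_rows(30, blocks, step)
  ex <- sc$phase == "exercise"
  elapsed <- ifelse(ex, sc$time_min - 30, 0)
  total_ex <- sum(vapply(blocks, `[[`, numeric(1), "duration"))
  sc$t_core_C <- clim$t_core0
  sc$t_core_C[ex] <- clim$t_core0 +
    (clim$t_core1 - clim$t_core0) * elapsed[ex] / total_ex
  sc$t_skin_C <- clim$t_skin
  sc$altitude_km <- if (protocol %in% c("altitude_absolute",
                                        "altitude_relative")) 4 else 0
  sc$mass_loss_kg <- pmin(elapsed / total_ex, 1) * clim$loss
  if (protocol == "fixed_load_heat") {
    sc$vo2_L_min <- ifelse(ex, vo2_fixed, NA_real_)
    sc$frac_vo2max <- NULL
  }
  attr(sc, "workload_relative") <-
    if (protocol == "altitude_relative") "environment" else "basic"
  sc
}
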