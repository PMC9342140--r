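#' Adjudicate whether a workload is aerobically sustainable
#'
#' Violations are evaluated in a fixed order - required oxygen uptake
#' against the environment-limited maximum, predicted heart rate against
#' the physiological maximum, then any user-supplied heart-rate and
#' body-temperature ceilings, then domain integrity - and the first
#' violation names the limiting factor. Comparisons use a relative
#' tolerance of 1e-9 so exact boundary workloads remain feasible.
#'
#' @param required_vo2 Oxygen uptake demanded by the task, L·min^-1.
#' @param vo2max_env Environment-limited maximal oxygen uptake,
#'   L·min^-1.
#' @param predicted_hr Predicted heart rate, beats·min^-1.
#' @param hr_max Maximal heart rate, beats·min^-1.
#' @param hr_ceiling Optional user heart-rate ceiling, beats·min^-1.
#' @param t_body Mean body temperature, degC (only used with a ceiling).
#' @param t_body_ceiling Optional body-temperature ceiling, degC.
#' @param domain_ok Logical; `FALSE` marks an out-of-domain state such as
#'   a non-positive muscle blood flow.
#' @return A list with `feasible` (logical) and `limiting` (one of
#'   `"none"`, `"vo2max_exceeded"`, `"hr_ceiling"`,
#'   `"domain_violation"`).
#' @export
check_feasibility <- function(required_vo2, vo2max_env, predicted_hr,
                              hr_max, hr_ceiling = NULL, t_body = NULL,
                              t_body_ceiling = NULL, domain_ok = TRUE) {
  if (any(c(required_vo2, vo2max_env, predicted_hr, hr_max) <= 0))
    stop("feasibility inputs must be positive", call. = FALSE)
  tol <- 1e-9
  exceeds <- function(x, limit) x > limit * (1 + tol)
  limiting <- "none"
  if (exceeds(required_vo2, vo2max_env)) {
    limiting <- "vo2max_exceeded"
  } else if (exceeds(predicted_hr, hr_max)) {
    limiting <- "hr_ceiling"
  } else if (!is.null(hr_ceiling) && exceeds(predicted_hr, hr_ceiling)) {
    limiting <- "hr_ceiling"
  } else if (!is.null(t_body_ceiling) && !is.null(t_body) &&
             exceeds(t_body, t_body_ceiling)) {
    limiting <- "t_body_ceiling"
  } else if (!isTRUE(domain_ok)) {
    limiting <- "domain_violation"
  }
  list(feasible = limiting == "none", limiting = limiting)
}

scenario_columns <- c("time_min", "phase", "vo2_L_min", "frac_vo2max",
                      "t_core_C", "t_skin_C", "t_body_C", "altitude_km",
                      "mass_loss_kg", "dehydration_pct")

validate_scenario <- function(scenario) {
  if (!is.data.frame(scenario))
    stop("scenario must be a data frame", call. = FALSE)
  for (nm in c("time_min", "phase"))
    if (!nm %in% names(scenario))
      stop("scenario is missing mandatory column '", nm, "'", call. = FALSE)
  if (!any(c("vo2_L_min", "frac_vo2max") %in% names(scenario)))
    stop("scenario needs a workload column: 'vo2_L_min' or 'frac_vo2max'",
         call. = FALSE)
  if (nrow(scenario) == 0) stop("scenario has no rows", call. = FALSE)
  if (!is.numeric(scenario$time_min) || anyNA(scenario$time_min))
    stop("'time_min' must be numeric and complete", call. = FALSE)
  if (any(diff(scenario$time_min) <= 0))
    stop("'time_min' must be strictly increasing (first violation at row ",
         which(diff(scenario$time_min) <= 0)[1] + 1, ")", call. = FALSE)
  bad <- !scenario$phase %in% c("rest", "exercise")
  if (any(bad))
    stop("'phase' must be 'rest' or 'exercise' (row ", which(bad)[1], ")",
         call. = FALSE)
  num_cols <- intersect(setdiff(scenario_columns, c("time_min", "phase")),
                        names(scenario))
  for (nm in num_cols)
    if (!is.numeric(scenario[[nm]]))
      stop("column '", nm, "' must be numeric", call. = FALSE)
  if (all(c("vo2_L_min", "frac_vo2max") %in% names(scenario))) {
    both <- !is.na(scenario$vo2_L_min) & !is.na(scenario$frac_vo2max)
    if (any(both))
      stop("row ", which(both)[1],
           " sets both 'vo2_L_min' and 'frac_vo2max'; the workload ",
           "columns are mutually exclusive", call. = FALSE)
  }
  if ("altitude_km" %in% names(scenario)) {
    km <- scenario$altitude_km
    out <- !is.na(km) & (km < 0 | km > 8)
    if (any(out))
      stop("row ", which(out)[1], ": altitude ", km[which(out)[1]],
           " km is outside the supported 0-8 km range", call. = FALSE)
  }
  invisible(scenario)
}

scenario_col <- function(scenario, nm, default = NA_real_) {
  if (nm %in% names(scenario)) scenario[[nm]] else
    rep(default, nrow(scenario))
}

#' Simulate a cardiovascular scenario time series
#'
#' Evaluates the model at every row of a scenario table. The model is
#' algebraic and memoryless: each row is evaluated independently from
#' its own workload, thermal, hydration and altitude state, and
#' identical inputs give identical outputs. Rows are never truncated at
#' task failure; every row is computed unclamped and flagged, and the
#' summary reports the first failure time, preserving the full
#' diagnostic trace.
#'
#' Scenario columns (units as named): `time_min` and `phase`
#' (`"rest"`/`"exercise"`) are mandatory; workload is `vo2_L_min`
#' (absolute) or `frac_vo2max` (fractional, interpretation set by the
#' config), mutually exclusive per row and ignored on rest rows; thermal
#' state is `t_body_C`, or `t_core_C` plus `t_skin_C` (the direct mean
#' body temperature wins if both are given); hydration is
#' `dehydration_pct`, or cumulative `mass_loss_kg` converted with the
#' profile mass; `altitude_km` defaults to 0. Missing thermal columns
#' mean thermoneutral.
#'
#' @param profile A [cvr_profile()].
#' @param scenario A scenario data frame, e.g. from [read_scenario()],
#'   [fixture_graded_test()] or [fixture_rest_exercise()].
#' @param config A [cvr_config()].
#' @return An object of class `cvr_simulation`: a list with
#'   `predictions` (one row per scenario row: workload, strain index,
#'   heart rate, stroke volume, cardiac output, whole-body extraction,
#'   environment-limited maximal uptake, regional flows, feasibility),
#'   `summary` (`first_failure_time_min`, `limiting_factor`), `profile`,
#'   `basic` and `config`.
#' @examples
#' p <- cvr_profile(25, 75, 175, "male", 4.0)
#' sim <- simulate_cvr(p, fixture_graded_test("fit", "heated"))
#' sim$predictions[, c("time_min", "hr_bpm", "co_L_min", "sv_mL")]
#' @export
simulate_cvr <- function(profile, scenario, config = cvr_config()) {
  stopifnot(inherits(profile, "cvr_profile"),
            inherits(config, "cvr_config"))
  validate_scenario(scenario)
  basic <- basic_cardio(profile, divisor = config$vo2rest_divisor,
                        hr_rest_intercept =
                          heat_sensitivities(config$calibration)$hr_rest_intercept)
  n <- nrow(scenario)
  t_core <- scenario_col(scenario, "t_core_C")
  t_skin <- scenario_col(scenario, "t_skin_C")
  t_body_direct <- scenario_col(scenario, "t_body_C")
  km <- scenario_col(scenario, "altitude_km", 0)
  km[is.na(km)] <- 0
  mass_loss <- scenario_col(scenario, "mass_loss_kg")
  dehyd_col <- scenario_col(scenario, "dehydration_pct")
  vo2_col <- scenario_col(scenario, "vo2_L_min")
  frac_col <- scenario_col(scenario, "frac_vo2max")

  out <- vector("list", n)
  for (i in seq_len(n)) {
    t_body <- if (!is.na(t_body_direct[i])) t_body_direct[i]
      else if (!is.na(t_core[i]) && !is.na(t_skin[i]))
        0.2 * t_skin[i] + 0.8 * t_core[i]
      else 36.54
    dehyd <- if (!is.na(dehyd_col[i])) dehyd_col[i]
      else if (!is.na(mass_loss[i])) mass_loss[i] / profile$mass * 100
      else 0
    strain <- chsi_index(dehyd, max(0, t_body - 36.54),
                         config$chsi_variant)
    env <- modulate_cardio(basic, strain, km = km[i],
                           calibration = config$calibration)
    vo2 <- if (scenario$phase[i] == "rest") {
      basic$vo2rest
    } else if (!is.na(vo2_col[i])) {
      vo2_col[i]
    } else if (!is.na(frac_col[i])) {
      ref <- if (config$workload_relative == "basic") basic$vo2max
             else env$vo2max_env
      frac_col[i] * ref
    } else {
      stop("row ", i, ": exercise row has no resolvable workload",
           call. = FALSE)
    }
    if (vo2 < basic$vo2rest - 1e-12)
      stop("row ", i, ": workload resolves to ", signif(vo2, 4),
           " L/min, below resting uptake", call. = FALSE)
    co_alt <- cardiac_output_at_altitude(basic, vo2, km[i])
    frac_env <- reserve_fraction_env(basic, env, co_alt)
    resp <- exercise_response_env(basic, env, frac_env)
    bf <- partition_blood_flow(resp$co, env$co_max_env, basic$co_rest,
                               co_alt, vo2, basic$vo2rest)
    feas <- check_feasibility(vo2, env$vo2max_env, resp$hr, basic$hr_max,
                              hr_ceiling = config$hr_ceiling,
                              t_body = t_body,
                              t_body_ceiling = config$t_body_ceiling,
                              domain_ok = bf$domain_ok && env$domain_ok)
    out[[i]] <- data.frame(
      time_min = scenario$time_min[i], phase = scenario$phase[i],
      vo2_L_min = vo2, t_body_C = t_body, dehydration_pct = dehyd,
      altitude_km = km[i], chsi = strain,
      hr_bpm = resp$hr, sv_mL = resp$sv, co_L_min = resp$co,
      avo2diff = vo2 / resp$co,
      reserve_fraction = frac_env,
      vo2max_env_L_min = env$vo2max_env,
      core_bf_L_min = bf$core_bf, skin_bf_L_min = bf$skin_bf,
      muscle_bf_L_min = bf$muscle_bf,
      active_muscle_avo2diff = bf$active_muscle_avo2diff,
      domain_ok = bf$domain_ok && env$domain_ok,
      feasible = feas$feasible, limiting = feas$limiting,
      stringsAsFactors = FALSE
    )
  }
  predictions <- do.call(rbind, out)
  rownames(predictions) <- NULL
  failed <- which(!predictions$feasible)
  summary <- if (length(failed)) {
    list(first_failure_time_min = predictions$time_min[failed[1]],
         limiting_factor = predictions$limiting[failed[1]])
  } else {
    list(first_failure_time_min = NA_real_, limiting_factor = "none")
  }
  structure(
    list(predictions = predictions, summary = summary,
         profile = profile, basic = basic, config = config),
    class = "cvr_simulation"
  )
}

#' @export
print.cvr_simulation <- function(x, ...) {
  p <- x$predictions
  cat(sprintf("Cardiovascular simulation: %d rows, %.0f-%.0f min\n",
              nrow(p), min(p$time_min), max(p$time_min)))
  cat(sprintf("  HR %.0f-%.0f beats/min, CO %.1f-%.1f L/min\n",
              min(p$hr_bpm), max(p$hr_bpm), min(p$co_L_min),
              max(p$co_L_min)))
  if (is.na(x$summary$first_failure_time_min)) {
    cat("  all rows feasible\n")
  } else {
    cat(sprintf("  first task failure at %g min (%s)\n",
                x$summary$first_failure_time_min,
                x$summary$limiting_factor))
  }
  invisible(x)
}

#' Quick-look plot of a simulation
#'
#' Base-graphics traces of heart rate, cardiac output and stroke volume,
#' and the regional flow partition over time.
#'
#' @param x A [simulate_cvr()] result.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.cvr_simulation <- function(x, ...) {
  p <- x$predictions
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(p$time_min, p$hr_bpm, type = "b", xlab = "time (min)",
       ylab = "HR (beats/min)", main = "Heart rate")
  plot(p$time_min, p$co_L_min, type = "b", xlab = "time (min)",
       ylab = "CO (L/min)", main = "Cardiac output")
  plot(p$time_min, p$sv_mL, type = "b", xlab = "time (min)",
       ylab = "SV (mL/beat)", main = "Stroke volume")
  ylim <- range(p$core_bf_L_min, p$skin_bf_L_min, p$muscle_bf_L_min)
  plot(p$time_min, p$muscle_bf_L_min, type = "b", ylim = ylim,
       xlab = "time (min)", ylab = "flow (L/min)",
       main = "Regional flows")
  graphics::lines(p$time_min, p$core_bf_L_min, type = "b", lty = 2)
  graphics::lines(p$time_min, p$skin_bf_L_min, type = "b", lty = 3)
  graphics::legend("topleft", c("muscle", "core", "skin"),
                   lty = 1:3, bty = "n")
  invisible(x)
}
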