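#' Simulation configuration
#'
#' Collects the numeric and structural options of a simulation run.
#'
#' @param chsi_variant Heat strain index variant, `"additive"` (default)
#'   or `"synergistic"`; see [chsi()].
#' @param vo2rest_divisor Energy-equivalent convention for resting oxygen
#'   uptake, `"weir"` (default) or `"literal"`; see [resting_vo2()].
#' @param calibration Heat sensitivity preset, `"published"` (default) or
#'   `"adjusted"`; see [heat_sensitivities()].
#' @param workload_relative How fractional workloads are interpreted:
#'   `"basic"` (default) as fractions of the baseline maximal oxygen
#'   uptake, or `"environment"` as fractions of the environment-limited
#'   maximum (relative-workload protocols at altitude).
#' @param hr_ceiling Optional user heart-rate ceiling, beats·min^-1,
#'   applied after the physiological limits in the feasibility check.
#' @param t_body_ceiling Optional mean body-temperature ceiling, degC.
#' @return A list of class `cvr_config`.
#' @export
cvr_config <- function(chsi_variant = c("additive", "synergistic"),
                       vo2rest_divisor = c("weir", "literal"),
                       calibration = c("published", "adjusted"),
                       workload_relative = c("basic", "environment"),
                       hr_ceiling = NULL, t_body_ceiling = NULL) {
  if (!is.null(hr_ceiling) &&
      (!is.numeric(hr_ceiling) || length(hr_ceiling) != 1L || hr_ceiling <= 0))
    stop("'hr_ceiling' must be a single positive number", call. = FALSE)
  if (!is.null(t_body_ceiling) &&
      (!is.numeric(t_body_ceiling) || length(t_body_ceiling) != 1L))
    stop("'t_body_ceiling' must be a single number", call. = FALSE)
  structure(
    list(chsi_variant = match.arg(chsi_variant),
         vo2rest_divisor = match.arg(vo2rest_divisor),
         calibration = match.arg(calibration),
         workload_relative = match.arg(workload_relative),
         hr_ceiling = hr_ceiling,
         t_body_ceiling = t_body_ceiling),
    class = "cvr_config"
  )
}
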