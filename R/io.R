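#' Read a scenario table from CSV
#'
#' Expects a header row, decimal points and comma separators, with the
#' columns documented in [simulate_cvr()]. Unknown columns are kept but
#' ignored, with a warning. Validation errors name the offending row or
#' column.
#'
#' @param path Path to a CSV file.
#' @return A validated scenario data frame.
#' @export
read_scenario <- function(path) {
  sc <- utils::read.csv(path, stringsAsFactors = FALSE)
  unknown <- setdiff(names(sc), scenario_columns)
  if (length(unknown))
    warning("ignoring unknown scenario column(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  validate_scenario(sc)
  sc
}

#' Write a scenario table to CSV
#'
#' The counterpart of [read_scenario()]; a written scenario reads back
#' equal (round-trip stable).
#'
#' @param scenario A scenario data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  validate_scenario(scenario)
  utils::write.csv(scenario, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write simulation results to CSV
#'
#' Writes the per-timestep prediction table of a [simulate_cvr()] result
#' (or a compatible data frame) with one row per scenario row.
#'
#' @param result A `cvr_simulation` or a data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  df <- if (inherits(result, "cvr_simulation")) result$predictions
        else result
  if (!is.data.frame(df))
    stop("'result' must be a cvr_simulation or a data frame",
         call. = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
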