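#' Regress measured on predicted heart rate
#'
#' Validation harness: ordinary least squares of measured heart rate on
#' model-predicted heart rate, pooled and (optionally) per stratum, as
#' used to benchmark the model against experimental datasets. The
#' measured data are supplied by the user; this package ships none.
#'
#' @param predicted Predicted heart rates, beats·min^-1.
#' @param measured Measured heart rates, beats·min^-1, same length.
#' @param strata Optional vector of stratum labels (e.g. fitness band or
#'   climate); per-stratum fits are added to the pooled fit.
#' @return A data frame with columns `stratum` (`"pooled"` plus any
#'   strata), `slope`, `intercept`, `r_squared` and `n`.
#' @examples
#' pred <- seq(80, 180, by = 10)
#' meas <- 0.76 * pred + 18.8
#' regress_predicted_vs_measured(pred, meas)
#' @export
regress_predicted_vs_measured <- function(predicted, measured,
                                          strata = NULL) {
  if (length(predicted) != length(measured))
    stop("'predicted' and 'measured' must have the same length",
         call. = FALSE)
  if (!is.null(strata) && length(strata) != length(predicted))
    stop("'strata' must match the length of the data", call. = FALSE)
  fit_one <- function(p, m, label) {
    if (length(p) < 3)
      stop("stratum '", label, "' has fewer than 3 pairs", call. = FALSE)
    if (stats::sd(p) == 0 || stats::sd(m) == 0)
      stop("stratum '", label,
           "' has degenerate (zero-variance) data", call. = FALSE)
    fit <- stats::lm(m ~ p)
    # coefficient of determination computed directly so that exact
    # synthetic fits do not trip summary.lm's perfect-fit warning
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum((m - mean(m))^2)
    data.frame(stratum = label,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = r2,
               n = length(p),
               stringsAsFactors = FALSE)
  }
  out <- fit_one(predicted, measured, "pooled")
  if (!is.null(strata)) {
    for (s in unique(strata)) {
      idx <- strata == s
      out <- rbind(out, fit_one(predicted[idx], measured[idx],
                                as.character(s)))
    }
  }
  rownames(out) <- NULL
  out
}
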