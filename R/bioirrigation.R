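# Bioirrigation from inert bromide tracer drawdown in the overlying water.

#' Bioirrigation statistic from start/end bromide concentrations
#'
#' Absolute change in the concentration of the inert tracer sodium bromide
#' in the overlying water over the incubation window:
#' \code{delta = t1 - t0}, optionally corrected by subtracting a
#' faunal-free control drift.  Negative values indicate increased
#' bioirrigation activity (tracer drawn into the sediment by burrow
#' flushing).  No normalisation by duration or water volume is applied by
#' default (the statistic is reported in mg L^-1 over the fixed incubation,
#' conventionally 8 h); set \code{per_hour = TRUE} to divide by
#' \code{duration_h}.
#'
#' @param t0_conc,t1_conc start and end concentrations (mg L^-1, >= 0);
#'   vectors are processed element-wise.
#' @param control_drift optional concentration change of a faunal-free
#'   control (mg L^-1), subtracted when provided.
#' @param duration_h incubation length in hours (> 0; required when
#'   \code{per_hour = TRUE}).
#' @param per_hour report mg L^-1 h^-1 instead of mg L^-1.
#' @return Numeric vector of concentration changes.
#' @examples
#' delta_br(1000, 513.21)            # -486.79
#' delta_br(1000, 900, control_drift = -20)  # -80
#' @export
delta_br <- function(t0_conc, t1_conc, control_drift = NULL,
                     duration_h = 8, per_hour = FALSE) {
  if (any(t0_conc < 0) || any(t1_conc < 0)) {
    stop("concentrations must be non-negative")
  }
  if (any(duration_h <= 0)) stop("duration_h must be positive")
  d <- t1_conc - t0_conc
  if (!is.null(control_drift)) d <- d - control_drift
  if (per_hour) d <- d / duration_h
  d
}

#' Bioirrigation table from a measurement data.frame
#'
#' Applies \code{\link{delta_br}} row-wise to a table with columns
#' \code{aquarium_id, t0_conc, t1_conc} and optionally \code{duration_h}
#' and \code{control_drift}.
#'
#' @param measurements data.frame of tracer measurements.
#' @param per_hour see \code{\link{delta_br}}.
#' @return data.frame: \code{aquarium_id, delta_br_mgL}.
#' @export
delta_br_table <- function(measurements, per_hour = FALSE) {
  stopifnot(is.data.frame(measurements),
            all(c("aquarium_id", "t0_conc", "t1_conc") %in%
                names(measurements)))
  drift <- if ("control_drift" %in% names(measurements)) {
    measurements$control_drift
  } else NULL
  dur <- if ("duration_h" %in% names(measurements)) {
    measurements$duration_h
  } else 8
  data.frame(aquarium_id = measurements$aquarium_id,
             delta_br_mgL = delta_br(measurements$t0_conc,
                                     measurements$t1_conc,
                                     control_drift = drift,
                                     duration_h = dur,
                                     per_hour = per_hour),
             stringsAsFactors = FALSE)
}
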