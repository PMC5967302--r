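# Scalar statistics on signal traces and intensity populations: Fura2
# delta-ratio and basal level, relative peak currents, median-intensity time
# courses, positive fractions, and 2^-ddCt fold changes.

.check_trace <- function(trace) {
  stopifnot(is.data.frame(trace), all(c("t_s", "value") %in% names(trace)))
  if (nrow(trace) < 1L) stop("empty trace", call. = FALSE)
  if (any(diff(trace$t_s) <= 0)) {
    stop("trace times must be strictly increasing", call. = FALSE)
  }
  invisible(trace)
}

#' Agonist-response magnitude of a ratiometric calcium trace
#'
#' The difference between the trace maximum and its value at the reference
#' time (default 60 s from imaging start, resolved to the nearest sample).
#' Non-negative by construction, since the maximum dominates every sample.
#'
#' @param trace Data frame with `t_s`, `value`.
#' @param t_ref Reference time in s (default 60).
#' @return The delta-ratio (dimensionless, >= 0).
#' @examples
#' tr <- generate_fura2_trace(baseline = 1, amplitude = 0.8, onset = 120)
#' delta_ratio(tr)  # 0.8
#' @export
delta_ratio <- function(trace, t_ref = 60) {
  .check_trace(trace)
  if (max(trace$t_s) < t_ref) {
    stop(sprintf("trace ends at %g s, before the %g-s reference time",
                 max(trace$t_s), t_ref), call. = FALSE)
  }
  ref <- trace$value[which.min(abs(trace$t_s - t_ref))]
  max(trace$value) - ref
}

#' Basal (pre-stimulus) level of a trace
#'
#' @param trace Data frame with `t_s`, `value`.
#' @param window Two-element time window in s (default the first 60 s).
#' @return Mean value over samples inside the window.
#' @export
basal_level <- function(trace, window = c(0, 60)) {
  .check_trace(trace)
  stopifnot(length(window) == 2L, window[1] <= window[2])
  sel <- trace$t_s >= window[1] & trace$t_s <= window[2]
  if (!any(sel)) stop("no samples inside the basal window", call. = FALSE)
  mean(trace$value[sel])
}

#' Relative peak current of a treated versus control recording
#'
#' Ratio of peak magnitudes, with the peak taken as the extreme value in the
#' stated direction: the most negative sample for inward currents (the
#' mechanically evoked currents at negative holding potential), the most
#' positive for outward.
#'
#' @param treated,control Data frames with `t_s`, `value` (current in pA).
#' @param direction `"inward"` (default) or `"outward"`.
#' @return `|peak(treated)| / |peak(control)|`.
#' @export
relative_peak_current <- function(treated, control,
                                  direction = c("inward", "outward")) {
  direction <- match.arg(direction)
  .check_trace(treated)
  .check_trace(control)
  pk <- function(v) if (direction == "inward") min(v) else max(v)
  pc <- abs(pk(control$value))
  if (pc <= 0) stop("control peak magnitude is zero", call. = FALSE)
  abs(pk(treated$value)) / pc
}

#' Median-intensity time course of cell populations
#'
#' Per-timepoint median fluorescence intensity, using the lower-median
#' convention for even population sizes (integer-stable on synthetic integer
#' data).
#'
#' @param populations Named or unnamed list of numeric intensity vectors, one
#'   per timepoint.
#' @param times Optional numeric timepoints (s); defaults to 0, 1, 2, ...
#' @return A data frame of class `trace` with `t_s` and `value` (medians).
#' @export
median_timecourse <- function(populations, times = NULL) {
  stopifnot(is.list(populations), length(populations) >= 1L)
  empty <- which(vapply(populations, length, integer(1)) == 0L)
  if (length(empty) > 0L) {
    stop("empty population(s) at timepoint(s): ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  if (is.null(times)) times <- seq_along(populations) - 1
  stopifnot(length(times) == length(populations))
  out <- data.frame(t_s = as.numeric(times),
                    value = vapply(populations, .lower_median, numeric(1)))
  class(out) <- c("trace", "data.frame")
  out
}

#' Fraction of a population above a threshold
#'
#' @param intensities Non-empty numeric vector.
#' @param threshold Gate; cells strictly above it count as positive.
#' @return Percentage of positive cells, in [0, 100].
#' @export
fraction_positive <- function(intensities, threshold) {
  if (length(intensities) == 0L) stop("empty intensity list", call. = FALSE)
  .check_nonneg(abs(threshold), "threshold")  # must be a single finite number
  100 * sum(intensities > threshold) / length(intensities)
}

#' Positive gate from a negative-control population
#'
#' Standard-practice gate: a high quantile (default the 99th percentile) of a
#' negative-control population; cells above it are called positive.
#'
#' @param negative_control Numeric vector of negative-control intensities.
#' @param prob Quantile probability (default 0.99).
#' @return The threshold intensity.
#' @export
positive_threshold <- function(negative_control, prob = 0.99) {
  if (length(negative_control) == 0L) {
    stop("empty negative-control population", call. = FALSE)
  }
  as.numeric(stats::quantile(negative_control, prob, names = FALSE))
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-[(Ct_target - Ct_reference)_sample - (Ct_target - Ct_reference)_calibrator]`.
#' Vectorized over samples; log2-linear (each added target cycle halves the
#' fold change).
#'
#' @param ct_target_sample,ct_reference_sample Ct values (cycles) of the
#'   target and reference gene in the sample.
#' @param ct_target_calibrator,ct_reference_calibrator Ct values in the
#'   calibrator condition.
#' @return Fold change(s) relative to the calibrator.
#' @examples
#' fold_change_ddct(25, 20, 24, 20)  # 0.5
#' @export
fold_change_ddct <- function(ct_target_sample, ct_reference_sample,
                             ct_target_calibrator, ct_reference_calibrator) {
  cts <- c(ct_target_sample, ct_reference_sample,
           ct_target_calibrator, ct_reference_calibrator)
  if (!all(is.finite(cts)) || any(cts <= 0)) {
    stop("all Ct values must be finite and > 0", call. = FALSE)
  }
  ddct <- (ct_target_sample - ct_reference_sample) -
    (ct_target_calibrator - ct_reference_calibrator)
  2^(-ddct)
}
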