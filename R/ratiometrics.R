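# Ratio computation, baseline estimation and dynamic-range normalization.
#
# The 490/420 excitation ratio cancels expression level and ROI size;
# normalizing its excursion to the span between the basal value and the
# maximum under a saturating pulse puts every cell on a common 0-100% scale.

#' Compute the 490/420 excitation ratio of a trace
#'
#' @param trace an [acquisition_trace()]
#' @param offset420,offset490 optional constant background offsets
#'   subtracted from each channel before the ratio (default 0; background
#'   subtraction is normally done upstream at acquisition)
#' @return object of class `ratio_trace`: list with `cell_id`, `time_min`,
#'   `ratio` and the trace `metadata`
#' @export
compute_ratio <- function(trace, offset420 = 0, offset490 = 0) {
  stopifnot(inherits(trace, "acquisition_trace"))
  f420 <- trace$f420 - offset420
  f490 <- trace$f490 - offset490
  if (any(f420 <= 0))
    hk_stop(sprintf("non-positive 420 nm signal in cell '%s'", trace$cell_id),
            "hyperkin_validation_error")
  if (any(f490 <= 0))
    hk_stop(sprintf("non-positive 490 nm signal in cell '%s'", trace$cell_id),
            "hyperkin_validation_error")
  structure(list(cell_id = trace$cell_id,
                 time_min = trace$time_s / 60,
                 ratio = f490 / f420,
                 metadata = trace$metadata),
            class = "ratio_trace")
}

#' @export
print.ratio_trace <- function(x, ...) {
  cat(sprintf("<ratio_trace> %s: %d frames, ratio %.3g-%.3g\n",
              x$cell_id, length(x$ratio), min(x$ratio), max(x$ratio)))
  invisible(x)
}

#' Estimate the basal ratio
#'
#' Arithmetic mean of the ratio over the `window_min` minutes immediately
#' preceding the first oxidant pulse.
#'
#' @param rt a [compute_ratio()] result
#' @param schedule the [protocol_schedule()] of the recording
#' @param window_min averaging window before the first pulse (minutes)
#' @return basal ratio (scalar)
#' @export
estimate_baseline <- function(rt, schedule, window_min = 2) {
  stopifnot(inherits(rt, "ratio_trace"))
  t_pulse <- first_pulse_start(schedule)
  sel <- rt$time_min >= t_pulse - window_min - 1e-9 & rt$time_min < t_pulse - 1e-9
  if (sum(sel) < 2)
    hk_stop(paste0("fewer than 2 frames in the baseline window; ",
                   "record a longer baseline or widen 'window_min'"),
            "hyperkin_validation_error")
  mean(rt$ratio[sel])
}

#' Dynamic range of a cell's biosensor response
#'
#' The span between the basal ratio and the maximal ratio reached during the
#' saturating pulse. Cells whose span is non-positive or below 5% of the
#' basal ratio are degenerate (biosensor unresponsive) and raise a classed
#' error so callers can exclude and count them.
#'
#' @param rt a [compute_ratio()] result
#' @param schedule the recording's [protocol_schedule()]
#' @param window_min baseline window passed to [estimate_baseline()]
#' @param median3 apply a 3-frame running median inside the pulse window
#'   before taking the maximum (guards against single-frame spikes)
#' @return object of class `dynamic_range`: list with `r_basal`, `r_max`,
#'   `span`
#' @export
dynamic_range <- function(rt, schedule, window_min = 2, median3 = FALSE) {
  r_basal <- estimate_baseline(rt, schedule, window_min)
  pw <- saturating_pulse(schedule)
  sel <- rt$time_min >= pw$start - 1e-9 & rt$time_min <= pw$end + 1e-9
  if (!any(sel))
    hk_stop("no frames inside the saturating-pulse window",
            "hyperkin_validation_error")
  vals <- rt$ratio[sel]
  if (median3 && length(vals) >= 3)
    vals <- stats::runmed(vals, 3, endrule = "keep")
  r_max <- max(vals)
  span <- r_max - r_basal
  if (span <= 0 || span < 0.05 * r_basal)
    hk_stop(sprintf("degenerate dynamic range for cell '%s' (span %.3g)",
                    rt$cell_id, span),
            "hyperkin_degenerate_cell")
  structure(list(r_basal = r_basal, r_max = r_max, span = span),
            class = "dynamic_range")
}

#' Normalize a ratio trace to its dynamic range
#'
#' Expresses the ratio excursion as a percentage of the cell's dynamic
#' range: 0% at the basal ratio, 100% at the saturating-pulse maximum.
#' Values may transiently leave \[0, 100\] through noise. Because both the
#' ratio and the span are invariant to per-channel gain rescaling, the
#' normalized trace is independent of biosensor expression level.
#'
#' @param rt a [compute_ratio()] result
#' @param dr a [dynamic_range()] result
#' @return object of class `normalized_trace`: list with `cell_id`,
#'   `time_min`, `percent`, `dr`, `metadata`
#' @export
normalize_trace <- function(rt, dr) {
  stopifnot(inherits(rt, "ratio_trace"), inherits(dr, "dynamic_range"))
  structure(list(cell_id = rt$cell_id, time_min = rt$time_min,
                 percent = 100 * (rt$ratio - dr$r_basal) / dr$span,
                 dr = dr, metadata = rt$metadata),
            class = "normalized_trace")
}
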