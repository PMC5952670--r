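# Phase segmentation, response quantification and the three-parameter
# exponential recovery fit -- the analysis chain behind the headline
# disulfide-reduction rate.

#' Segment a recording into protocol phases
#'
#' Maps the schedule onto the recording: baseline, first (submaximal) pulse,
#' washout, second (saturating) pulse and the recovery phase, which begins
#' at the final `pulse_end` and runs to the end of the recording. Protocols
#' with a single pulse yield `pulse2 = NULL` and recovery follows pulse 1.
#'
#' @param schedule a [protocol_schedule()]
#' @param trace_times optional sample times (minutes) used to verify that
#'   the scheduled pulses fall inside the recording
#' @return object of class `phase_segmentation`: list of intervals
#'   `baseline`, `pulse1` (+`conc1`), `washout1`, `pulse2` (+`conc2`),
#'   `recovery`, each `c(start, end)` in minutes
#' @export
segment_phases <- function(schedule, trace_times = NULL) {
  pw <- pulse_windows(schedule)
  if (!nrow(pw))
    hk_stop("schedule contains no oxidant pulse", "hyperkin_schema_error")
  t_end <- if (!is.null(trace_times)) max(trace_times) else schedule$duration_min
  if (max(pw$end) > t_end + 1e-9)
    hk_stop("scheduled pulse extends beyond the recording",
            "hyperkin_validation_error")
  seg <- list(baseline = c(0, pw$start[1]),
              pulse1 = c(pw$start[1], pw$end[1]),
              conc1 = pw$conc_uM[1],
              washout1 = NULL, pulse2 = NULL, conc2 = NULL,
              recovery = c(max(pw$end), t_end))
  if (nrow(pw) >= 2) {
    seg$washout1 <- c(pw$end[1], pw$start[2])
    seg$pulse2 <- c(pw$start[2], pw$end[2])
    seg$conc2 <- pw$conc_uM[2]
  }
  structure(seg, class = "phase_segmentation")
}

in_window <- function(t, w) t >= w[1] - 1e-9 & t <= w[2] + 1e-9

#' Response amplitudes and rise time of a ratio trace
#'
#' Amplitudes are within-pulse maxima minus the basal ratio; the plateau
#' time is the first crossing of 95% of the pulse-1 maximum excursion,
#' measured from pulse onset.
#'
#' @param rt a [compute_ratio()] result
#' @param seg a [segment_phases()] result
#' @param r_basal basal ratio from [estimate_baseline()]
#' @return object of class `response_summary`: `delta_r_50` (pulse-1
#'   amplitude), `delta_r_500` (saturating-pulse amplitude; equals the
#'   pulse-1 amplitude for single-pulse protocols), `t_plateau_50`
#'   (minutes). A warning is emitted when the saturating amplitude falls
#'   below the submaximal one.
#' @export
response_amplitude <- function(rt, seg, r_basal) {
  stopifnot(inherits(rt, "ratio_trace"), inherits(seg, "phase_segmentation"))
  sel1 <- in_window(rt$time_min, seg$pulse1)
  if (!any(sel1))
    hk_stop("no frames inside the pulse-1 window", "hyperkin_validation_error")
  max1 <- max(rt$ratio[sel1])
  delta1 <- max(max1 - r_basal, 0)
  thresh <- r_basal + 0.95 * (max1 - r_basal)
  idx <- which(sel1 & rt$ratio >= thresh - 1e-12)
  t_plateau <- if (length(idx)) rt$time_min[idx[1]] - seg$pulse1[1] else NA_real_
  if (!is.null(seg$pulse2)) {
    sel2 <- in_window(rt$time_min, seg$pulse2)
    if (!any(sel2))
      hk_stop("no frames inside the pulse-2 window",
              "hyperkin_validation_error")
    delta2 <- max(max(rt$ratio[sel2]) - r_basal, 0)
  } else delta2 <- delta1
  if (delta2 < delta1)
    warning(sprintf(
      "cell '%s': saturating response (%.3g) below submaximal response (%.3g)",
      rt$cell_id, delta2, delta1))
  structure(list(delta_r_50 = delta1, delta_r_500 = delta2,
                 t_plateau_50 = t_plateau),
            class = "response_summary")
}

#' Fit the post-washout recovery with a three-parameter exponential
#'
#' Fits `y(t) = y0 + A * exp(-k * (t - t0))` to the recovery phase by
#' bounded nonlinear least squares (Levenberg-Marquardt, `k` in
#' \[0, 1000\] per min, `A >= 0`, at most 500 iterations, tolerance 1e-10),
#' with `t0` fixed at the first recovery frame and deterministic
#' initialization from a log-linear regression of `y - min(y) + eps`. The
#' fitted `k` estimates the disulfide-reduction rate and is invariant to
#' affine rescaling of `y`, so ratio-scale and normalized (%) traces give
#' the same rate.
#'
#' @param time_min sample times (minutes) or a `ratio_trace`/
#'   `normalized_trace` object (then `y` is taken from it)
#' @param y observed series (ratio or % of dynamic range)
#' @param seg optional [segment_phases()] result; when given, only frames in
#'   the recovery window are fitted
#' @return object of class `recovery_fit`: `y0`, `A`, `k` (per min), `r`
#'   (correlation between fitted and observed), `n_points`, `converged`,
#'   `identifiable` (`FALSE` for flat traces where `k` is meaningless),
#'   `t0` (fit origin, min)
#' @export
fit_exponential_recovery <- function(time_min, y = NULL, seg = NULL) {
  if (inherits(time_min, "ratio_trace")) {
    y <- time_min$ratio; time_min <- time_min$time_min
  } else if (inherits(time_min, "normalized_trace")) {
    y <- time_min$percent; time_min <- time_min$time_min
  }
  if (!is.null(seg)) {
    sel <- in_window(time_min, seg$recovery)
    time_min <- time_min[sel]; y <- y[sel]
  }
  if (any(!is.finite(time_min)) || any(!is.finite(y)))
    hk_stop("non-finite values in the recovery window",
            "hyperkin_validation_error")
  n <- length(y)
  if (n < 5)
    hk_stop("need at least 5 frames in the recovery window",
            "hyperkin_validation_error")
  t0 <- time_min[1]
  tt <- time_min - t0
  amp <- diff(range(y))
  if (amp < 1e-12 * max(1, abs(mean(y)))) {
    # flat trace: converged by convention, rate not identifiable
    return(structure(list(y0 = mean(y), A = 0, k = NA_real_, r = NA_real_,
                          n_points = n, converged = TRUE,
                          identifiable = FALSE, t0 = t0),
                     class = "recovery_fit"))
  }
  eps <- max(1e-6, 1e-3 * amp)
  z <- y - min(y) + eps
  init <- stats::lm.fit(cbind(1, tt), log(z))$coefficients
  k0 <- min(max(-init[2], 1e-3), 999)
  start <- list(y0 = min(y), A = max(exp(init[1]), 0.1 * amp), k = k0)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ y0 + A * exp(-k * tt),
                      data = data.frame(y = y, tt = tt),
                      start = start,
                      lower = c(y0 = -Inf, A = 0, k = 0),
                      upper = c(y0 = Inf, A = Inf, k = 1000),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-10, ptol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(y0 = NA_real_, A = NA_real_, k = NA_real_,
                          r = NA_real_, n_points = n, converged = FALSE,
                          identifiable = FALSE, t0 = t0),
                     class = "recovery_fit"))
  }
  cf <- stats::coef(fit)
  k_hat <- unname(cf["k"])
  at_bound <- k_hat <= 1e-9 || k_hat >= 1000 - 1e-6
  fitted_y <- stats::fitted(fit)
  r <- if (stats::sd(fitted_y) > 0) stats::cor(y, fitted_y) else NA_real_
  structure(list(y0 = unname(cf["y0"]), A = unname(cf["A"]), k = k_hat,
                 r = r, n_points = n,
                 converged = isTRUE(fit$convInfo$isConv) && !at_bound,
                 identifiable = unname(cf["A"]) > 1e-6 * amp,
                 t0 = t0),
            class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf(
    "<recovery_fit> k = %.4g /min, A = %.4g, y0 = %.4g (r = %.3f, n = %d)%s\n",
    x$k, x$A, x$y0, x$r, x$n_points,
    if (!isTRUE(x$converged)) " [not converged]"
    else if (!isTRUE(x$identifiable)) " [rate not identifiable]" else ""))
  invisible(x)
}

#' Pooled mean +/- SE recovery curve across cells
#'
#' Resamples each cell's normalized trace onto the first cell's recovery
#' time grid (nearest frame) and returns the per-timepoint mean and
#' standard error, the conventional population display of recovery data.
#'
#' @param cells list of `normalized_trace` objects
#' @param seg a [segment_phases()] result
#' @return data frame with `time_min`, `mean`, `se`, `n`
#' @export
pooled_recovery_curve <- function(cells, seg) {
  if (length(cells) < 2)
    hk_stop("need at least 2 cells to pool", "hyperkin_validation_error")
  ref <- cells[[1]]
  sel <- in_window(ref$time_min, seg$recovery)
  grid <- ref$time_min[sel]
  if (!length(grid))
    hk_stop("no frames inside the recovery window",
            "hyperkin_validation_error")
  mat <- vapply(cells, function(ct) {
    idx <- vapply(grid, function(g) which.min(abs(ct$time_min - g)), 0L)
    ct$percent[idx]
  }, numeric(length(grid)))
  data.frame(time_min = grid,
             mean = rowMeans(mat),
             se = apply(mat, 1, stats::sd) / sqrt(ncol(mat)),
             n = ncol(mat))
}

#' Analyze an experiment into a per-cell results table
#'
#' Runs the full chain -- ratio, baseline, dynamic range, normalization,
#' segmentation, response amplitudes and the exponential recovery fit -- on
#' every trace. Cells with a degenerate dynamic range are excluded and
#' counted; cells whose fit correlation falls below `r_flag` are flagged
#' (retained in the table, excluded from group statistics by default
#' downstream).
#'
#' @param x a `simulated_experiment` or a list of [acquisition_trace()]
#' @param schedule the recording's [protocol_schedule()] (taken from the
#'   experiment when `x` is a `simulated_experiment`)
#' @param baseline_window_min baseline averaging window (minutes)
#' @param fit_on fit the recovery on the normalized (`"percent"`, default)
#'   or raw `"ratio"` scale; the fitted rate is identical, only `y0`/`A`
#'   units change
#' @param r_flag fit-quality threshold; fits with `r < r_flag` are flagged
#' @return data frame, one row per analyzed cell, with identifiers and
#'   metadata, `r_basal`, `r_max`, `span`, `delta_r_50`, `delta_r_500`,
#'   `t_plateau_50`, fit parameters (`k`, `A`, `y0`, `r_fit`, `converged`,
#'   `flagged`); attribute `n_degenerate` counts excluded cells
#' @export
analyze_experiment <- function(x, schedule = NULL, baseline_window_min = 2,
                               fit_on = c("percent", "ratio"),
                               r_flag = 0.8) {
  fit_on <- match.arg(fit_on)
  if (inherits(x, "simulated_experiment")) {
    traces <- x$traces
    schedule <- schedule %||% x$schedule
  } else traces <- x
  if (is.null(schedule))
    hk_stop("'schedule' is required when analyzing plain traces",
            "hyperkin_param_error")
  rows <- list(); n_degenerate <- 0L
  for (tr in traces) {
    rt <- compute_ratio(tr)
    dr <- tryCatch(dynamic_range(rt, schedule, baseline_window_min),
                   hyperkin_degenerate_cell = function(e) NULL)
    if (is.null(dr)) { n_degenerate <- n_degenerate + 1L; next }
    seg <- segment_phases(schedule, rt$time_min)
    resp <- response_amplitude(rt, seg, dr$r_basal)
    nt <- normalize_trace(rt, dr)
    fit <- if (fit_on == "percent") fit_exponential_recovery(nt, seg = seg)
           else fit_exponential_recovery(rt, seg = seg)
    rows[[length(rows) + 1L]] <- data.frame(
      experiment_id = meta_field(tr, "experiment_id", "exp1"),
      cell_id = tr$cell_id,
      cell_line = meta_field(tr, "cell_line"),
      compartment = meta_field(tr, "compartment"),
      treatment = meta_field(tr, "treatment"),
      r_basal = dr$r_basal, r_max = dr$r_max, span = dr$span,
      delta_r_50 = resp$delta_r_50, delta_r_500 = resp$delta_r_500,
      t_plateau_50 = resp$t_plateau_50,
      k = fit$k, A = fit$A, y0 = fit$y0, r_fit = fit$r,
      converged = fit$converged,
      flagged = !isTRUE(fit$converged) || !isTRUE(fit$identifiable) ||
        (is.finite(fit$r) && fit$r < r_flag),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame()
  attr(out, "n_degenerate") <- n_degenerate
  out
}
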