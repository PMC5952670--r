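#' Protocol schedules
#'
#' A protocol schedule is the timed event list that drives both the forward
#' simulator and the phase segmentation of recorded traces: oxidant pulses,
#' pH clamps and treatment windows, plus the recording duration and the
#' acquisition sampling interval.
#'
#' @param events data frame with columns `t_min` (event time, minutes),
#'   `kind` (one of `pulse_start`, `pulse_end`, `ph_clamp_start`,
#'   `treatment_start`, `treatment_end`), `conc_uM` (H2O2 concentration for
#'   `pulse_start`, `NA` otherwise) and `ph` (target pH for
#'   `ph_clamp_start`, `NA` otherwise)
#' @param duration_min total recording duration (minutes)
#' @param sample_interval_s acquisition sampling interval (seconds)
#' @return object of class `protocol_schedule`
#' @seealso [default_schedule()], [single_pulse_schedule()],
#'   [fast_recovery_schedule()], [ph_clamp_schedule()]
#' @export
protocol_schedule <- function(events, duration_min, sample_interval_s = 20) {
  kinds <- c("pulse_start", "pulse_end", "ph_clamp_start",
             "treatment_start", "treatment_end")
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  for (col in c("conc_uM", "ph"))
    if (is.null(events[[col]])) events[[col]] <- rep(NA_real_, nrow(events))
  need <- c("t_min", "kind", "conc_uM", "ph")
  if (!all(need %in% names(events)))
    hk_stop("schedule events need columns t_min, kind [, conc_uM, ph]",
            "hyperkin_schema_error")
  events <- events[, need]
  if (nrow(events) && any(!events$kind %in% kinds))
    hk_stop(sprintf("unknown event kind(s): %s",
                    paste(setdiff(events$kind, kinds), collapse = ", ")),
            "hyperkin_schema_error")
  if (is.unsorted(events$t_min))
    hk_stop("schedule events must be time-ordered", "hyperkin_schema_error")
  check_pos(duration_min, "duration_min")
  check_pos(sample_interval_s, "sample_interval_s")
  if (nrow(events) && (min(events$t_min) < 0 || max(events$t_min) > duration_min))
    hk_stop("schedule events must lie within [0, duration_min]",
            "hyperkin_schema_error")
  # pulse starts and ends must strictly alternate, starting with a start
  pk <- events$kind[events$kind %in% c("pulse_start", "pulse_end")]
  if (length(pk)) {
    expected <- rep(c("pulse_start", "pulse_end"), length.out = length(pk))
    if (!identical(pk, expected))
      hk_stop("pulse_start/pulse_end events must strictly alternate",
              "hyperkin_schema_error")
  }
  bad_pulse <- events$kind == "pulse_start" &
    (!is.finite(events$conc_uM) | events$conc_uM <= 0)
  if (any(bad_pulse))
    hk_stop("every pulse_start needs a positive conc_uM payload",
            "hyperkin_schema_error")
  bad_clamp <- events$kind == "ph_clamp_start" & !is.finite(events$ph)
  if (any(bad_clamp))
    hk_stop("every ph_clamp_start needs a pH payload", "hyperkin_schema_error")
  structure(list(events = events, duration_min = duration_min,
                 sample_interval_s = sample_interval_s),
            class = "protocol_schedule")
}

#' @export
print.protocol_schedule <- function(x, ...) {
  cat(sprintf("<protocol_schedule> %.3g min @ %.3g s/frame, %d event(s)\n",
              x$duration_min, x$sample_interval_s, nrow(x$events)))
  if (nrow(x$events)) print(x$events, row.names = FALSE)
  invisible(x)
}

#' Acquisition time grid of a schedule
#' @param schedule a [protocol_schedule()]
#' @return sample times in minutes (frame 0 at t = 0)
#' @export
sample_times_min <- function(schedule) {
  dt <- schedule$sample_interval_s / 60
  seq(0, schedule$duration_min, by = dt)
}

#' Oxidant pulse windows of a schedule
#' @param schedule a [protocol_schedule()]
#' @return data frame with columns `start`, `end` (minutes) and `conc_uM`,
#'   one row per pulse; an unterminated final pulse ends at the recording end
#' @export
pulse_windows <- function(schedule) {
  ev <- schedule$events
  starts <- which(ev$kind == "pulse_start")
  ends <- which(ev$kind == "pulse_end")
  data.frame(
    start = ev$t_min[starts],
    end = if (length(ends) == length(starts)) ev$t_min[ends]
          else c(ev$t_min[ends], schedule$duration_min),
    conc_uM = ev$conc_uM[starts]
  )
}

# window of the saturating (maximum-concentration) pulse
saturating_pulse <- function(schedule) {
  pw <- pulse_windows(schedule)
  if (!nrow(pw))
    hk_stop("schedule contains no oxidant pulse", "hyperkin_schema_error")
  pw[which.max(pw$conc_uM), , drop = FALSE]
}

first_pulse_start <- function(schedule) {
  pw <- pulse_windows(schedule)
  if (!nrow(pw))
    hk_stop("schedule contains no oxidant pulse", "hyperkin_schema_error")
  min(pw$start)
}

final_pulse_end <- function(schedule) {
  pw <- pulse_windows(schedule)
  if (!nrow(pw))
    hk_stop("schedule contains no oxidant pulse", "hyperkin_schema_error")
  max(pw$end)
}

#' Standard two-pulse recording protocol
#'
#' The canonical recording: a long baseline to establish the basal value, a
#' submaximal pulse, a washout, a saturating pulse that defines the top of
#' the biosensor's dynamic range, and a final recovery phase from which the
#' disulfide-reduction rate is fitted.
#'
#' @param baseline_min baseline duration before the first pulse (min)
#' @param pulse1_conc,pulse1_min submaximal pulse concentration (uM)/duration
#' @param washout_min washout between the pulses (min)
#' @param pulse2_conc,pulse2_min saturating pulse concentration (uM)/duration
#' @param recovery_min recording time after the final washout (min)
#' @param sample_interval_s sampling interval (s)
#' @return a [protocol_schedule()]
#' @export
default_schedule <- function(baseline_min = 20, pulse1_conc = 50,
                             pulse1_min = 5, washout_min = 10,
                             pulse2_conc = 500, pulse2_min = 4,
                             recovery_min = 16, sample_interval_s = 20) {
  t1 <- baseline_min
  t2 <- t1 + pulse1_min
  t3 <- t2 + washout_min
  t4 <- t3 + pulse2_min
  protocol_schedule(
    data.frame(
      t_min = c(t1, t2, t3, t4),
      kind = c("pulse_start", "pulse_end", "pulse_start", "pulse_end"),
      conc_uM = c(pulse1_conc, NA, pulse2_conc, NA),
      ph = NA_real_
    ),
    duration_min = t4 + recovery_min,
    sample_interval_s = sample_interval_s
  )
}

#' Single saturating-pulse protocol
#'
#' Used for compartment characterization: baseline, one saturating pulse,
#' recovery.
#'
#' @param baseline_min baseline duration (min)
#' @param conc_uM pulse concentration (uM)
#' @param pulse_min pulse duration (min)
#' @param recovery_min recording time after washout (min)
#' @param sample_interval_s sampling interval (s)
#' @return a [protocol_schedule()]
#' @export
single_pulse_schedule <- function(baseline_min = 20, conc_uM = 500,
                                  pulse_min = 4, recovery_min = 16,
                                  sample_interval_s = 20) {
  protocol_schedule(
    data.frame(t_min = c(baseline_min, baseline_min + pulse_min),
               kind = c("pulse_start", "pulse_end"),
               conc_uM = c(conc_uM, NA), ph = NA_real_),
    duration_min = baseline_min + pulse_min + recovery_min,
    sample_interval_s = sample_interval_s
  )
}

#' Fine-sampled protocol for fast recovery kinetics
#'
#' Recovery rates of tens per minute relax on a timescale of seconds and are
#' unresolvable at the standard 20 s sampling; this compressed protocol
#' samples at sub-second intervals.
#'
#' @param baseline_min baseline duration (min)
#' @param conc_uM pulse concentration (uM)
#' @param pulse_min pulse duration (min)
#' @param recovery_min recording time after washout (min)
#' @param sample_interval_s sampling interval (s)
#' @return a [protocol_schedule()]
#' @export
fast_recovery_schedule <- function(baseline_min = 2, conc_uM = 500,
                                   pulse_min = 1, recovery_min = 2,
                                   sample_interval_s = 0.5) {
  single_pulse_schedule(baseline_min = baseline_min, conc_uM = conc_uM,
                        pulse_min = pulse_min, recovery_min = recovery_min,
                        sample_interval_s = sample_interval_s)
}

#' pH-clamp protocol
#'
#' An ionophore-based pH clamp (nigericin/valinomycin in high-K+ buffer)
#' forces intracellular pH to the commanded extracellular value; the clamp
#' event is followed by an equilibration period, then a saturating pulse and
#' recovery.
#'
#' @param ph commanded pH
#' @param clamp_min time at which the clamp is applied (min)
#' @param equil_min equilibration time between clamp and pulse (min)
#' @param conc_uM pulse concentration (uM)
#' @param pulse_min pulse duration (min)
#' @param recovery_min recording time after washout (min)
#' @param sample_interval_s sampling interval (s)
#' @return a [protocol_schedule()]
#' @export
ph_clamp_schedule <- function(ph, clamp_min = 2, equil_min = 6,
                              conc_uM = 500, pulse_min = 1,
                              recovery_min = 2, sample_interval_s = 0.5) {
  t_pulse <- clamp_min + equil_min
  protocol_schedule(
    data.frame(t_min = c(clamp_min, t_pulse, t_pulse + pulse_min),
               kind = c("ph_clamp_start", "pulse_start", "pulse_end"),
               conc_uM = c(NA, conc_uM, NA),
               ph = c(ph, NA, NA)),
    duration_min = t_pulse + pulse_min + recovery_min,
    sample_interval_s = sample_interval_s
  )
}
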