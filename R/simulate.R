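# Forward simulation of dual-channel biosensor recordings.
#
# The system is integrated piecewise between schedule events (within a
# segment the external peroxide level, pH command and any treatment scaling
# are constant) with a stiff-capable adaptive solver at rtol 1e-8, and the
# dense solution is sampled on the acquisition grid.

PH_CLAMP_TAU_MIN <- 0.5  # ionophore pH equilibration time constant (min)

# Split a schedule into constant-coefficient segments. Returns a data frame
# with one row per segment: t0, t1, He (uM), pH_target, k_mult, prod_mult.
# `perturbation` may be NULL or a perturbation_preset; washout-only
# perturbations act from the final pulse_end onward, whole-recording ones
# act everywhere unless the schedule carries treatment_start/treatment_end
# events, in which case they act only inside those windows.
build_segments <- function(schedule, resting_ph, perturbation = NULL) {
  ev <- schedule$events
  breaks <- sort(unique(c(0, ev$t_min, schedule$duration_min)))
  n <- length(breaks) - 1L
  seg <- data.frame(t0 = breaks[-length(breaks)], t1 = breaks[-1],
                    He = 0, pH_target = resting_ph,
                    k_mult = 1, prod_mult = 1)
  He <- 0; ph_t <- resting_ph; in_treat <- FALSE
  has_treat_events <- any(ev$kind %in% c("treatment_start", "treatment_end"))
  wash_from <- if (!is.null(perturbation) &&
                   perturbation$applies_during == "washout-only")
    final_pulse_end(schedule) else NA_real_
  for (i in seq_len(n)) {
    here <- ev[abs(ev$t_min - seg$t0[i]) < 1e-9, , drop = FALSE]
    for (j in seq_len(nrow(here))) {
      k <- here$kind[j]
      if (k == "pulse_start") He <- here$conc_uM[j]
      if (k == "pulse_end") He <- 0
      if (k == "ph_clamp_start") ph_t <- here$ph[j]
      if (k == "treatment_start") in_treat <- TRUE
      if (k == "treatment_end") in_treat <- FALSE
    }
    seg$He[i] <- He
    seg$pH_target[i] <- ph_t
    active <- FALSE
    if (!is.null(perturbation)) {
      active <- if (perturbation$applies_during == "washout-only")
        seg$t0[i] >= wash_from - 1e-9
      else if (has_treat_events) in_treat else TRUE
    }
    if (active) {
      seg$k_mult[i] <- perturbation$k_red_scale
      seg$prod_mult[i] <- perturbation$prod_scale
    }
  }
  seg
}

biosensor_deriv <- function(t, y, p) {
  cons_eff <- p$cons * (1 + p$cons_ind * y[["A"]])
  dH <- p$perm * (p$He - y[["H"]]) + p$prod - cons_eff * y[["H"]]
  dA <- if (p$cons_ind > 0) (p$s - y[["A"]]) / p$tau_ind else 0
  dTH <- p$k_ox * y[["H"]] * (1 - y[["TH"]]) - p$k_red * y[["TH"]]
  dPH <- (p$pH_target - y[["PH"]]) / PH_CLAMP_TAU_MIN
  list(c(dH, dA, dTH, dPH))
}

# Integrate one cell over the whole schedule. kin is a kinetic_params,
# segments from build_segments(). Returns a data frame on `times` with
# columns time_min, h2o2_uM, theta, ph.
integrate_cell <- function(kin, segments, theta0, ph0,
                           times, rtol = 1e-8, atol = 1e-10) {
  den <- kin$perm + kin$cons
  y <- c(H = if (den > 0) kin$prod * segments$prod_mult[1] / den else 0,
         A = 0, TH = theta0, PH = ph0)
  out_t <- numeric(0); out <- NULL
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    tt <- times[times > s$t0 + 1e-9 & times <= s$t1 + 1e-9]
    solve_t <- unique(c(s$t0, tt, s$t1))
    p <- list(He = s$He, s = as.numeric(s$He > 0),
              pH_target = s$pH_target,
              k_ox = kin$k_ox, k_red = kin$k_red * s$k_mult,
              perm = kin$perm, prod = kin$prod * s$prod_mult,
              cons = kin$cons, cons_ind = kin$cons_ind, tau_ind = kin$tau_ind)
    sol <- deSolve::lsoda(y, solve_t, biosensor_deriv, p,
                          rtol = rtol, atol = atol)
    y <- sol[nrow(sol), c("H", "A", "TH", "PH")]
    keep <- sol[sol[, "time"] %in% tt, , drop = FALSE]
    if (i == 1 && length(times) && abs(times[1] - s$t0) < 1e-9)
      keep <- rbind(sol[1, , drop = FALSE], keep)
    out <- rbind(out, keep)
  }
  data.frame(time_min = out[, "time"],
             h2o2_uM = pmax(out[, "H"], 0),
             theta = pmin(pmax(out[, "TH"], 0), 1),
             ph = out[, "PH"])
}

#' Simulate intracellular H2O2 under a pulse protocol
#'
#' Integrates `dHi/dt = perm (He(t) - Hi) + prod - cons_eff Hi`, with the
#' scheduled extracellular pulse profile `He(t)` and (optionally) inducible
#' consumption (see [kinetic_params()]). The intracellular level starts at
#' the production/consumption balance `prod/cons` (0 when `cons = 0`).
#'
#' @param schedule a [protocol_schedule()]
#' @param kin a [kinetic_params()] object
#' @return data frame with `time_min` and `h2o2_uM` on the acquisition grid
#' @examples
#' sch <- single_pulse_schedule()
#' kin <- kinetic_params(k_ox = 0, k_red = 1, perm = 10, prod = 0, cons = 2)
#' h <- simulate_h2o2_intracellular(sch, kin)
#' max(h$h2o2_uM)  # ~ perm * 500 / (perm + cons)
#' @export
simulate_h2o2_intracellular <- function(schedule, kin) {
  stopifnot(inherits(schedule, "protocol_schedule"),
            inherits(kin, "kinetic_params"))
  segs <- build_segments(schedule, resting_ph = 7.2)
  res <- integrate_cell(kin, segs, theta0 = 0, ph0 = 7.2,
                        times = sample_times_min(schedule))
  res[, c("time_min", "h2o2_uM")]
}

#' Simulate the oxidized biosensor fraction given an H2O2 time course
#'
#' Integrates `dtheta/dt = k_ox Hi(t) (1 - theta) - k_red theta` with
#' `Hi(t)` linearly interpolated from the supplied series. With `Hi = 0`
#' this reduces exactly to `theta0 * exp(-k_red * t)`, the single-exponential
#' recovery that the post-washout fit estimates.
#'
#' @param h2o2 data frame with columns `time_min` and `h2o2_uM` (as returned
#'   by [simulate_h2o2_intracellular()])
#' @param kin a [kinetic_params()] object (uses `k_ox`, `k_red`)
#' @param theta0 initial oxidized fraction in \[0, 1\]
#' @return data frame with `time_min` and `theta`
#' @export
simulate_oxidized_fraction <- function(h2o2, kin, theta0 = 0) {
  stopifnot(inherits(kin, "kinetic_params"))
  if (!is_number(theta0) || theta0 < 0 || theta0 > 1)
    hk_stop("'theta0' must lie in [0, 1]", "hyperkin_param_error")
  if (!all(c("time_min", "h2o2_uM") %in% names(h2o2)))
    hk_stop("'h2o2' needs columns time_min and h2o2_uM", "hyperkin_param_error")
  Hfun <- stats::approxfun(h2o2$time_min, h2o2$h2o2_uM, rule = 2)
  deriv <- function(t, y, p)
    list(p$k_ox * Hfun(t) * (1 - y) - p$k_red * y)
  sol <- deSolve::lsoda(c(TH = theta0), h2o2$time_min, deriv,
                        list(k_ox = kin$k_ox, k_red = kin$k_red),
                        rtol = 1e-8, atol = 1e-14)
  data.frame(time_min = sol[, "time"],
             theta = pmin(pmax(sol[, "TH"], 0), 1))
}

#' Render dual-channel fluorescence from oxidized fraction and pH
#'
#' Applies the channel model of [fluorescence_model()] frame-wise and adds
#' per-frame multiplicative noise (mean-one lognormal with the requested
#' coefficient of variation, so channels stay strictly positive).
#'
#' @param theta oxidized fraction series in \[0, 1\]
#' @param ph pH series (scalar or same length as `theta`)
#' @param fluor a [fluorescence_model()]
#' @param seed optional integer; when given, rendering is reproducible and
#'   the caller's RNG state is left untouched
#' @return data frame with columns `f420`, `f490`
#' @export
render_fluorescence <- function(theta, ph, fluor, seed = NULL) {
  stopifnot(inherits(fluor, "fluorescence_model"))
  if (any(theta < 0 | theta > 1))
    hk_stop("'theta' must lie in [0, 1]", "hyperkin_param_error")
  if (length(ph) == 1L) ph <- rep(ph, length(theta))
  f420 <- fluor$gain420 * (fluor$base420 + fluor$amp420 * theta) *
    protonation_factor(ph, fluor$pKa420)
  f490 <- fluor$gain490 * (fluor$base490 + fluor$amp490 * theta) *
    protonation_factor(ph, fluor$pKa490)
  if (fluor$noise_cv > 0) {
    mults <- with_local_seed(seed, matrix(rlnorm_cv(2L * length(theta),
                                                    fluor$noise_cv),
                                          ncol = 2L))
    f420 <- f420 * mults[, 1L]
    f490 <- f490 * mults[, 2L]
  }
  data.frame(f420 = f420, f490 = f490)
}

#' Simulate a multi-cell biosensor imaging experiment
#'
#' End-to-end forward model: per-cell kinetic and gain heterogeneity
#' (lognormal multipliers with coefficient of variation `cell_cv` on
#' `k_red` and on each channel gain), mechanistic integration of peroxide,
#' oxidized fraction and pH under the schedule, channel rendering with
#' per-frame noise, and a ground-truth table for parameter-recovery studies.
#'
#' @param preset a [compartment_preset()] (or any list with `kinetics`,
#'   `fluor`, `pH` and `name` fields)
#' @param schedule a [protocol_schedule()]
#' @param perturbation optional [perturbation_preset()]; washout-only
#'   presets scale `k_red` only after the final `pulse_end`
#' @param n_cells number of cells (>= 1)
#' @param cell_cv per-cell lognormal coefficient of variation (0 disables
#'   heterogeneity)
#' @param noise_cv per-frame noise cv; default taken from the preset's
#'   fluorescence model, 0 disables noise
#' @param seed integer RNG seed; identical seed and configuration reproduce
#'   the experiment bit-identically
#' @param experiment_id label stored in the trace metadata
#' @param line_label optional cell-line label for the metadata
#' @return object of class `simulated_experiment`: list with `traces`
#'   (list of [acquisition_trace()]), `schedule`, `truth` (data frame with
#'   per-cell true `k_red`, recovery-phase effective `k_red_recovery`, basal
#'   theta, compartment, treatment) and `seed`
#' @export
simulate_experiment <- function(preset, schedule = default_schedule(),
                                perturbation = NULL, n_cells = 30,
                                cell_cv = 0.15, noise_cv = NULL, seed = 1,
                                experiment_id = "sim", line_label = NA) {
  stopifnot(inherits(schedule, "protocol_schedule"))
  if (!is_number(n_cells) || n_cells < 1)
    hk_stop("'n_cells' must be >= 1", "hyperkin_param_error")
  n_cells <- as.integer(n_cells)
  check_nonneg(cell_cv, "cell_cv")
  fluor <- preset$fluor
  if (!is.null(noise_cv)) fluor$noise_cv <- check_nonneg(noise_cv, "noise_cv")
  kin <- preset$kinetics
  segs <- build_segments(schedule, resting_ph = preset$pH, perturbation)
  times <- sample_times_min(schedule)

  with_local_seed(seed, {
    mult_k <- rlnorm_cv(n_cells, cell_cv)
    mult_g420 <- rlnorm_cv(n_cells, cell_cv)
    mult_g490 <- rlnorm_cv(n_cells, cell_cv)
    traces <- vector("list", n_cells)
    truth <- data.frame(cell_id = sprintf("cell%03d", seq_len(n_cells)),
                        k_red = NA_real_, k_red_recovery = NA_real_,
                        basal_theta = NA_real_,
                        compartment = preset$name,
                        treatment = if (is.null(perturbation)) "control"
                                    else perturbation$name,
                        stringsAsFactors = FALSE)
    for (i in seq_len(n_cells)) {
      kin_i <- kin
      kin_i$k_red <- kin$k_red * mult_k[i]
      den <- kin_i$perm + kin_i$cons
      H_b <- if (den > 0) kin_i$prod * segs$prod_mult[1] / den else 0
      th0 <- steady_state_theta(
        list(k_ox = kin_i$k_ox, k_red = kin_i$k_red * segs$k_mult[1]), H_b)
      dyn <- integrate_cell(kin_i, segs, theta0 = th0, ph0 = preset$pH, times)
      fl_i <- fluor
      fl_i$gain420 <- fluor$gain420 * mult_g420[i]
      fl_i$gain490 <- fluor$gain490 * mult_g490[i]
      chans <- render_fluorescence(dyn$theta, dyn$ph, fl_i, seed = NULL)
      traces[[i]] <- acquisition_trace(
        cell_id = truth$cell_id[i],
        time_s = dyn$time_min * 60,
        f420 = chans$f420, f490 = chans$f490,
        metadata = list(experiment_id = experiment_id,
                        cell_line = line_label,
                        compartment = preset$name,
                        treatment = truth$treatment[i],
                        ph = preset$pH))
      # effective rates: at recording start (whole-recording treatments act
      # from t = 0) and during the recovery phase (washout-only ones too)
      truth$k_red[i] <- kin_i$k_red * segs$k_mult[1]
      truth$k_red_recovery[i] <- kin_i$k_red *
        segs$k_mult[nrow(segs)]
      truth$basal_theta[i] <- th0
    }
    structure(list(traces = traces, schedule = schedule, truth = truth,
                   seed = seed, preset = preset,
                   perturbation = perturbation),
              class = "simulated_experiment")
  })
}

#' @export
print.simulated_experiment <- function(x, ...) {
  cat(sprintf("<simulated_experiment> %d cell(s), %s preset, treatment %s\n",
              length(x$traces), x$preset$name,
              unique(x$truth$treatment)))
  cat(sprintf("  %.3g min @ %.3g s/frame, seed %s\n",
              x$schedule$duration_min, x$schedule$sample_interval_s,
              format(x$seed)))
  invisible(x)
}

#' Simulate a pH-clamped biosensor recording
#'
#' Convenience wrapper over [simulate_experiment()] for schedules carrying
#' `ph_clamp_start` events: after the clamp, intracellular pH relaxes
#' exponentially (time constant 0.5 min) to the commanded value, shifting
#' the ratio baseline while leaving the oxidation/reduction kinetics --
#' and hence the fitted recovery rate -- untouched.
#'
#' @inheritParams simulate_experiment
#' @return a `simulated_experiment`
#' @export
simulate_ph_clamp <- function(preset, schedule, n_cells = 30,
                              cell_cv = 0.15, noise_cv = NULL, seed = 1,
                              experiment_id = "phclamp") {
  if (!any(schedule$events$kind == "ph_clamp_start"))
    hk_stop("schedule carries no ph_clamp_start event",
            "hyperkin_schema_error")
  simulate_experiment(preset, schedule, perturbation = NULL,
                      n_cells = n_cells, cell_cv = cell_cv,
                      noise_cv = noise_cv, seed = seed,
                      experiment_id = experiment_id)
}
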