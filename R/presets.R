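# Compartment and perturbation presets.
#
# Kinetic parameters are chosen to reproduce the characteristic behavior of
# each compartment under the standard saturating-pulse protocol; the
# fluorescence amplitudes are then *calibrated* at construction so that the
# noiseless preset reproduces the compartment's documented ratio phenotype
# (basal ratio and fractional ratio increase under 500 uM H2O2) exactly.

# Observable ratio phenotype per compartment: resting-ratio level and the
# fractional ratio increase under a saturating 500 uM pulse. The ER sits
# near-oxidized at rest (highest basal ratio, smallest relative response);
# the cytosol is near-reduced (ratio roughly quadruples); the mitochondrion
# shows an absolute response of ~0.93 ratio units on a basal ratio of ~1.09.
.compartment_phenotype <- list(
  cytosol       = list(basal_ratio = 0.90,        fold_increase = 3.00),
  mitochondrion = list(basal_ratio = 0.93 / 0.85, fold_increase = 0.85),
  ER            = list(basal_ratio = 1.13 / 0.25, fold_increase = 0.25)
)

.compartment_kinetics <- list(
  # near-reduced at rest; membrane equilibration fast relative to k_red so
  # the post-washout decay is governed by reduction alone
  cytosol = list(k_ox = 0.027, k_red = 1.0, perm = 30, prod = 0.3, cons = 3,
                 cons_ind = 0, tau_ind = 1, pH = 7.2),
  # strong, inducible peroxide disposal: theta peaks early in the pulse and
  # then relaxes even while external oxidant persists
  mitochondrion = list(k_ox = 0.03, k_red = 2.0, perm = 2, prod = 0.3,
                       cons = 1.5, cons_ind = 40, tau_ind = 1.5, pH = 7.8),
  # oxidizing folding environment: elevated basal peroxide, slowest reduction
  ER = list(k_ox = 0.03, k_red = 0.15, perm = 6, prod = 6.5, cons = 0.5,
            cons_ind = 0, tau_ind = 1, pH = 7.2)
)

# F420 oxidation amplitude fraction shared by all presets; kept small so the
# ratio is close to affine in theta and the post-washout ratio decay stays
# close to a single exponential in the oxidized fraction.
.AMP420 <- -0.05

# Solve the 490 nm amplitude fraction u so that the rendered ratio satisfies
# r(theta_pk)/r(theta_b) = rho, given the shared 420 nm fraction d:
#   (1 + u theta_pk) (1 + d theta_b) = rho (1 + u theta_b) (1 + d theta_pk)
solve_amp490 <- function(theta_b, theta_pk, rho, d = .AMP420) {
  num <- rho * (1 + d * theta_pk) - (1 + d * theta_b)
  den <- theta_pk * (1 + d * theta_b) - rho * theta_b * (1 + d * theta_pk)
  if (den <= 0 || num <= 0)
    hk_stop("compartment phenotype not representable: response span too small",
            "hyperkin_param_error")
  num / den
}

#' Compartment presets for the biosensor simulator
#'
#' Returns the kinetic and fluorescence parameter bundle characterizing the
#' biosensor in one of three subcellular compartments. Kinetics differ in
#' reduction rate (ER slowest), basal peroxide tone (ER highest) and
#' peroxide disposal (mitochondrion strongly inducible, so its oxidized
#' fraction declines during a sustained pulse). Channel amplitudes are
#' calibrated at construction so the noiseless simulation reproduces each
#' compartment's ratio phenotype under the standard saturating pulse
#' ([single_pulse_schedule()] with default timing): basal ratio ~0.90 with
#' a 300% pulse increase (cytosol), ~1.09 with 85% (mitochondrion, an
#' absolute response of 0.93 ratio units), ~4.5 with 25% (ER).
#'
#' @param name `"cytosol"`, `"mitochondrion"` or `"ER"`
#' @param noise_cv per-frame multiplicative noise coefficient of variation
#' @return object of class `compartment_preset`: list with `name`,
#'   `kinetics` ([kinetic_params()]), `fluor` ([fluorescence_model()]),
#'   `basal_theta` and resting `pH`
#' @export
compartment_preset <- function(name = c("cytosol", "mitochondrion", "ER"),
                               noise_cv = 0.02) {
  name <- match.arg(name)
  kp <- .compartment_kinetics[[name]]
  ph <- .compartment_phenotype[[name]]
  kin <- kinetic_params(kp$k_ox, kp$k_red, kp$perm, kp$prod, kp$cons,
                        kp$cons_ind, kp$tau_ind)
  theta_b <- steady_state_theta(kin, basal_h2o2(kin))
  # oxidized-fraction peak under the standard saturating pulse
  sch <- single_pulse_schedule()
  segs <- build_segments(sch, resting_ph = kp$pH)
  dyn <- integrate_cell(kin, segs, theta0 = theta_b, ph0 = kp$pH,
                        times = sample_times_min(sch))
  pw <- saturating_pulse(sch)
  in_pulse <- dyn$time_min >= pw$start - 1e-9 & dyn$time_min <= pw$end + 1e-9
  theta_pk <- max(dyn$theta[in_pulse])
  rho <- 1 + ph$fold_increase
  u <- solve_amp490(theta_b, theta_pk, rho)
  # absolute basal ratio fixed through the channel gains at resting pH
  gain420 <- 600
  gain490 <- ph$basal_ratio * gain420 *
    protonation_factor(kp$pH, 6.8) * (1 + .AMP420 * theta_b) /
    (protonation_factor(kp$pH, 7.8) * (1 + u * theta_b))
  fluor <- fluorescence_model(gain420 = gain420, gain490 = gain490,
                              base420 = 1, base490 = 1,
                              amp420 = .AMP420, amp490 = u,
                              pKa420 = 6.8, pKa490 = 7.8,
                              noise_cv = noise_cv)
  structure(list(name = name, kinetics = kin, fluor = fluor,
                 basal_theta = theta_b, pH = kp$pH),
            class = "compartment_preset")
}

#' @export
print.compartment_preset <- function(x, ...) {
  cat(sprintf("<compartment_preset> %s  (pH %.2f, basal theta %.3f)\n",
              x$name, x$pH, x$basal_theta))
  print(x$kinetics)
  invisible(x)
}

#' Override the disulfide-reduction rate of a preset
#'
#' Sets `k_red` of a compartment preset, either alone (cell-line variants
#' whose reduction machinery differs while peroxide handling is shared) or
#' by rescaling the whole first-order rate set (`k_ox`, `perm`, `prod`,
#' `cons` and the induction time constant) by the same factor, which leaves
#' every steady state untouched and simply replays the same dynamics on a
#' faster or slower clock. Time rescaling is the natural way to reach
#' regimes where recovery completes in seconds.
#'
#' @param preset a [compartment_preset()]
#' @param k_red new disulfide-reduction rate (per min)
#' @param time_rescale if `TRUE`, rescale all rates by `k_red / old k_red`
#' @return the modified preset
#' @export
set_recovery_rate <- function(preset, k_red, time_rescale = FALSE) {
  check_pos(k_red, "k_red")
  f <- k_red / preset$kinetics$k_red
  kin <- preset$kinetics
  if (time_rescale) {
    kin$k_ox <- kin$k_ox * f
    kin$perm <- kin$perm * f
    kin$prod <- kin$prod * f
    kin$cons <- kin$cons * f
    kin$tau_ind <- kin$tau_ind / f
  }
  kin$k_red <- k_red
  preset$kinetics <- kin
  preset$basal_theta <- steady_state_theta(kin, basal_h2o2(kin))
  preset
}

# printed control/treated recovery-rate ratios behind the perturbation scales
.perturbations <- list(
  auranofin10  = list(k_red_scale = 1,           prod_scale = 1,
                      applies_during = "whole-recording"),
  auranofin100 = list(k_red_scale = 13.7 / 41.8, prod_scale = 1,
                      applies_during = "whole-recording"),
  px12_1uM     = list(k_red_scale = 38.8 / 88.5, prod_scale = 1,
                      applies_during = "washout-only"),
  px12_10uM    = list(k_red_scale = 25.8 / 88.5, prod_scale = 1,
                      applies_during = "washout-only"),
  euk134       = list(k_red_scale = 1,           prod_scale = 0.5,
                      applies_during = "whole-recording"),
  nac          = list(k_red_scale = 1.7,         prod_scale = 1,
                      applies_during = "whole-recording")
)

#' Pharmacological perturbation presets
#'
#' Multiplicative perturbations of the kinetic parameters modelling drug
#' treatments of the antioxidant machinery: auranofin (selenoenzyme
#' disruption; 100 nM cuts the reduction rate to about a third, 10 nM has
#' no effect), PX-12 (thioredoxin-1 inhibition, applied only during washout
#' because prolonged exposure is cytotoxic), EUK-134 (SOD/catalase mimetic:
#' halves basal peroxide production, leaves reduction untouched) and NAC
#' (cysteine donor: accelerates reduction 1.7-fold, reversibly -- combine
#' with `treatment_start`/`treatment_end` schedule events to model washout
#' of the treatment itself).
#'
#' @param name one of `"auranofin10"`, `"auranofin100"`, `"px12_1uM"`,
#'   `"px12_10uM"`, `"euk134"`, `"nac"`
#' @return object of class `perturbation_preset` with fields `name`,
#'   `k_red_scale`, `prod_scale`, `applies_during`
#' @export
perturbation_preset <- function(name = names(.perturbations)) {
  name <- match.arg(name)
  p <- .perturbations[[name]]
  structure(list(name = name, k_red_scale = p$k_red_scale,
                 prod_scale = p$prod_scale,
                 applies_during = p$applies_during),
            class = "perturbation_preset")
}

#' @export
print.perturbation_preset <- function(x, ...) {
  cat(sprintf("<perturbation_preset> %s: k_red x%.3g, prod x%.3g (%s)\n",
              x$name, x$k_red_scale, x$prod_scale, x$applies_during))
  invisible(x)
}

#' Default ten-line cohort of cytosolic recovery rates
#'
#' Ten human cell lines with their cytosolic disulfide-reduction rates used
#' by the cohort simulator. Three rates are anchored to characterized lines
#' (A549 1.35, DU145 0.89, A704 0.28 per min); the remaining seven are
#' synthetic placements spread across the same range.
#'
#' @return data frame with columns `cell_line` and `k_red` (per min)
#' @export
cell_line_presets <- function() {
  data.frame(
    cell_line = c("A704", "Caco-2", "HepG2", "CCD-1068SK", "MCF-7",
                  "SVGp12", "CCD1102KERTr", "DU145", "TIME", "A549"),
    k_red = c(0.28, 0.35, 0.45, 0.55, 0.65, 0.75, 0.85, 0.89, 1.10, 1.35),
    stringsAsFactors = FALSE
  )
}
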