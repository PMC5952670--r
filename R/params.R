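#' Kinetic parameters of the biosensor/peroxide system
#'
#' Bundles the first-order rate constants that govern intracellular H2O2
#' handling and biosensor disulfide chemistry. Canonical units are minutes
#' and micromolar throughout the package.
#'
#' The mechanistic model is
#' \deqn{dH_i/dt = perm (H_e(t) - H_i) + prod - cons_{eff}(t) H_i}
#' \deqn{d\theta/dt = k_{ox} H_i (1 - \theta) - k_{red} \theta}
#' where \eqn{H_e(t)} is the scheduled extracellular peroxide profile and
#' \eqn{\theta} the oxidized biosensor fraction. `cons_ind > 0` adds an
#' inducible component to peroxide consumption,
#' \eqn{cons_{eff} = cons (1 + cons_{ind} a(t))} with activation
#' \eqn{da/dt = (s - a)/\tau_{ind}}, \eqn{s = 1} while oxidant is present.
#' This models adaptive up-regulation of the peroxide disposal system and is
#' what lets the mitochondrial preset relax while the external pulse is
#' still applied; with the default `cons_ind = 0` consumption is constant.
#'
#' @param k_ox second-order biosensor oxidation rate (per uM per min)
#' @param k_red disulfide-reduction rate of the oxidized biosensor (per min);
#'   the quantity the recovery fit estimates
#' @param perm membrane H2O2 equilibration rate (per min)
#' @param prod basal intracellular H2O2 production (uM per min)
#' @param cons basal intracellular H2O2 consumption rate (per min)
#' @param cons_ind fold-increase of consumption at full induction
#'   (dimensionless, >= 0; 0 disables induction)
#' @param tau_ind induction time constant (min)
#' @return object of class `kinetic_params`
#' @examples
#' kinetic_params(k_ox = 0.027, k_red = 1, perm = 3, prod = 0.1, cons = 1)
#' @export
kinetic_params <- function(k_ox, k_red, perm = 0, prod = 0, cons = 0,
                           cons_ind = 0, tau_ind = 1) {
  kp <- list(
    k_ox = check_nonneg(k_ox, "k_ox"),
    k_red = check_nonneg(k_red, "k_red"),
    perm = check_nonneg(perm, "perm"),
    prod = check_nonneg(prod, "prod"),
    cons = check_nonneg(cons, "cons"),
    cons_ind = check_nonneg(cons_ind, "cons_ind"),
    tau_ind = check_pos(tau_ind, "tau_ind")
  )
  structure(kp, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>  (min, uM)\n")
  cat(sprintf("  k_ox %.4g /uM/min   k_red %.4g /min\n", x$k_ox, x$k_red))
  cat(sprintf("  perm %.4g /min   prod %.4g uM/min   cons %.4g /min\n",
              x$perm, x$prod, x$cons))
  if (x$cons_ind > 0)
    cat(sprintf("  inducible consumption: x%.3g fold, tau %.3g min\n",
                1 + x$cons_ind, x$tau_ind))
  invisible(x)
}

#' Steady-state oxidized biosensor fraction
#'
#' At constant intracellular peroxide `H`, oxidation and reduction balance at
#' \eqn{\theta_{ss} = k_{ox} H / (k_{ox} H + k_{red})}.
#'
#' @param kin a [kinetic_params()] object
#' @param H intracellular H2O2 concentration (uM), vectorized
#' @return steady-state oxidized fraction in \[0, 1)
#' @export
steady_state_theta <- function(kin, H) {
  num <- kin$k_ox * H
  den <- num + kin$k_red
  ifelse(den == 0, 0, num / den)
}

# Basal intracellular peroxide: with no external oxidant the membrane term
# exports peroxide too, so production balances export + consumption.
basal_h2o2 <- function(kin) {
  den <- kin$perm + kin$cons
  if (den > 0) kin$prod / den else 0
}

#' Channel rendering model for a dual-excitation ratiometric biosensor
#'
#' Maps oxidized fraction and pH onto the two excitation channels. Each
#' channel is rendered as
#' `gain * (base + amp * theta) * f(pH, pKa)` with the Henderson-Hasselbalch
#' deprotonated fraction `f(pH, pKa) = 1 / (1 + 10^(pKa - pH))`, so oxidation
#' moves the channels reciprocally (`amp420 < 0 < amp490`) while pH rescales
#' each channel and hence shifts the ratio baseline without touching the
#' oxidation kinetics.
#'
#' @param gain420,gain490 channel gains (arbitrary units, > 0)
#' @param base420,base490 reduced-state brightness fractions (> 0)
#' @param amp420,amp490 oxidation-driven signed amplitude fractions;
#'   `amp420` must be negative and `amp490` positive (reciprocal response),
#'   with `base + amp > 0` so channels stay positive at full oxidation
#' @param pKa420,pKa490 channel protonation midpoints (pH units)
#' @param noise_cv per-frame multiplicative noise coefficient of variation
#' @return object of class `fluorescence_model`
#' @export
fluorescence_model <- function(gain420, gain490, base420 = 1, base490 = 1,
                               amp420, amp490, pKa420 = 6.8, pKa490 = 7.8,
                               noise_cv = 0.02) {
  check_pos(gain420, "gain420"); check_pos(gain490, "gain490")
  check_pos(base420, "base420"); check_pos(base490, "base490")
  if (!is_number(amp420) || amp420 >= 0)
    hk_stop("'amp420' must be negative (420 nm channel dims on oxidation)",
            "hyperkin_param_error")
  if (!is_number(amp490) || amp490 <= 0)
    hk_stop("'amp490' must be positive (490 nm channel brightens on oxidation)",
            "hyperkin_param_error")
  if (base420 + amp420 <= 0 || base490 + amp490 <= 0)
    hk_stop("channel brightness must stay positive at full oxidation",
            "hyperkin_param_error")
  check_nonneg(noise_cv, "noise_cv")
  structure(list(gain420 = gain420, gain490 = gain490,
                 base420 = base420, base490 = base490,
                 amp420 = amp420, amp490 = amp490,
                 pKa420 = pKa420, pKa490 = pKa490,
                 noise_cv = noise_cv),
            class = "fluorescence_model")
}

#' @export
print.fluorescence_model <- function(x, ...) {
  cat("<fluorescence_model>\n")
  cat(sprintf("  gains 420/490: %.4g / %.4g   amp: %+.3f / %+.3f\n",
              x$gain420, x$gain490, x$amp420, x$amp490))
  cat(sprintf("  pKa 420/490: %.2f / %.2f   noise cv %.3g\n",
              x$pKa420, x$pKa490, x$noise_cv))
  invisible(x)
}
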