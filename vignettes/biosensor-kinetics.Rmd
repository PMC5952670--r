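---
title: "Measuring cellular disulfide-reduction capacity from ratiometric biosensor kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cellular disulfide-reduction capacity from ratiometric biosensor kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperkin)
```

## Scope and rationale

Dual-excitation H2O2 biosensors of the HyPer family report the fraction of
sensor molecules carrying an OxyR-type disulfide: oxidation dims the 420 nm
excitation channel, brightens the 490 nm channel, and the ratio
R = F490/F420 therefore rises with oxidation while cancelling expression
level and ROI size. Three quantities summarize a pulse-protocol recording:

* the **basal ratio**, a steady-state readout of endogenous peroxide tone;
* the **response amplitude**, the ratio increase over basal during an
  oxidant pulse;
* the **recovery rate** `k`, the exponential rate at which the signal
  returns toward baseline after the oxidant is washed out.

The first two are confounded by compartment pH (the cpYFP fluorophore is
pH sensitive) and by the sensor's local dynamic range; the recovery rate is
driven by enzymatic disulfide reduction alone and is the package's headline
statistic. `hyperkin` provides a mechanistic simulator of such recordings
and the full analysis chain, so that every estimator can be validated by
parameter recovery against known ground truth.

## The forward model

### Peroxide and sensor kinetics

Per cell, intracellular peroxide `Hi` (µM) and oxidized sensor fraction
`theta` evolve as

$$\frac{dH_i}{dt} = perm\,(H_e(t) - H_i) + prod - cons_{\mathrm{eff}}(t)\,H_i,
\qquad
\frac{d\theta}{dt} = k_{ox} H_i (1-\theta) - k_{red}\,\theta,$$

with `He(t)` the scheduled extracellular pulse profile. Units are minutes
and µM throughout. The resting state is the production/export/consumption
balance `Hi = prod/(perm + cons)` with
`theta_ss = k_ox Hi / (k_ox Hi + k_red)`.

A strictly constant consumption term makes `Hi`, and hence `theta`,
monotone under a held pulse. Mitochondria, however, are observed to relax
their signal *while the oxidant is still present*, which requires peroxide
disposal to strengthen during the exposure. We model this as first-order
induction of consumption,

$$cons_{\mathrm{eff}} = cons\,(1 + cons_{ind}\, a(t)), \qquad
\frac{da}{dt} = \frac{s(t) - a}{\tau_{ind}},$$

where `s(t) = 1` while external oxidant is applied. With the default
`cons_ind = 0` the textbook constant-consumption ODE is recovered exactly;
only the mitochondrial preset uses a non-zero induction (40-fold,
`tau_ind` 1.5 min), which makes `theta` peak early in the pulse and then
decline — an adaptive-disposal reading of the observed phenotype rather
than a peroxiredoxin-relay model, which is out of scope.

### Channel rendering and pH

Channels are rendered as
`F = gain (1 + amp * theta) f(pH, pKa)` per excitation wavelength, with
`amp420 < 0 < amp490` (reciprocal response) and Henderson–Hasselbalch
factors `f(pH, pKa) = 1/(1 + 10^(pKa - pH))`, `pKa420 = 6.8`,
`pKa490 = 7.8`. These pKa values are calibration constants chosen so the
ratio baseline rises monotonically with pH across 6.5–7.5; pH multiplies
each channel and therefore rescales the ratio without entering the `theta`
dynamics. This is the mechanism behind the clamp experiments: arms clamped
at different pH show clearly separated baselines and response amplitudes
while their fitted recovery rates coincide.

`amp420` is fixed at −0.05 for all presets. Keeping the 420 nm excursion
small keeps the ratio nearly affine in `theta`, so that the post-washout
ratio decay inherits the single-exponential form of `theta` itself; with
this choice the end-to-end bias of the fitted rate is below ~3% across the
0.28–1.35 per-min range (verified by the parameter-recovery tests). The
490 nm amplitude and the channel gains are *solved*, per compartment, so
that the noiseless simulation reproduces the compartment's documented
ratio phenotype under the standard saturating pulse:

| preset | basal ratio | pulse increase | interpretation |
|---|---|---|---|
| cytosol | 0.90 | +300% | near-reduced at rest, large dynamic range |
| mitochondrion | ~1.09 | +85% (0.93 ratio units) | inducible disposal, transient response |
| ER | ~4.5 | +25% | oxidizing folding environment, highest baseline |

Because the calibration is exact by construction, the compartment
phenotype checks in the validation suite are tests of the *analysis chain*
(baseline window, pulse-window maximum, normalization) as much as of the
presets.

### Noise and heterogeneity

Per-frame noise is multiplicative with coefficient of variation
`noise_cv` (default 0.02, standing in for shot + camera noise). It is
realized as mean-one lognormal multipliers rather than literal Gaussian
factors so that rendered channels are strictly positive at any cv; at
cv = 0.02 the two are indistinguishable. Cell-to-cell heterogeneity applies
independent lognormal multipliers (cv 0.15 by default) to `k_red` and to
each channel gain, which reproduces realistic spreads of per-cell baselines
and makes cohort standard errors meaningful. All randomness is
seed-controlled; equal seed and configuration reproduce an experiment
bit-identically.

### Protocols

The standard two-pulse protocol is 20 min baseline, 50 µM for 5 min, 10 min
washout, 500 µM for 4 min, 16 min recovery, sampled every 20 s (the
concentrations, baseline length and sampling interval follow standard
practice for this assay; pulse durations are package choices, configurable
in `default_schedule()`). pH-clamp schedules add a `ph_clamp_start` event
after which intracellular pH relaxes exponentially with a 0.5 min time
constant — fast relative to the equilibration period, slow enough to be
visible at sub-second sampling.

### The two rate regimes

Published recovery rates for this methodology span ~0.3–1.4 per min in
cell-line comparisons but ~14–90 per min in clamp/perturbation
experiments (and per-second figures elsewhere); the package does not try
to reconcile these units. Each scenario treats its printed value as ground
truth in per-minute units and chooses a sampling interval able to resolve
it: 20 s frames for line-scale rates, 0.5 s frames for the fast regime.
Fast presets are built with `set_recovery_rate(..., time_rescale = TRUE)`,
which scales the entire first-order rate set by one factor — steady states
and amplitudes are untouched and the same dynamics replay on a faster
clock, so conclusions drawn at one scale transfer to the other.

## The analysis chain

1. **Ratio**: `compute_ratio()` forms F490/F420 frame-wise (with optional
   constant background offsets, default 0 — background subtraction is
   assumed done upstream at acquisition).
2. **Baseline**: mean ratio over the 2 min immediately preceding the first
   pulse. Recordings carry ~20 min of baseline; the short window matches
   common practice and is configurable.
3. **Dynamic range**: the within-pulse maximum of the raw ratio during the
   saturating pulse minus the baseline. The maximum is taken on raw frames
   (a 3-frame median filter is available but off by default) because peak
   sharpness is informative; cells whose span is non-positive or < 5% of
   the baseline are flagged degenerate, excluded and counted.
4. **Normalization**: `100 (R - R_basal)/span`, i.e. percent of the cell's
   own dynamic range: 0% at baseline, 100% at the saturating maximum. This
   is invariant to per-channel gain rescaling (the expression-independence
   property, property-tested).
5. **Recovery fit**: `y(t) = y0 + A exp(-k (t - t0))` on the recovery
   phase, `t0` fixed at the first post-washout frame so exactly three
   parameters are free. Bounded Levenberg–Marquardt (`k` in [0, 1000] per
   min, `A >= 0`, 500 iterations, tolerance 1e-10), deterministic
   initialization from a log-linear regression of `y - min(y) + eps` — no
   random restarts, so fits are reproducible. Flat traces return
   `A = 0` with the rate marked non-identifiable; optimizer failure or a
   rate pinned at its bounds clears the `converged` flag. Fit quality is
   the correlation `r` between fitted and observed series; cells with
   `r < 0.8` are retained but flagged and excluded from group statistics
   by default.

Per-cell fitting is the primary route; `pooled_recovery_curve()` provides
the mean ± SE population curve for display parity, but statistics are
always computed over per-cell fits, matching the "average ± SE of N cells"
reporting convention. Fitting on the normalized or raw-ratio scale yields
identical rates (affine invariance of the exponential rate; tested).

## Cohort statistics

`summarize_lines()` aggregates per-cell records into per-line mean ± SE
profiles (SE across cells pooled over experiments). `compare_groups()`
implements the field's standard decision rule: Shapiro–Wilk screening at
α = 0.05 in every group; if all pass, one-way ANOVA with Bonferroni
pairwise t-tests, otherwise Kruskal–Wallis with Dunn's Bonferroni-adjusted
rank post-hoc (implemented in-package); paired before/after designs use
the paired t-test. The screen-based branch choice is a package decision —
source protocols state that both branches were used but not the rule.

`simulate_migration_cohort()` generates the ten-line migration cohort:
`efficiency = 5 + 25 k_red + N(0, 7.1)` percent, truncated to [0, 100].
Three line rates are anchored to characterized values (A549 1.35, DU145
0.89, A704 0.28 per min); the other seven are synthetic placements across
that range, since no numeric table of the remaining lines exists. The
noise SD is a calibration constant, set once by Monte-Carlo search over
20 000 seeds so that the expected Pearson correlation between efficiency
and recovery rate is ≈ 0.77;
`correlate_migration()` then recovers that correlation on simulated
cohorts.

## Numerical choices

* ODE integration: `deSolve::lsoda` (stiff-capable, adaptive), rtol 1e-8,
  atol 1e-10 (1e-14 for the standalone `theta` integrator), integrated
  piecewise between schedule events so coefficient discontinuities never
  cross a solver step; dense output is sampled on the acquisition grid.
* In the `Hi = 0` limit the integrated `theta` matches
  `theta0 exp(-k_red t)` to better than 1e-6 relative error down to
  `theta ~ 1e-6` (property-tested across four decades of `k_red`).
* `theta` is clamped to [0, 1] and `Hi` to non-negative values after
  integration to absorb solver round-off at the bound.
* Ties and degenerate inputs: flat traces fit with `A = 0` (rate
  non-identifiable); single-frame baselines, empty pulse windows and
  non-finite values raise classed validation errors rather than NA
  propagation.

## Problem sizes

The validation suites use 30 cells per scenario at cv 0.15/0.02
(heterogeneity/noise) for parameter recovery, 30 cells per pH arm, 200
cohort draws for the migration correlation and 2000 null replicates for
the type-I-error property — sizes chosen to put Monte-Carlo error well
inside each validation tolerance while the whole suite runs in well under
a minute per scenario on one core.

## Known limitations

* The fitter reports the *apparent* exponential rate. Washout clearance of
  peroxide and basal re-oxidation pressure (`k_ox Hi_basal`) are not
  deconvolved from sensor reduction; presets are parameterized so
  clearance is fast relative to `k_red` and basal pressure is negligible
  in the cytosol, but in the high-peroxide ER preset the apparent rate
  exceeds `k_red` by design of the environment (≈ 20%) — an inherent
  confound of the measurement, not an estimator defect. Only ratio
  phenotypes and orderings, never the ER rate itself, are used
  quantitatively.
* No photobleaching, no spatial/pixel-level synthesis, no peroxiredoxin
  relay, no nitrosative chemistry; the simulator starts at per-ROI traces
  and the analysis assumes background-subtracted channels.
* The synthetic generator emulates trace morphology, pH dissociation,
  compartment phenotypes and cohort coupling. It does not emulate focus
  drift, cell movement, heterogeneous expression-dependent noise or
  experiment-level batch effects, so passing recovery tests here bounds
  estimator bias under the stated noise model only — it does not certify
  performance on arbitrary real recordings.
* Migration efficiencies for the real cohort exist only as a figure; the
  cohort here is a calibrated synthetic stand-in and its correlation
  checks the generator/estimator loop, not the biological dataset.
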