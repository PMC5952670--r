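# hyperkin

Simulation and kinetic analysis of ratiometric hydrogen peroxide biosensor
recordings.

## The problem

Genetically encoded H2O2 biosensors such as HyPer report intracellular
oxidation through a dual-excitation readout: oxidation of the sensor's
OxyR-derived disulfide dims the 420 nm excitation channel and brightens the
490 nm channel, so the ratio R = F490/F420 tracks the oxidized sensor
fraction independently of expression level. Because the fluorophore (a
circularly permuted YFP) is intrinsically pH sensitive, the absolute ratio
confounds oxidation with pH — but the *rate* at which the signal recovers
after an oxidant pulse is washed out reflects only the cell's
disulfide-reduction machinery (thioredoxin/glutathione systems) and is
pH-independent. That recovery rate is a quantitative, live-cell measure of
antioxidant capacity, and it predicts functional phenotypes such as
transwell migration efficiency.

`hyperkin` packages both sides of this methodology:

* a **mechanistic forward simulator** of single-cell recordings under pulse
  protocols, with compartment presets (cytosol, mitochondrion, ER),
  ionophore pH clamps and pharmacological perturbations
  (auranofin, PX-12, EUK-134, NAC);
* the **analysis chain** that turns dual-channel traces into per-cell
  statistics: ratio computation, baseline estimation, dynamic-range
  normalization, protocol phase segmentation and a three-parameter
  exponential fit of the post-washout recovery;
* **cohort statistics**: per-line profiles, ANOVA/Bonferroni or
  Kruskal–Wallis/Dunn group comparisons, and the Pearson correlation of
  recovery rate with migration efficiency.

## The model

Intracellular peroxide and the oxidized sensor fraction θ follow

    dHi/dt = perm (He(t) − Hi) + prod − cons_eff(t) Hi
    dθ/dt  = k_ox Hi (1 − θ) − k_red θ

with He(t) the scheduled extracellular pulse profile (µM) and, optionally,
inducible consumption `cons_eff = cons (1 + cons_ind a(t))` modelling
adaptive peroxide disposal (this is what makes the mitochondrial signal
decline while the oxidant is still present). Channels are rendered as

    F420 = g420 (1 + a420 θ) f(pH, pKa420),  a420 < 0
    F490 = g490 (1 + a490 θ) f(pH, pKa490),  a490 > 0

with Henderson–Hasselbalch factors f(pH, pKa) = 1/(1 + 10^(pKa − pH)), so pH
shifts the ratio baseline without touching the θ kinetics. After washout
Hi ≈ 0 and θ decays as θ_w e^(−k_red t); the analysis chain fits

    y(t) = y0 + A exp(−k (t − t0))

to the recovery phase by bounded Levenberg–Marquardt least squares, and the
fitted k estimates k_red. All rates are per minute, concentrations µM.

## Worked example

```r
library(hyperkin)

preset <- compartment_preset("cytosol")       # calibrated cytosolic preset
a549   <- set_recovery_rate(preset, 1.35)     # fast-recovering line
exp    <- simulate_experiment(a549, default_schedule(), n_cells = 5,
                              cell_cv = 0.15, noise_cv = 0.02, seed = 42,
                              line_label = "A549")
results <- analyze_experiment(exp)
results[, c("cell_id", "r_basal", "delta_r_50", "delta_r_500", "k", "r_fit")]
#>   cell_id r_basal delta_r_50 delta_r_500    k r_fit
#> 1 cell001   1.114      1.632        3.55 1.64 0.998
#> 2 cell002   1.009      1.682        3.10 1.23 0.998
#> 3 cell003   0.755      1.224        2.25 1.40 0.998
#> 4 cell004   0.647      0.982        2.02 1.44 0.998
#> 5 cell005   0.907      1.418        2.68 1.41 0.998
```

Each row is one cell: `r_basal` is the 2-min pre-pulse ratio average,
`delta_r_50`/`delta_r_500` the ratio increases over basal during the 50 and
500 µM pulses, `k` the fitted recovery rate (per min; the cells were drawn
around a true rate of 1.35 with 15% cell-to-cell spread) and `r_fit` the
fit quality. The same fit is available directly:

```r
rt  <- compute_ratio(exp$traces[[1]])
fit <- fit_exponential_recovery(
  normalize_trace(rt, dynamic_range(rt, exp$schedule)),
  seg = segment_phases(exp$schedule))
fit
#> <recovery_fit> k = 1.636 /min, A = 88.76, y0 = -0.08248 (r = 0.998, n = 49)
```

Cohort level — ten synthetic lines whose migration efficiency is coupled to
their recovery rate:

```r
coh <- simulate_migration_cohort(seed = 42)
correlate_migration(coh[, c("cell_line", "recovery_rate")],
                    coh[, c("cell_line", "migration_efficiency")])
#> <correlation_result> Pearson r = 0.838 (p = 0.00247, n = 10); fit y = 7.56 + 26.8 x
```

A command-line front end over the same functions lives at
`inst/cli/hyperkin.R` (`simulate`, `analyze`, `stats`, `full` subcommands);
see the pipeline section of the vignette.

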