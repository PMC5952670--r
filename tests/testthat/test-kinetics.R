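test_that("phase segmentation maps the default protocol onto its intervals", {
  seg <- segment_phases(default_schedule())
  expect_equal(seg$baseline, c(0, 20))
  expect_equal(seg$pulse1, c(20, 25))
  expect_equal(seg$washout1, c(25, 35))
  expect_equal(seg$pulse2, c(35, 39))
  expect_equal(seg$recovery, c(39, 55))
  expect_equal(seg$conc1, 50)
  expect_equal(seg$conc2, 500)

  one <- segment_phases(single_pulse_schedule())
  expect_null(one$pulse2)
  expect_equal(one$recovery, c(24, 40))

  # a pulse scheduled beyond the recorded frames is an error
  expect_error(segment_phases(default_schedule(), trace_times = seq(0, 30, 1 / 3)),
               class = "hyperkin_validation_error")
})

test_that("response amplitudes are window maxima relative to basal", {
  sch <- single_pulse_schedule(baseline_min = 4, pulse_min = 2,
                               recovery_min = 4)
  vals <- c(rep(1, 12), 1.2, 1.4, 1.35, 1.3, 1.25, 1.2, 1.15,
            rep(1.05, 12))
  rt <- compute_ratio(ratio_fixture_trace(vals))
  seg <- segment_phases(sch)
  resp <- response_amplitude(rt, seg, r_basal = 1.0)
  expect_equal(resp$delta_r_50, 0.4, tolerance = 1e-12)
  expect_equal(resp$delta_r_500, 0.4, tolerance = 1e-12)  # single-pulse protocol
  flat <- compute_ratio(ratio_fixture_trace(rep(1, 31)))
  respf <- response_amplitude(flat, seg, r_basal = 1.0)
  expect_equal(respf$delta_r_50, 0)
  expect_equal(respf$delta_r_500, 0)
})

test_that("rise plateau time is the first 95% crossing of the pulse-1 maximum", {
  p <- get_preset("cytosol")
  ex <- simulate_experiment(p, default_schedule(), n_cells = 1, cell_cv = 0,
                            noise_cv = 0, seed = 1)
  res <- analyze_experiment(ex)
  expect_gt(res$t_plateau_50, 0.5)
  expect_lt(res$t_plateau_50, 4)   # plateau reached within a few minutes
})

test_that("three-parameter exponential fit recovers closed-form data to 1e-6", {
  tt <- seq(0, 15, by = 1 / 3)                 # 20 s sampling over 15 min
  y <- 10 + 90 * exp(-0.5 * tt)
  fit <- fit_exponential_recovery(tt, y)
  expect_true(fit$converged)
  expect_equal(fit$k, 0.5, tolerance = 1e-6)
  expect_equal(fit$y0, 10, tolerance = 1e-5)
  expect_equal(fit$A, 90, tolerance = 1e-5)
  expect_gt(fit$r, 0.999999)
})

test_that("degenerate and invalid recovery inputs follow the fit contract", {
  tt <- seq(0, 10, by = 0.5)
  flat <- fit_exponential_recovery(tt, rep(3.3, length(tt)))
  expect_true(flat$converged)
  expect_false(flat$identifiable)
  expect_equal(flat$A, 0)
  expect_true(is.na(flat$k))

  expect_error(fit_exponential_recovery(0:3, c(1, 2, 3, 4)),
               class = "hyperkin_validation_error")
  expect_error(fit_exponential_recovery(tt, c(NA, rep(1, length(tt) - 1))),
               class = "hyperkin_validation_error")
})

test_that("fitted rate is invariant to the scale of the recovery signal", {
  p <- get_preset("cytosol")
  ex <- simulate_experiment(p, default_schedule(), n_cells = 1, cell_cv = 0,
                            noise_cv = 0.02, seed = 8)
  on_pct <- analyze_experiment(ex, fit_on = "percent")
  on_ratio <- analyze_experiment(ex, fit_on = "ratio")
  expect_equal(on_pct$k, on_ratio$k, tolerance = 1e-6)
})

test_that("pooled recovery curves average cells on a common grid", {
  sch <- single_pulse_schedule(baseline_min = 4, pulse_min = 2,
                               recovery_min = 4)
  seg <- segment_phases(sch)
  mk <- function(shift) {
    vals <- c(rep(1, 12), 1.5, 3, 2.8, 2.4, 2.0, 1.7,
              1.5 + shift, 1.4 + shift, 1.3 + shift, 1.25 + shift,
              1.2 + shift, 1.18 + shift, rep(1.15 + shift, 7))
    rt <- compute_ratio(ratio_fixture_trace(vals))
    normalize_trace(rt, dynamic_range(rt, sch))
  }
  same <- pooled_recovery_curve(list(mk(0), mk(0)), seg)
  expect_true(all(same$se == 0))
  offset <- pooled_recovery_curve(list(mk(0), mk(0.2)), seg)
  mid <- (mk(0)$percent + mk(0.2)$percent) / 2
  sel <- mk(0)$time_min >= seg$recovery[1]
  expect_equal(offset$mean, mid[sel])
  expect_error(pooled_recovery_curve(list(mk(0)), seg),
               class = "hyperkin_validation_error")
})

test_that("pooled simulated recovery decays after washout", {
  p <- get_preset("cytosol")
  sch <- single_pulse_schedule(recovery_min = 10)
  ex <- simulate_experiment(p, sch, n_cells = 15, cell_cv = 0.1,
                            noise_cv = 0.02, seed = 21)
  seg <- segment_phases(sch)
  nts <- lapply(ex$traces, function(tr) {
    rt <- compute_ratio(tr)
    normalize_trace(rt, dynamic_range(rt, sch))
  })
  curve <- pooled_recovery_curve(nts, seg)
  n <- nrow(curve)
  expect_gt(mean(curve$mean[1:5]), mean(curve$mean[(n - 4):n]) + 30)
  # noise-smoothed: coarse 2-min bins decrease monotonically
  bins <- tapply(curve$mean, cut(curve$time_min, 5), mean)
  expect_true(all(diff(bins) < 0))
})
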