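test_that("intracellular H2O2 follows the closed-form linear-ODE solutions", {
  # decoupled cell: no production, consumption or membrane exchange
  sch <- single_pulse_schedule()
  kin0 <- kinetic_params(k_ox = 0, k_red = 1, perm = 0, prod = 0, cons = 0)
  h <- simulate_h2o2_intracellular(sch, kin0)
  expect_true(all(h$h2o2_uM == 0))

  # production/consumption balance without membrane exchange
  quiet <- protocol_schedule(data.frame(t_min = numeric(0),
                                        kind = character(0)),
                             duration_min = 120, sample_interval_s = 60)
  kin1 <- kinetic_params(k_ox = 0, k_red = 1, perm = 0, prod = 0.1, cons = 0.1)
  h1 <- simulate_h2o2_intracellular(quiet, kin1)
  expect_equal(tail(h1$h2o2_uM, 1), 1.0, tolerance = 1e-6)

  # held external step: plateau at perm*He/(perm+cons)
  held <- protocol_schedule(data.frame(t_min = 0, kind = "pulse_start",
                                       conc_uM = 500, ph = NA),
                            duration_min = 10, sample_interval_s = 20)
  kin2 <- kinetic_params(k_ox = 0, k_red = 1, perm = 10, prod = 0, cons = 2)
  h2 <- simulate_h2o2_intracellular(held, kin2)
  expect_equal(tail(h2$h2o2_uM, 1), 10 * 500 / 12, tolerance = 1e-6)
})

test_that("negative rates and out-of-range theta0 are rejected", {
  expect_error(kinetic_params(k_ox = -1, k_red = 1),
               class = "hyperkin_param_error")
  hz <- data.frame(time_min = 0:10, h2o2_uM = 0)
  expect_error(simulate_oxidized_fraction(hz, kinetic_params(0.01, 1),
                                          theta0 = 1.2),
               class = "hyperkin_param_error")
})

test_that("oxidized fraction matches the exponential closed form when H = 0", {
  hz <- data.frame(time_min = seq(0, 5, by = 1 / 3), h2o2_uM = 0)
  kin <- kinetic_params(k_ox = 0.01, k_red = 1)
  th <- simulate_oxidized_fraction(hz, kin, theta0 = 0.8)
  expected <- 0.8 * exp(-hz$time_min)
  expect_lt(max(abs(th$theta - expected) / expected), 1e-6)
  expect_equal(th$theta[hz$time_min == 1], 0.8 * exp(-1), tolerance = 1e-6)
})

test_that("oxidized fraction reaches the algebraic steady state under held H2O2", {
  hz <- data.frame(time_min = seq(0, 30, by = 0.25), h2o2_uM = 500)
  kin <- kinetic_params(k_ox = 0.01, k_red = 1)
  th <- simulate_oxidized_fraction(hz, kin, theta0 = 0)
  expect_equal(tail(th$theta, 1), 5 / 6, tolerance = 1e-6)
  expect_equal(steady_state_theta(kin, 500), 5 / 6)
})

test_that("state trajectories respect physical bounds on dense output", {
  sch <- default_schedule()
  for (nm in c("cytosol", "mitochondrion", "ER")) {
    p <- get_preset(nm)
    h <- simulate_h2o2_intracellular(sch, p$kinetics)
    expect_true(all(h$h2o2_uM >= 0))
    th <- simulate_oxidized_fraction(h, p$kinetics, theta0 = p$basal_theta)
    expect_true(all(th$theta >= 0 & th$theta <= 1))
  }
})

test_that("mitochondrial oxidized fraction peaks and then declines during a sustained pulse", {
  p <- get_preset("mitochondrion")
  sch <- single_pulse_schedule()
  h <- simulate_h2o2_intracellular(sch, p$kinetics)
  th <- simulate_oxidized_fraction(h, p$kinetics, theta0 = p$basal_theta)
  in_pulse <- th$time_min >= 20 & th$time_min <= 24
  theta_p <- th$theta[in_pulse]
  i_peak <- which.max(theta_p)
  expect_lt(i_peak, length(theta_p))          # peak strictly inside the pulse
  expect_lt(theta_p[length(theta_p)], 0.6 * max(theta_p))  # clear decline
})

test_that("channel rendering is reciprocal, positive and seed-reproducible", {
  fl <- fluorescence_model(gain420 = 500, gain490 = 800,
                           amp420 = -0.05, amp490 = 2, noise_cv = 0)
  # constant state, constant pH -> constant channels
  out <- render_fluorescence(rep(0, 10), 7.2, fl)
  expect_equal(length(unique(out$f420)), 1L)
  expect_equal(length(unique(out$f490)), 1L)
  # oxidation step moves channels reciprocally
  st <- render_fluorescence(c(0, 1), 7.2, fl)
  expect_lt(st$f420[2], st$f420[1])
  expect_gt(st$f490[2], st$f490[1])
  expect_true(all(st$f420 > 0 & st$f490 > 0))
  # seeded noise: equal seeds agree, different seeds do not
  fl$noise_cv <- 0.05
  a <- render_fluorescence(rep(0.5, 50), 7.2, fl, seed = 9)
  b <- render_fluorescence(rep(0.5, 50), 7.2, fl, seed = 9)
  c <- render_fluorescence(rep(0.5, 50), 7.2, fl, seed = 10)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_error(fluorescence_model(gain420 = 0, gain490 = 1,
                                  amp420 = -0.1, amp490 = 1),
               class = "hyperkin_param_error")
})

test_that("simulated experiments are bit-reproducible and honor cell_cv = 0", {
  p <- get_preset("cytosol")
  sch <- single_pulse_schedule(recovery_min = 6)
  e1 <- simulate_experiment(p, sch, n_cells = 3, cell_cv = 0.1, seed = 42)
  e2 <- simulate_experiment(p, sch, n_cells = 3, cell_cv = 0.1, seed = 42)
  e3 <- simulate_experiment(p, sch, n_cells = 3, cell_cv = 0.1, seed = 43)
  expect_identical(e1$traces, e2$traces)
  expect_identical(e1$truth, e2$truth)
  expect_false(identical(e1$traces, e3$traces))

  # homogeneous noiseless population: identical traces
  e4 <- simulate_experiment(p, sch, n_cells = 5, cell_cv = 0, noise_cv = 0,
                            seed = 1)
  for (i in 2:5)
    expect_equal(e4$traces[[i]]$f490, e4$traces[[1]]$f490)
})

test_that("two-pulse cytosolic recording shows the canonical morphology", {
  p <- get_preset("cytosol")
  ex <- simulate_experiment(p, default_schedule(), n_cells = 1, cell_cv = 0,
                            noise_cv = 0, seed = 1)
  rt <- compute_ratio(ex$traces[[1]])
  basal <- mean(rt$ratio[rt$time_min < 20])
  max1 <- max(rt$ratio[rt$time_min >= 20 & rt$time_min <= 25])
  max2 <- max(rt$ratio[rt$time_min >= 35 & rt$time_min <= 39])
  final <- tail(rt$ratio, 1)
  expect_gt(max1, basal * 1.2)   # submaximal response
  expect_gt(max2, max1)          # saturating peak above submaximal plateau
  expect_lt(final, basal + 0.3 * (max2 - basal))  # spontaneous decay
})

test_that("perturbation presets scale the recovery-phase truth as configured", {
  p <- get_preset("cytosol")
  sch <- single_pulse_schedule(recovery_min = 6)
  au <- perturbation_preset("auranofin100")
  ex <- simulate_experiment(p, sch, perturbation = au, n_cells = 2,
                            cell_cv = 0, noise_cv = 0, seed = 1)
  # whole-recording treatment: scaled from t = 0 through recovery
  expect_equal(ex$truth$k_red_recovery, ex$truth$k_red)
  expect_equal(ex$truth$k_red, rep(1.0 * 13.7 / 41.8, 2))

  px <- perturbation_preset("px12_10uM")
  ex2 <- simulate_experiment(p, sch, perturbation = px, n_cells = 2,
                             cell_cv = 0, noise_cv = 0, seed = 1)
  expect_equal(ex2$truth$k_red, rep(1.0, 2))              # untouched pre-washout
  expect_equal(ex2$truth$k_red_recovery, rep(25.8 / 88.5, 2))
})

test_that("pH clamp shifts the baseline but not the reduction kinetics", {
  p <- get_preset("cytosol")
  expect_error(simulate_ph_clamp(p, single_pulse_schedule()),
               class = "hyperkin_schema_error")
  exps <- lapply(c(6.5, 7.2, 7.5), function(ph)
    simulate_ph_clamp(p, ph_clamp_schedule(ph, sample_interval_s = 5),
                      n_cells = 1, cell_cv = 0, noise_cv = 0, seed = 1))
  res <- lapply(exps, analyze_experiment)
  basals <- vapply(res, function(r) r$r_basal, 0)
  expect_gt(basals[3], basals[2])
  expect_gt(basals[2], basals[1])
  # clamping to the resting pH leaves the baseline at the unclamped value
  un <- simulate_experiment(p, single_pulse_schedule(sample_interval_s = 5),
                            n_cells = 1, cell_cv = 0, noise_cv = 0, seed = 1)
  expect_equal(basals[2], analyze_experiment(un)$r_basal, tolerance = 1e-6)
})

test_that("fitted recovery rate rises with k_red; peak theta falls with cons", {
  p <- get_preset("cytosol")
  sch <- default_schedule()
  ks <- c(0.4, 0.8, 1.6)
  fits <- vapply(ks, function(k) {
    ex <- simulate_experiment(set_recovery_rate(p, k), sch, n_cells = 1,
                              cell_cv = 0, noise_cv = 0, seed = 1)
    analyze_experiment(ex)$k
  }, 0)
  expect_true(all(diff(fits) > 0))

  peaks <- vapply(c(1, 5, 20), function(cons) {
    kin <- p$kinetics; kin$cons <- cons
    h <- simulate_h2o2_intracellular(sch, kin)
    max(simulate_oxidized_fraction(h, kin, 0)$theta)
  }, 0)
  expect_true(all(diff(peaks) < 0))
})
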