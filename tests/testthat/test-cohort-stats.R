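test_that("per-line summaries report means, SEs and counts", {
  rec <- data.frame(experiment_id = c("e1", "e1", "e2", "e1", "e1", "e1"),
                    cell_id = paste0("c", 1:6),
                    cell_line = c("A", "A", "A", "B", "B", "B"),
                    r_basal = c(1, 1.2, 1.1, 2, 2.2, 2.1),
                    delta_r_50 = c(0.4, 0.5, 0.6, 0.2, 0.3, 0.4),
                    k = c(1, 2, 3, 4, 5, 6),
                    flagged = FALSE)
  prof <- summarize_lines(rec)
  expect_equal(nrow(prof), 2)
  a <- prof[prof$cell_line == "A", ]
  expect_equal(a$recovery_rate_mean, 2)
  expect_equal(a$recovery_rate_se, sd(1:3) / sqrt(3))
  expect_equal(a$recovery_rate_se, 0.577, tolerance = 1e-3)
  expect_equal(a$n_cells, 3)
  expect_equal(a$n_experiments, 2)
  ranked <- summarize_lines(rec, sort_by = "recovery_rate_mean")
  expect_equal(ranked$cell_line, c("A", "B"))
  # flagged cells are dropped from group statistics by default
  rec$flagged[1:2] <- TRUE
  expect_equal(summarize_lines(rec)[1, "n_cells"], 1)
})

test_that("line ranking by fitted recovery rate matches the simulation truth", {
  p <- get_preset("cytosol")
  sch <- default_schedule()
  lines <- data.frame(cell_line = c("slow", "mid", "fast"),
                      k_red = c(0.3, 0.7, 1.3))
  recs <- do.call(rbind, lapply(seq_len(nrow(lines)), function(i) {
    ex <- simulate_experiment(set_recovery_rate(p, lines$k_red[i]), sch,
                              n_cells = 8, cell_cv = 0.1, noise_cv = 0.02,
                              seed = 100 + i, line_label = lines$cell_line[i])
    analyze_experiment(ex)
  }))
  prof <- summarize_lines(recs, sort_by = "recovery_rate_mean")
  expect_equal(prof$cell_line, c("slow", "mid", "fast"))
})

test_that("group comparison branches correctly and detects shifts", {
  set.seed(31)
  base <- rnorm(30)
  # identical groups: zero between-group variance, omnibus p = 1
  cmp0 <- compare_groups(rep(base, 3), rep(c("a", "b", "c"), each = 30))
  expect_equal(cmp0$p_value, 1)
  expect_false(any(cmp0$pairwise$significant))

  # one shifted group: only its pairs flagged
  vals <- c(rnorm(30), rnorm(30), rnorm(30, 5))
  grp <- rep(c("a", "b", "c"), each = 30)
  cmp1 <- compare_groups(vals, grp)
  expect_lt(cmp1$p_value, 0.001)
  pw <- cmp1$pairwise
  involves_c <- pw$group1 == "c" | pw$group2 == "c"
  expect_true(all(pw$significant[involves_c]))
  expect_false(any(pw$significant[!involves_c]))

  # clearly non-normal data routes to Kruskal-Wallis + Dunn
  skew <- c(rexp(30)^3, rexp(30)^3, (rexp(30) + 3)^3)
  cmp2 <- compare_groups(skew, grp)
  expect_match(cmp2$method, "Kruskal")
  expect_false(cmp2$parametric)

  # paired before/after design
  before <- rnorm(12); after <- before + 1 + rnorm(12, sd = 0.2)
  cmp3 <- compare_groups(c(before, after),
                         rep(c("before", "after"), each = 12), paired = TRUE)
  expect_match(cmp3$method, "Paired")
  expect_lt(cmp3$p_value, 1e-6)

  expect_error(compare_groups(1:4, c("a", "a", "b", "b")),
               class = "hyperkin_param_error")
})

test_that("migration correlation matches explicit-sum Pearson to 1e-12", {
  brute_pearson <- function(x, y) {
    n <- length(x)
    (n * sum(x * y) - sum(x) * sum(y)) /
      sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  }
  set.seed(77)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    prof <- data.frame(cell_line = paste0("L", 1:n),
                       recovery_rate = runif(n, 0.1, 2))
    mig <- data.frame(cell_line = paste0("L", 1:n),
                      migration_efficiency = runif(n, 0, 60))
    cr <- correlate_migration(prof, mig)
    expect_equal(cr$pearson_r,
                 brute_pearson(prof$recovery_rate, mig$migration_efficiency),
                 tolerance = 1e-12)
  }
})

test_that("correlation endpoints and join validation behave as specified", {
  prof <- data.frame(cell_line = c("a", "b", "c", "d"),
                     recovery_rate = c(0.2, 0.5, 0.9, 1.4))
  lin <- data.frame(cell_line = prof$cell_line,
                    migration_efficiency = 10 + 20 * prof$recovery_rate)
  expect_equal(correlate_migration(prof, lin)$pearson_r, 1.0)
  neg <- transform(lin, migration_efficiency = 60 - migration_efficiency)
  expect_equal(correlate_migration(prof, neg)$pearson_r, -1.0)
  bad <- data.frame(cell_line = c("a", "b", "x"),
                    migration_efficiency = 1:3)
  expect_error(correlate_migration(prof, bad), "x",
               class = "hyperkin_join_error")
})

test_that("migration cohort generator honors its coupling contract", {
  coh0 <- simulate_migration_cohort(noise_sd = 0, seed = 1)
  expect_equal(cor(coh0$recovery_rate, coh0$migration_efficiency), 1.0)
  expect_true(all(coh0$migration_efficiency >= 0 &
                    coh0$migration_efficiency <= 100))
  # zero coupling: correlation centred on 0 across seeds
  rs <- vapply(1:300, function(s) {
    coh <- simulate_migration_cohort(coupling_slope = 0, noise_sd = 5,
                                     seed = s)
    cor(coh$recovery_rate, coh$migration_efficiency)
  }, 0)
  expect_lt(abs(mean(rs)), 0.06)
  expect_error(simulate_migration_cohort(cell_line_presets()[1:2, ]),
               class = "hyperkin_param_error")
  # reproducibility
  expect_identical(simulate_migration_cohort(seed = 7),
                   simulate_migration_cohort(seed = 7))
})
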