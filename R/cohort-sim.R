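# Synthetic migration cohort: per-line migration efficiency linearly
# coupled to the line's disulfide-reduction (recovery) rate.

# Default coupling and noise. The noise SD was set once by Monte-Carlo
# search so that, with the default ten-line cohort and coupling, the
# expected Pearson correlation between migration efficiency and recovery
# rate across seeds is ~0.77.
MIGRATION_SLOPE <- 25      # percentage points per (1/min)
MIGRATION_INTERCEPT <- 5   # %
MIGRATION_NOISE_SD <- 7.1  # percentage points (Monte-Carlo calibrated)

#' Simulate a cell-line migration cohort
#'
#' Generates per-line transwell migration efficiencies coupled linearly to
#' the line's biosensor recovery rate:
#' `efficiency = intercept + slope * k_red + noise`, truncated to
#' \[0, 100\]%. With the default ten lines, coupling and calibrated noise,
#' the expected Pearson correlation between efficiency and recovery rate is
#' about 0.77.
#'
#' @param lines data frame with columns `cell_line` and `k_red` (per min);
#'   default [cell_line_presets()]
#' @param coupling_slope percentage points of migration per unit recovery
#'   rate
#' @param coupling_intercept baseline migration efficiency (%)
#' @param noise_sd Gaussian noise SD (percentage points)
#' @param seed integer RNG seed
#' @return data frame (class `migration_cohort`) with `cell_line`,
#'   `recovery_rate` and `migration_efficiency`
#' @export
simulate_migration_cohort <- function(lines = cell_line_presets(),
                                      coupling_slope = MIGRATION_SLOPE,
                                      coupling_intercept = MIGRATION_INTERCEPT,
                                      noise_sd = MIGRATION_NOISE_SD,
                                      seed = 1) {
  lines <- as.data.frame(lines)
  if (!all(c("cell_line", "k_red") %in% names(lines)))
    hk_stop("'lines' needs columns cell_line and k_red",
            "hyperkin_param_error")
  if (nrow(lines) < 3)
    hk_stop("need at least 3 cell lines (correlation undefined otherwise)",
            "hyperkin_param_error")
  if (any(lines$k_red <= 0))
    hk_stop("recovery rates must be positive", "hyperkin_param_error")
  check_nonneg(noise_sd, "noise_sd")
  eff <- with_local_seed(seed, {
    coupling_intercept + coupling_slope * lines$k_red +
      stats::rnorm(nrow(lines), 0, noise_sd)
  })
  out <- data.frame(cell_line = lines$cell_line,
                    recovery_rate = lines$k_red,
                    migration_efficiency = pmin(pmax(eff, 0), 100),
                    stringsAsFactors = FALSE)
  class(out) <- c("migration_cohort", class(out))
  out
}
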