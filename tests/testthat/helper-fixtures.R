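# Shared fixtures. Preset construction runs a short ODE solve, so presets
# are built once per test run and memoised here.

.preset_cache <- new.env(parent = emptyenv())

get_preset <- function(name, noise_cv = 0.02) {
  key <- paste(name, noise_cv)
  if (is.null(.preset_cache[[key]]))
    .preset_cache[[key]] <- compartment_preset(name, noise_cv = noise_cv)
  .preset_cache[[key]]
}

# tiny synthetic trace with a prescribed ratio series (f420 constant)
ratio_fixture_trace <- function(ratio, dt_s = 20, cell_id = "cellA",
                                metadata = list(experiment_id = "fix")) {
  n <- length(ratio)
  acquisition_trace(cell_id, time_s = seq(0, by = dt_s, length.out = n),
                    f420 = rep(100, n), f490 = 100 * ratio,
                    metadata = metadata)
}

# random but valid trace for round-trip property tests
random_trace <- function(id, n = 12) {
  acquisition_trace(
    cell_id = id,
    time_s = cumsum(stats::runif(n, 5, 30)),
    f420 = stats::runif(n, 50, 500),
    f490 = stats::runif(n, 50, 500),
    metadata = list(experiment_id = "rt", cell_line = "L1",
                    compartment = "cytosol", treatment = "control",
                    ph = 7.2))
}
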