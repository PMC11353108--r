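# Shared fixture builders (all in code; nothing binary on disk).

# Random passive impedance spectrum on a short grid.
random_spectrum <- function(n = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- sort(runif(n, 1e3, 1e6))
  while (any(duplicated(f))) f <- sort(runif(n, 1e3, 1e6))
  impedance_spectrum(f, resistance = runif(n, 1, 500),
                     reactance = runif(n, -200, 200))
}

# Buffer whose measured conductance is flat at g siemens.
flat_buffer <- function(sigma_ref = 0.25, g = 0.05, n = 16) {
  grid <- log_frequency_grid(n, 3e3, 1e6)
  reference_buffer("flat", sigma_ref,
                   impedance_spectrum(grid, rep(1 / g, n), rep(0, n)))
}

# Small simulation config for fast end-to-end tests.
small_config <- function(seed = 42, n_points = 64, parasitics = parasitic_model(),
                         group_specs = default_group_specs()) {
  simulation_config(seed = seed, grid = log_frequency_grid(n_points, 3e3, 1e6),
                    parasitics = parasitics, group_specs = group_specs)
}

# Positivity-truncated normal draws (independent of the package internals).
rtnorm_pos <- function(n, mean, sd) {
  out <- numeric(0)
  while (length(out) < n) {
    d <- rnorm(2 * n, mean, sd)
    out <- c(out, d[d > 0])
  }
  out[seq_len(n)]
}

# Reshape the bundled group-summary table into summarize_groups() layout.
reference_summaries <- function() {
  df <- reference_group_summary()
  data.frame(tissue_class = df$tissue_class, state = df$state,
             frequency_khz = df$frequency_khz, n = df$n,
             mean = df$mean_s_per_m, sd = df$sd_s_per_m)
}
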