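# Shared fixtures: small, fast synthetic sessions built in code.

light_params <- function(...) {
  args <- list(...)
  base <- list(n_trials = 20, n_ca1 = 8, n_acc = 4, lap_duration = 8,
               water_duration = 4, swr_per_water_period = 2, seed = 42L)
  base[names(args)] <- args
  do.call(synth_params, base)
}

# Richer CA1 population (8 members per trajectory template, the default
# density) for the SWR/replay recovery tests.
replay_params <- function(...) {
  args <- list(...)
  base <- list(n_trials = 20, n_ca1 = 32, n_acc = 4, lap_duration = 64,
               water_duration = 10, swr_per_water_period = 3, seed = 42L)
  base[names(args)] <- args
  do.call(synth_params, base)
}

# Memoized sessions so several test files can share one build.
.fixture_env <- new.env(parent = emptyenv())
light_session <- function() {
  if (is.null(.fixture_env$gs)) .fixture_env$gs <- generate_session(light_params())
  .fixture_env$gs
}
replay_session <- function() {
  if (is.null(.fixture_env$rs)) .fixture_env$rs <- generate_session(replay_params())
  .fixture_env$rs
}

# Brute-force membership check for interval arithmetic oracles.
grid_membership <- function(iv, tgrid) {
  vapply(tgrid, function(t) any(t >= iv$start & t < iv$end), logical(1))
}
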