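# Shared helpers: trajectory comparison on a common time grid, and the
# frozen cross-validation preset ids spanning both outcome labels.

suite_preset_ids <- function() {
  ids <- preset_ids()
  ids[startsWith(ids, "suite-")]
}

# Interpolates both trajectories onto a shared grid over their common time
# span and returns the worst per-column relative max-norm difference,
# max_t |a - b| / max_t |a|.
traj_rel_maxnorm <- function(a, b, dt = 0.01) {
  t_end <- min(max(a$times), max(b$times))
  grid <- seq(0, t_end, by = dt)
  worst <- 0
  for (j in seq_len(ncol(a$states))) {
    av <- stats::approx(a$times, a$states[, j], grid)$y
    bv <- stats::approx(b$times, b$states[, j], grid)$y
    scale <- max(abs(av), 1e-12)
    worst <- max(worst, max(abs(av - bv)) / scale)
  }
  worst
}

# Default-resolution phase diagram, computed once per test session.
.grid_cache <- new.env(parent = emptyenv())
default_phase_grid <- function() {
  if (is.null(.grid_cache$grid))
    .grid_cache$grid <- phase_diagram(seq(0.05, 3, by = 0.05),
                                      seq(0.1, 5, by = 0.1))
  .grid_cache$grid
}

run_preset <- function(id, controls = sim_controls()) {
  cfg <- preset(id)$config
  simulate_response(cfg$params, cfg$init, controls)
}
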