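# shared fixtures: everything is generated in code, no stored data

# a small grid keeps IO and property tests fast
small_sensor <- function(n = 8L, Z = 60) sensor_spec(n, n, pitch_mm = 1.9,
                                                     frame_rate = Z)

# stack with given per-frame total forces, spread over a fixed point
stack_with_totals <- function(totals, sensor = small_sensor()) {
  forces <- array(0, dim = c(sensor$rows, sensor$cols, length(totals)))
  forces[2, 3, ] <- totals
  frame_stack(forces, sensor)
}

random_stack <- function(n_frames = 4L, sensor = small_sensor(), seed = 1) {
  set.seed(seed)
  forces <- array(stats::runif(sensor$rows * sensor$cols * n_frames, 0, 5),
                  dim = c(sensor$rows, sensor$cols, n_frames))
  frame_stack(forces, sensor)
}

# small fast simulation used by several files
quick_sim <- function(h = 0.1, ...) {
  simulate_impact(simulator_params(h, steps_per_frame = 200L, ...))
}

# trapezoidal integral (independent work oracle)
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# mask with prescribed runs per column: runs[[j]] is a list of c(start,end)
# pixel-row pairs (inclusive)
mask_from_runs <- function(nr, runs) {
  m <- matrix(FALSE, nr, length(runs))
  for (j in seq_along(runs))
    for (r in runs[[j]]) m[r[1]:r[2], j] <- TRUE
  m
}
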