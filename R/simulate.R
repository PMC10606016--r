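#' Drop-impact simulator parameters
#'
#' Parameters of the synthetic contact-mechanics stand-in for a hammer drop
#' test: a free-falling hammer meets a Hertzian spring (force
#' `k * delta^(3/2)`) with optional linear damping `c * delta_dot`, clamped
#' at zero (no tensile contact). The total force is spread over the sensing
#' grid with a Hertz pressure profile `p(r) ~ sqrt(1 - r^2/a^2)` whose
#' contact radius grows as `a = sqrt(R_eff * delta)`.
#'
#' The default stiffness/geometry are a numerical stand-in chosen so contact
#' spans several 60 fps frames and ~20 sensing points laterally (the regime
#' in which frame-wise energy reconstruction is meaningful); they are not
#' calibrated apple material properties.
#'
#' @param drop_height_m Drop height in metres (paper-like scenarios use
#'   0.05-0.2 m).
#' @param hammer_mass_kg Hammer mass (default 0.5 kg).
#' @param contact_stiffness Hertz stiffness `k` in N m^-3/2 (default 50).
#' @param damping Linear damping `c` in N s/m (default 2).
#' @param contact_radius_eff Effective contact geometry radius `R_eff` in m
#'   (default 0.003); contact patch radius is `sqrt(R_eff * delta)`.
#' @param sensor A [sensor_spec()].
#' @param contact_center Grid coordinate `c(i, j)` of the contact centre
#'   (may be fractional; default grid centre).
#' @param steps_per_frame Fine integration steps per sensor frame (default
#'   gives a fine step of ~1e-5 s).
#' @param penetration_cap_m Abort if penetration exceeds this (default
#'   0.35 m).
#' @param max_frames Abort if contact outlasts this many frames (default
#'   600).
#' @param noise_sd Relative multiplicative sensor noise on the downsampled
#'   frames (default 0, exact).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return An object of class `simulator_params`.
#' @export
simulator_params <- function(drop_height_m, hammer_mass_kg = 0.5,
                             contact_stiffness = 50, damping = 2,
                             contact_radius_eff = 0.003,
                             sensor = sensor_spec(),
                             contact_center = NULL,
                             steps_per_frame = NULL,
                             penetration_cap_m = 0.35,
                             max_frames = 600L,
                             noise_sd = 0, seed = 1L) {
  if (!is.finite(drop_height_m) || drop_height_m <= 0)
    stop("drop_height_m must be > 0")
  if (contact_stiffness <= 0) stop("contact_stiffness must be > 0")
  if (damping < 0) stop("damping must be >= 0")
  if (is.null(contact_center))
    contact_center <- c((sensor$rows + 1) / 2, (sensor$cols + 1) / 2)
  if (is.null(steps_per_frame))
    steps_per_frame <- as.integer(ceiling(1 / (sensor$frame_rate * 1e-5)))
  if (steps_per_frame < 10L)
    stop("steps_per_frame must give a fine step <= 1/(10 * frame rate)")
  structure(list(drop_height_m = drop_height_m,
                 hammer_mass_kg = hammer_mass_kg,
                 contact_stiffness = contact_stiffness, damping = damping,
                 contact_radius_eff = contact_radius_eff, sensor = sensor,
                 contact_center = contact_center,
                 steps_per_frame = as.integer(steps_per_frame),
                 penetration_cap_m = penetration_cap_m,
                 max_frames = as.integer(max_frames),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "simulator_params")
}

# contact force law; delta in m, v in m/s (positive = penetrating)
contact_force <- function(delta, v, p) {
  if (delta <= 0) return(0)
  max(0, p$contact_stiffness * delta^1.5 + p$damping * v)
}

#' Simulate a hammer drop impact
#'
#' Integrates the hammer dynamics `m a = -F_contact` from the free-fall
#' impact velocity `sqrt(2 g h)` with an RK4 scheme at the fine time step,
#' stops at the hammer's rest point (first non-positive velocity; rebound is
#' not modelled), projects the Hertzian pressure profile onto the sensing
#' grid at each fine step, and downsamples to sensor frames. A frame's force
#' at a sensing point is the mean of the fine-step forces in the frame
#' window (an integrating sensor), which makes the frame-wise impulse
#' bookkeeping of the reconstruction exact at frame boundaries.
#'
#' @param p A [simulator_params()].
#' @return A list of class `impact_simulation`:
#'   * `stack`: the downsampled [frame_stack()] (raw = calibrated here),
#'   * `truth_energy`: matrix of fine-dt work per sensing point (J),
#'   * `kinematics`: data.frame `t, delta_m, v_mps, force_N` at fine steps,
#'   * `v1`: impact velocity; `params`: the input parameters.
#' @export
simulate_impact <- function(p) {
  if (!inherits(p, "simulator_params")) stop("p must be simulator_params")
  sn <- p$sensor
  Z <- sn$frame_rate
  dt <- 1 / (Z * p$steps_per_frame)
  v1 <- sqrt(2 * GRAVITY * p$drop_height_m)
  m <- p$hammer_mass_kg
  nmax <- p$max_frames * p$steps_per_frame
  delta <- numeric(nmax); vel <- numeric(nmax); ftot <- numeric(nmax)
  d <- 0; v <- v1
  acc <- function(dd, vv) -contact_force(dd, vv, p) / m
  n <- 0L
  for (s in seq_len(nmax)) {
    # RK4 on (delta, v)
    k1d <- v;                 k1v <- acc(d, v)
    k2d <- v + dt / 2 * k1v;  k2v <- acc(d + dt / 2 * k1d, v + dt / 2 * k1v)
    k3d <- v + dt / 2 * k2v;  k3v <- acc(d + dt / 2 * k2d, v + dt / 2 * k2v)
    k4d <- v + dt * k3v;      k4v <- acc(d + dt * k3d, v + dt * k3v)
    d <- d + dt / 6 * (k1d + 2 * k2d + 2 * k3d + k4d)
    v <- v + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
    if (d > p$penetration_cap_m)
      stop("simulation error: hammer penetrated beyond the configured cap")
    if (v <= 0) break
    n <- s
    delta[s] <- d; vel[s] <- v; ftot[s] <- contact_force(d, v, p)
  }
  if (n == nmax)
    stop("simulation error: contact outlasted max_frames")
  if (n == 0L) stop("simulation error: hammer at rest before any step")
  delta <- delta[seq_len(n)]; vel <- vel[seq_len(n)]; ftot <- ftot[seq_len(n)]

  # grid geometry: squared distance (m^2) of each sensing point from centre
  pitch_m <- sn$pitch_mm / 1000
  xi <- (seq_len(sn$rows) - p$contact_center[1]) * pitch_m
  xj <- (seq_len(sn$cols) - p$contact_center[2]) * pitch_m
  r2 <- outer(xi^2, xj^2, "+")
  r2v <- as.vector(r2)
  nearest <- which.min(r2v)
  npts <- length(r2v)

  a2 <- p$contact_radius_eff * delta # contact radius^2 at each step
  n_frames <- ceiling(n / p$steps_per_frame)
  frames <- array(0, dim = c(sn$rows, sn$cols, n_frames))
  e_pt <- numeric(npts)
  for (f in seq_len(n_frames)) {
    idx <- ((f - 1L) * p$steps_per_frame + 1L):min(f * p$steps_per_frame, n)
    w <- 1 - outer(r2v, a2[idx], "/")
    w[w < 0] <- 0
    w <- sqrt(w)
    cs <- colSums(w)
    bad <- cs <= 0
    if (any(bad)) { w[nearest, bad] <- 1; cs[bad] <- 1 }
    fpt <- sweep(w, 2L, ftot[idx] / cs, "*")
    frames[, , f] <- rowSums(fpt) / p$steps_per_frame
    e_pt <- e_pt + as.vector(fpt %*% (vel[idx] * dt))
  }
  if (p$noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(p$seed)
    frames <- frames * (1 + stats::rnorm(length(frames), 0, p$noise_sd))
    frames[frames < 0] <- 0
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  structure(list(stack = frame_stack(frames, sn),
                 truth_energy = matrix(e_pt, sn$rows, sn$cols),
                 kinematics = data.frame(t = seq_len(n) * dt,
                                         delta_m = delta, v_mps = vel,
                                         force_N = ftot),
                 v1 = v1, fine_dt = dt, params = p),
            class = "impact_simulation")
}

#' @export
print.impact_simulation <- function(x, ...) {
  cat(sprintf(
    "<impact_simulation> h = %g m: contact %.3g s (%d frame(s) at %g fps), peak %.3g N, truth E = %.4g J\n",
    x$params$drop_height_m, nrow(x$kinematics) * x$fine_dt,
    x$stack$n_frames, x$params$sensor$frame_rate,
    max(x$kinematics$force_N), sum(x$truth_energy)))
  invisible(x)
}
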