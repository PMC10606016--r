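#' Hammer kinematics from the total force history
#'
#' Reconstructs the per-frame velocity and displacement of a free-falling
#' impact hammer from the measured contact-force history. The velocity in the
#' first effective frame is the free-fall impact velocity
#' `V_1 = sqrt(2 g h)`; for later frames the velocity is reduced by the
#' accumulated specific impulse of the measured forces,
#' `V_f = V_1 - (1 / (m Z)) * sum_{x < f} TotalForce(x)`,
#' and the per-frame travel is `S_f = V_f / Z`. Gravity during contact is
#' neglected (the impulse comes from the measured forces only).
#'
#' The series is truncated at the last frame with positive velocity: once the
#' accumulated impulse exceeds `m V_1` the formula would drive the velocity
#' negative, which corresponds to rebound, not further energy absorption. A
#' warning is emitted when truncation occurs before the end of the stack.
#'
#' @param stack A trimmed [frame_stack()] (effective frames only).
#' @param cfg An [impact_config()] with drop height and hammer mass.
#' @return An object of class `kinematics_series` with fields
#'   `velocity` (m/s), `displacement` (m per frame), `n_frames`,
#'   `truncated` (logical) and `config`.
#' @export
velocity_series <- function(stack, cfg) {
  if (!inherits(cfg, "impact_config")) stop("cfg must be an impact_config")
  Z <- stack$sensor$frame_rate
  v1 <- sqrt(2 * cfg$gravity * cfg$drop_height_m)
  tot <- total_force(stack)
  l <- length(tot)
  # V[f] = v1 - cumsum of total force over frames 1..f-1, scaled by 1/(m Z)
  v <- v1 - c(0, cumsum(tot)[-l]) / (cfg$hammer_mass_kg * Z)
  keep <- v > 0
  if (!all(keep)) {
    n <- which(!keep)[1] - 1L
    if (n < 1L) stop("velocity non-positive at the first effective frame")
    warning(sprintf(
      "velocity reaches zero at frame %d of %d; series truncated", n + 1L, l))
    v <- v[seq_len(n)]
  }
  structure(list(velocity = v, displacement = v / Z,
                 n_frames = length(v), truncated = length(v) < l,
                 config = cfg, frame_rate = Z),
            class = "kinematics_series")
}

#' @export
print.kinematics_series <- function(x, ...) {
  cat(sprintf(
    "<kinematics_series> %d frame(s), V1 = %.4g m/s, V_end = %.4g m/s%s\n",
    x$n_frames, x$velocity[1], x$velocity[x$n_frames],
    if (x$truncated) " (truncated at rest)" else ""))
  invisible(x)
}

#' Per-sensing-point absorbed impact energy
#'
#' Accumulates, per sensing point, the work done by the measured contact
#' force over the per-frame hammer travel:
#' `E(i,j) = sum_x F(i,j,x) * S_x`, with the sum running over the frames
#' retained in the kinematics series (truncation at hammer rest applies).
#'
#' @param stack The trimmed [frame_stack()] the kinematics were computed from.
#' @param kin The [velocity_series()] result for the same stack.
#' @return An object of class `energy_map` with fields `energy` (matrix, J)
#'   and `sensor`.
#' @export
energy_map <- function(stack, kin) {
  if (!inherits(kin, "kinematics_series")) stop("kin must be a kinematics_series")
  if (kin$n_frames > stack$n_frames)
    stop("kinematics series longer than stack: inputs do not correspond")
  lp <- kin$n_frames
  d <- dim(stack$forces)
  fmat <- matrix(stack$forces[, , seq_len(lp)], nrow = d[1] * d[2])
  e <- matrix(fmat %*% kin$displacement[seq_len(lp)], d[1], d[2])
  structure(list(energy = e, sensor = stack$sensor), class = "energy_map")
}

#' @export
print.energy_map <- function(x, ...) {
  cat(sprintf("<energy_map> %d x %d, total %.4g J, peak %.4g J\n",
              nrow(x$energy), ncol(x$energy), sum(x$energy), max(x$energy)))
  invisible(x)
}

#' Locate the impact centre of an energy map
#'
#' Grid argmax of the energy; ties are broken toward the grid centroid.
#'
#' @param map An [energy_map()].
#' @return Integer vector `c(i, j)`.
#' @export
impact_center <- function(map) {
  e <- map$energy
  if (max(e) <= 0) stop("no impact: energy map is identically zero")
  idx <- which(e == max(e), arr.ind = TRUE)
  if (nrow(idx) > 1L) {
    cen <- (dim(e) + 1) / 2
    d2 <- (idx[, 1] - cen[1])^2 + (idx[, 2] - cen[2])^2
    idx <- idx[which.min(d2), , drop = FALSE]
  }
  as.integer(idx[1, ])
}

#' Axial slice of an energy map through the impact centre
#'
#' Extracts the 1-D energy profile through the impact centre along a grid row
#' or column, with positions in millimetres at the sensor pitch. Positions are
#' absolute along the slice axis: sensing point `n` sits at `(n - 1) * pitch`.
#'
#' @param map An [energy_map()].
#' @param axis `"row"` (slice runs along a row, varying the column index) or
#'   `"col"`.
#' @param center `"auto"` (argmax of the map) or an integer `c(i, j)` grid
#'   coordinate.
#' @return An object of class `energy_profile`: a data.frame with columns
#'   `position_mm` and `energy_J`, with attributes `center_index` (index along
#'   the slice of the impact centre) and `center_mm`.
#' @export
energy_profile <- function(map, axis = c("row", "col"), center = "auto") {
  axis <- match.arg(axis)
  cen <- if (identical(center, "auto")) impact_center(map) else as.integer(center)
  if (length(cen) != 2L) stop("center must be a grid coordinate c(i, j)")
  e <- if (axis == "row") map$energy[cen[1], ] else map$energy[, cen[2]]
  cidx <- if (axis == "row") cen[2] else cen[1]
  pitch <- map$sensor$pitch_mm
  out <- data.frame(position_mm = (seq_along(e) - 1) * pitch, energy_J = e)
  structure(out, class = c("energy_profile", "data.frame"),
            center_index = cidx, center_mm = (cidx - 1) * pitch,
            axis = axis, pitch_mm = pitch)
}

#' Per-point peak force profile along the same slice
#'
#' Maximum force over the effective frames at each sensing point of the
#' slice; the temporal statistic used for sub-yield masking.
#'
#' @param stack A trimmed [frame_stack()].
#' @param axis,center As in [energy_profile()]; `center` must be `c(i, j)`.
#' @return Data frame `position_mm`, `peak_force_N`.
#' @export
peak_force_profile <- function(stack, axis = c("row", "col"), center) {
  axis <- match.arg(axis)
  cen <- as.integer(center)
  peak <- apply(stack$forces, c(1L, 2L), max)
  p <- if (axis == "row") peak[cen[1], ] else peak[, cen[2]]
  data.frame(position_mm = (seq_along(p) - 1) * stack$sensor$pitch_mm,
             peak_force_N = p)
}

#' Write an energy map to CSV
#'
#' Long format `i,j,energy_J`; optionally also the full grid as a headerless
#' CSV matrix.
#'
#' @param map An [energy_map()].
#' @param path Output CSV path.
#' @param grid_path Optional path for the grid-format CSV.
#' @return `path`, invisibly.
#' @export
write_energy_map <- function(map, path, grid_path = NULL) {
  idx <- expand.grid(i = seq_len(nrow(map$energy)),
                     j = seq_len(ncol(map$energy)))
  dt <- data.table::data.table(i = idx$i, j = idx$j,
                               energy_J = map$energy[cbind(idx$i, idx$j)])
  data.table::setorder(dt, i, j)
  data.table::fwrite(dt, path)
  if (!is.null(grid_path))
    data.table::fwrite(data.table::as.data.table(map$energy), grid_path,
                       col.names = FALSE)
  invisible(path)
}

#' Write an energy profile to CSV
#'
#' @param profile An [energy_profile()].
#' @param path Output CSV path (`position_mm,energy_J`).
#' @return `path`, invisibly.
#' @export
write_energy_profile <- function(profile, path) {
  data.table::fwrite(as.data.frame(profile)[, c("position_mm", "energy_J")],
                     path)
  invisible(path)
}
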