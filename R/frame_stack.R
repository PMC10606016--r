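#' Pressure frame stack
#'
#' A time-ordered stack of per-sensing-point force grids, the raw observable
#' of a drop-impact recording. Forces are stored as a 3-D array
#' `forces[i, j, f]` in newtons, with `i, j` 1-based grid coordinates and `f`
#' the frame index (contiguous from first contact once trimmed).
#'
#' @param forces Numeric array `rows x cols x frames`, all values >= 0, or a
#'   matrix for a single frame.
#' @param sensor A [sensor_spec()] describing the grid.
#' @param trimmed Logical; `TRUE` once the stack has been trimmed to the
#'   effective contact window.
#' @return An object of class `pressure_frame_stack` with fields `forces`,
#'   `sensor`, `n_frames` and `trimmed`.
#' @export
frame_stack <- function(forces, sensor = sensor_spec(), trimmed = FALSE) {
  if (is.matrix(forces)) forces <- array(forces, dim = c(dim(forces), 1L))
  if (length(dim(forces)) != 3L)
    stop("forces must be a rows x cols x frames array")
  d <- dim(forces)
  if (d[1] != sensor$rows || d[2] != sensor$cols)
    stop(sprintf("frame shape %d x %d does not match sensor spec %d x %d",
                 d[1], d[2], sensor$rows, sensor$cols))
  if (d[3] < 1L) stop("stack must contain at least one frame")
  if (any(!is.finite(forces))) stop("forces must be finite")
  if (any(forces < 0)) stop("negative force values are not valid")
  structure(list(forces = forces, sensor = sensor,
                 n_frames = d[3], trimmed = isTRUE(trimmed)),
            class = "pressure_frame_stack")
}

#' @export
print.pressure_frame_stack <- function(x, ...) {
  cat(sprintf(
    "<pressure_frame_stack> %d x %d grid, %d frame(s)%s, peak total %.3g N\n",
    x$sensor$rows, x$sensor$cols, x$n_frames,
    if (x$trimmed) " (trimmed)" else "",
    max(total_force(x))))
  invisible(x)
}

#' Per-frame total force
#'
#' Sum of forces over all sensing points, per frame.
#'
#' @param stack A [frame_stack()].
#' @return Numeric vector of length `n_frames`, in newtons.
#' @export
total_force <- function(stack) {
  apply(stack$forces, 3L, sum)
}

#' Read a pressure frame stack
#'
#' Two on-disk dialects are accepted: a directory of per-frame CSV grids
#' (`frame_0001.csv`, `frame_0002.csv`, ...; each file one `rows x cols`
#' numeric grid, no header), or a single long-format CSV with header
#' `frame,i,j,force_raw` (or `force`) and 1-based indices. The long format is
#' the canonical one written by [write_frame_stack()].
#'
#' @param path Directory of per-frame grids, or a long-format CSV file.
#' @param sensor A [sensor_spec()]; frame shapes are validated against it.
#' @return A [frame_stack()] in raw (uncalibrated) units, frames in temporal
#'   order.
#' @export
read_frame_stack <- function(path, sensor = sensor_spec()) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "^frame_\\d+\\.csv$",
                             full.names = TRUE))
    if (length(files) == 0L) stop("no frame_*.csv files found in ", path)
    frames <- lapply(files, function(f) {
      m <- as.matrix(data.table::fread(f, header = FALSE))
      storage.mode(m) <- "double"
      if (nrow(m) != sensor$rows || ncol(m) != sensor$cols)
        stop(sprintf("frame file %s is %d x %d, expected %d x %d",
                     basename(f), nrow(m), ncol(m), sensor$rows, sensor$cols))
      m
    })
    forces <- array(unlist(frames, use.names = FALSE),
                    dim = c(sensor$rows, sensor$cols, length(frames)))
  } else {
    dt <- data.table::fread(path)
    vcol <- intersect(c("force_raw", "force", "value"), names(dt))[1]
    if (is.na(vcol) || !all(c("frame", "i", "j") %in% names(dt)))
      stop("long-format stack needs columns frame,i,j,force_raw")
    nf <- max(dt$frame)
    if (min(dt$frame) != 1L) stop("frame indices must start at 1")
    if (max(dt$i) > sensor$rows || max(dt$j) > sensor$cols ||
        min(dt$i) < 1L || min(dt$j) < 1L)
      stop("grid indices out of range for sensor spec")
    forces <- array(0, dim = c(sensor$rows, sensor$cols, nf))
    forces[cbind(dt$i, dt$j, dt$frame)] <- dt[[vcol]]
  }
  frame_stack(forces, sensor)
}

#' Write a pressure frame stack
#'
#' Writes the canonical long format (`frame,i,j,force_raw`), omitting zero
#' entries for compactness; [read_frame_stack()] restores them.
#'
#' @param stack A [frame_stack()].
#' @param path Output CSV path.
#' @param keep_zeros Write explicit zeros too (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path, keep_zeros = FALSE) {
  d <- dim(stack$forces)
  idx <- which(if (keep_zeros) array(TRUE, d) else stack$forces != 0,
               arr.ind = TRUE)
  if (nrow(idx) == 0L) idx <- matrix(c(1L, 1L, 1L), 1L) # all-zero stack
  dt <- data.table::data.table(frame = idx[, 3L], i = idx[, 1L], j = idx[, 2L],
                               force_raw = stack$forces[idx])
  # anchor the first and last frame so the frame count round-trips even when
  # those frames are all zero
  for (f in c(1L, d[3]))
    if (!any(dt$frame == f))
      dt <- rbind(dt, data.table::data.table(frame = f, i = 1L, j = 1L,
                                             force_raw = stack$forces[1, 1, f]))
  data.table::setorder(dt, frame, i, j)
  # %.17g guarantees binary round trip of the force values
  dt$force_raw <- sprintf("%.17g", dt$force_raw)
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' Apply per-point calibration
#'
#' Maps raw readings to calibrated forces with the per-point affine model
#' `F = gain * raw + offset`, floored at zero (a sensor cannot report a
#' negative contact force).
#'
#' @param raw A [frame_stack()] of raw readings.
#' @param cal A [calibration_table()] with the same grid shape.
#' @return A calibrated [frame_stack()].
#' @export
apply_calibration <- function(raw, cal) {
  d <- dim(raw$forces)
  if (nrow(cal$gain) != d[1] || ncol(cal$gain) != d[2])
    stop("calibration table shape does not match stack")
  out <- raw$forces * as.vector(cal$gain) + as.vector(cal$offset)
  out[out < 0] <- 0
  frame_stack(out, raw$sensor, trimmed = raw$trimmed)
}

#' Trim a stack to its effective contact window
#'
#' Removes leading and trailing frames whose total force does not exceed
#' `force_floor`; the first retained frame becomes frame 1 of the effective
#' window. Frames inside the window that dip below the floor (contact
#' chatter) are retained — only the window edges are trimmed.
#'
#' @param stack A [frame_stack()].
#' @param force_floor Total-force floor in newtons (default 0.1 N, small
#'   relative to forces of interest yet robust to sensor noise).
#' @return The trimmed [frame_stack()] with `trimmed = TRUE`.
#' @export
trim_to_effective_frames <- function(stack, force_floor = 0.1) {
  if (!is.finite(force_floor) || force_floor < 0)
    stop("force_floor must be >= 0")
  tot <- total_force(stack)
  live <- which(tot > force_floor)
  if (length(live) == 0L)
    stop("no contact: no frame exceeds the force floor")
  keep <- seq(min(live), max(live))
  frame_stack(stack$forces[, , keep, drop = FALSE], stack$sensor,
              trimmed = TRUE)
}
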