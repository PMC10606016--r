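#' Array pressure sensor geometry
#'
#' Describes the sensing grid of an array pressure sensor: number of rows and
#' columns of sensing points, the centre-to-centre pitch in millimetres, and
#' the acquisition frame rate. Defaults match a 1600-point (40 x 40) tactile
#' array with one sensing point every 1.9 mm sampled at 60 frames per second.
#'
#' @param rows,cols Number of sensing points along each grid axis.
#' @param pitch_mm Centre-to-centre spacing of sensing points, in mm.
#' @param frame_rate Acquisition rate in frames per second.
#' @return An object of class `sensor_spec`.
#' @examples
#' sensor_spec()
#' sensor_spec(rows = 8, cols = 8, pitch_mm = 2, frame_rate = 120)
#' @export
sensor_spec <- function(rows = 40L, cols = 40L, pitch_mm = 1.9,
                        frame_rate = 60) {
  rows <- as.integer(rows)
  cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) stop("sensor grid must have rows, cols >= 1")
  if (!is.finite(pitch_mm) || pitch_mm <= 0) stop("pitch_mm must be > 0")
  if (!is.finite(frame_rate) || frame_rate <= 0) stop("frame_rate must be > 0")
  structure(list(rows = rows, cols = cols, pitch_mm = pitch_mm,
                 frame_rate = frame_rate),
            class = "sensor_spec")
}

#' @export
print.sensor_spec <- function(x, ...) {
  cat(sprintf("<sensor_spec> %d x %d points, %.3g mm pitch, %g fps\n",
              x$rows, x$cols, x$pitch_mm, x$frame_rate))
  invisible(x)
}

# Gravitational acceleration used throughout (m s^-2); fixed by convention.
GRAVITY <- 9.8

#' Drop-impact configuration
#'
#' Drop height and hammer mass for a free-fall impact experiment. The
#' gravitational acceleration is fixed at 9.8 m s^-2.
#'
#' @param drop_height_m Drop height of the impact hammer, in metres (> 0).
#' @param hammer_mass_kg Mass of the impact hammer, in kilograms (default
#'   0.5 kg).
#' @return An object of class `impact_config`.
#' @examples
#' impact_config(0.125)
#' @export
impact_config <- function(drop_height_m, hammer_mass_kg = 0.5) {
  if (!is.finite(drop_height_m) || drop_height_m <= 0)
    stop("drop_height_m must be > 0")
  if (!is.finite(hammer_mass_kg) || hammer_mass_kg <= 0)
    stop("hammer_mass_kg must be > 0")
  structure(list(drop_height_m = drop_height_m,
                 hammer_mass_kg = hammer_mass_kg,
                 gravity = GRAVITY),
            class = "impact_config")
}

#' @export
print.impact_config <- function(x, ...) {
  cat(sprintf("<impact_config> h = %g m, m = %g kg, g = %g m/s^2\n",
              x$drop_height_m, x$hammer_mass_kg, x$gravity))
  invisible(x)
}

#' Per-sensing-point calibration table
#'
#' Affine calibration mapping raw sensor readings to force in newtons:
#' `force = gain * raw + offset`, applied per sensing point.
#'
#' @param gain Matrix of per-point gains (all > 0), one row/column per sensing
#'   point.
#' @param offset Matrix of per-point offsets (N); defaults to all zero.
#' @return An object of class `calibration_table`.
#' @examples
#' cal <- calibration_table(gain = matrix(1, 4, 4))
#' @export
calibration_table <- function(gain, offset = NULL) {
  gain <- as.matrix(gain)
  if (is.null(offset)) offset <- matrix(0, nrow(gain), ncol(gain))
  offset <- as.matrix(offset)
  if (!all(dim(gain) == dim(offset)))
    stop("gain and offset must have identical dimensions")
  if (any(!is.finite(gain)) || any(gain <= 0))
    stop("all gains must be finite and > 0")
  if (any(!is.finite(offset))) stop("all offsets must be finite")
  structure(list(gain = gain, offset = offset), class = "calibration_table")
}

#' Read a calibration table from CSV
#'
#' Expects columns `i,j,gain,offset` with 1-based grid indices.
#'
#' @param path CSV file path.
#' @param sensor A [sensor_spec()] giving the expected grid shape.
#' @return A [calibration_table()].
#' @export
read_calibration <- function(path, sensor = sensor_spec()) {
  dt <- data.table::fread(path)
  need <- c("i", "j", "gain", "offset")
  if (!all(need %in% names(dt)))
    stop("calibration file must have columns i,j,gain,offset")
  gain <- matrix(NA_real_, sensor$rows, sensor$cols)
  offset <- matrix(NA_real_, sensor$rows, sensor$cols)
  idx <- cbind(dt$i, dt$j)
  gain[idx] <- dt$gain
  offset[idx] <- dt$offset
  if (anyNA(gain)) stop("calibration file does not cover the full grid")
  calibration_table(gain, offset)
}

#' Write a calibration table to CSV
#'
#' @param cal A [calibration_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(cal, path) {
  idx <- expand.grid(i = seq_len(nrow(cal$gain)), j = seq_len(ncol(cal$gain)))
  dt <- data.table::data.table(i = idx$i, j = idx$j,
                               gain = cal$gain[cbind(idx$i, idx$j)],
                               offset = cal$offset[cbind(idx$i, idx$j)])
  data.table::setorder(dt, i, j)
  data.table::fwrite(dt, path)
  invisible(path)
}
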