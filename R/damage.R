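#' Per-column run boundaries of a death-zone mask
#'
#' For each image column, the run-length boundaries of foreground along the
#' depth axis, in half-open convention: a run occupying pixel rows
#' `a..b` yields the boundary pair `(a, b + 1)`, so that run length is simply
#' the boundary difference. A column with `k` runs yields `2k` strictly
#' increasing boundaries; columns without foreground yield an empty vector.
#'
#' @param mask A `death_zone_mask` from [segment_death_zone()] (or a logical
#'   matrix).
#' @return An object of class `zone_segments`: a list with one numeric vector
#'   of boundaries per column.
#' @export
column_segments <- function(mask) {
  m <- if (inherits(mask, "death_zone_mask")) mask$mask else mask
  segs <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (!any(col)) return(numeric(0))
    r <- rle(col)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    fg <- which(r$values)
    as.numeric(rbind(starts[fg], ends[fg] + 1L))
  })
  structure(segs, class = "zone_segments")
}

#' Depth and width profile of the cell death zone
#'
#' Applies the depth/width rules per column: the zone centre is the midpoint
#' of the two outermost run boundaries (for two runs with boundaries
#' `Y1 < Y2 < Y3 < Y4`, the centre is `(Y1 + Y4) / 2`), the depth is the
#' distance from the peel surface to that centre, and the width is the sum of
#' all run lengths (`(Y2 - Y1) + (Y4 - Y3)` in the two-run case). The rule
#' generalises to any number of runs. Columns with no detected zone get
#' depth and width 0 and `defined = FALSE`.
#'
#' @param segs A [column_segments()] result.
#' @param peel A [trace_peel()] curve (pixel rows, `NA` where undefined).
#' @param scale_mm_per_px Image scale in mm per pixel.
#' @return An object of class `damage_profile`: data.frame with columns
#'   `lateral_mm`, `depth_mm`, `width_mm`, `defined`. Lateral position of
#'   column `x` is `(x - 0.5) * scale` (pixel centres).
#' @export
depth_and_width <- function(segs, peel, scale_mm_per_px) {
  if (!is.finite(scale_mm_per_px) || scale_mm_per_px <= 0)
    stop("scale_mm_per_px must be > 0")
  n <- length(segs)
  if (length(peel) != n)
    stop("peel curve and segments cover different numbers of columns")
  depth <- width <- numeric(n)
  defined <- logical(n)
  for (x in seq_len(n)) {
    b <- segs[[x]]
    if (length(b) == 0L || is.na(peel[x])) next
    center <- (b[1] + b[length(b)]) / 2
    if (center < peel[x])
      stop(sprintf(
        "column %d: zone centre (%.1f px) above the peel surface (%.1f px)",
        x, center, peel[x]))
    depth[x] <- (center - peel[x]) * scale_mm_per_px
    width[x] <- sum(b[seq(2, length(b), by = 2)] -
                    b[seq(1, length(b), by = 2)]) * scale_mm_per_px
    defined[x] <- TRUE
  }
  structure(data.frame(lateral_mm = (seq_len(n) - 0.5) * scale_mm_per_px,
                       depth_mm = depth, width_mm = width, defined = defined),
            class = c("damage_profile", "data.frame"))
}

#' Resample a damage profile onto a regular lateral grid
#'
#' Linear interpolation of depth and width onto a grid at the given pitch
#' (typically the 1.9 mm sensor pitch) centred at the given lateral position.
#' Grid positions outside the measured defined support are flagged undefined.
#'
#' @param profile A [depth_and_width()] profile.
#' @param pitch_mm Target grid pitch in mm (> 0).
#' @param center_mm Lateral position (mm, profile coordinates) of the grid
#'   centre point.
#' @param half_span Number of grid points either side of the centre (default
#'   spans the profile).
#' @return A `damage_profile` data.frame on the new grid, with an extra
#'   attribute `center_index`.
#' @export
resample_profile <- function(profile, pitch_mm, center_mm, half_span = NULL) {
  if (!is.finite(pitch_mm) || pitch_mm <= 0) stop("pitch_mm must be > 0")
  def <- profile[profile$defined, , drop = FALSE]
  if (nrow(def) < 2L) stop("resampling needs at least 2 defined points")
  if (is.null(half_span))
    half_span <- ceiling(max(abs(range(profile$lateral_mm) - center_mm)) /
                           pitch_mm)
  pos <- center_mm + seq(-half_span, half_span) * pitch_mm
  tol <- 1e-6 * pitch_mm # guards against FP drift at the support edges
  lo_s <- min(def$lateral_mm); hi_s <- max(def$lateral_mm)
  inside <- pos >= lo_s - tol & pos <= hi_s + tol
  depth <- width <- rep(0, length(pos))
  defined <- rep(FALSE, length(pos))
  if (any(inside)) {
    px <- pmin(pmax(pos[inside], lo_s), hi_s)
    depth[inside] <- stats::approx(def$lateral_mm, def$depth_mm, xout = px)$y
    width[inside] <- stats::approx(def$lateral_mm, def$width_mm, xout = px)$y
    # positions interpolated across an internal undefined gap stay undefined
    gapless <- vapply(px, function(p) {
      lo <- max(def$lateral_mm[def$lateral_mm <= p + tol])
      hi <- min(def$lateral_mm[def$lateral_mm >= p - tol])
      nbr <- profile$lateral_mm >= lo - tol & profile$lateral_mm <= hi + tol
      all(profile$defined[nbr])
    }, logical(1))
    defined[inside] <- gapless
  }
  structure(data.frame(lateral_mm = pos, depth_mm = depth, width_mm = width,
                       defined = defined),
            class = c("damage_profile", "data.frame"),
            center_index = half_span + 1L)
}

#' Write a damage profile to CSV
#'
#' @param profile A `damage_profile`.
#' @param path Output CSV path
#'   (`lateral_mm,depth_mm,width_mm,defined_flag`).
#' @return `path`, invisibly.
#' @export
write_damage_profile <- function(profile, path) {
  out <- data.frame(lateral_mm = profile$lateral_mm,
                    depth_mm = profile$depth_mm,
                    width_mm = profile$width_mm,
                    defined_flag = as.integer(profile$defined))
  data.table::fwrite(out, path)
  invisible(path)
}
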