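#' Correlation analysis configuration
#'
#' @param yield_force_N Biological yield force in newtons (default 8.75 N);
#'   sensing points whose peak force stays below it never bruise and can be
#'   masked out of the correlation.
#' @param mask_sub_yield Exclude sub-yield points from the correlation
#'   (default `FALSE`).
#' @param registration `"metadata"` (use provided frame offsets; default) or
#'   `"peak_align"` (align the depth peak to the energy peak).
#' @param pitch_mm Comparison grid pitch in mm (default the 1.9 mm sensor
#'   pitch).
#' @param method Correlation flavour: `"pearson"` (default) or
#'   `"spearman"`.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(yield_force_N = 8.75, mask_sub_yield = FALSE,
                            registration = c("metadata", "peak_align"),
                            pitch_mm = 1.9,
                            method = c("pearson", "spearman")) {
  registration <- match.arg(registration)
  method <- match.arg(method)
  if (!is.finite(yield_force_N) || yield_force_N <= 0)
    stop("yield_force_N must be > 0")
  if (!is.finite(pitch_mm) || pitch_mm <= 0) stop("pitch_mm must be > 0")
  structure(list(yield_force_N = yield_force_N,
                 mask_sub_yield = isTRUE(mask_sub_yield),
                 registration = registration, pitch_mm = pitch_mm,
                 method = method),
            class = "analysis_config")
}

#' Pearson correlation coefficient
#'
#' Standard product-moment coefficient of two equal-length series. Returns a
#' flagged `NA` (rather than propagating `NaN`) when either series has zero
#' variance.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return The coefficient, with attribute `defined` (`FALSE` for the
#'   zero-variance case).
#' @export
pearson_r <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(NA_real_, defined = FALSE))
  structure(stats::cor(x, y, method = method), defined = TRUE)
}

#' Register a damage profile against an energy profile
#'
#' Resamples the damage profile onto the sensor pitch and aligns the two
#' lateral frames, either from metadata (`offset_mm`: the lateral coordinate
#' transform from image frame to sensor frame,
#' `sensor_pos = image_pos + offset_mm`) or by aligning the depth peak with
#' the energy peak. Returns paired (depth, energy) and (width, energy)
#' vectors over the overlapping defined support.
#'
#' @param damage A [depth_and_width()] profile (image lateral frame, mm).
#' @param energy An [energy_profile()] (sensor frame, mm).
#' @param cfg An [analysis_config()].
#' @param offset_mm Image-to-sensor lateral offset in mm (required for
#'   `registration = "metadata"`).
#' @param undefined_as_zero Treat grid points with no detected zone as depth
#'   and width 0 (sites that never bruised) instead of dropping them; pairs
#'   them with their energy values so sub-yield masking has something to
#'   remove (default `FALSE`).
#' @return An object of class `paired_profiles`: data.frame with columns
#'   `position_mm` (sensor frame), `depth_mm`, `width_mm`, `energy_J`;
#'   attribute `offset_mm` records the alignment used.
#' @export
register_profiles <- function(damage, energy, cfg = analysis_config(),
                              offset_mm = NULL, undefined_as_zero = FALSE) {
  if (sum(damage$defined) < 2L) stop("degenerate damage profile")
  if (nrow(energy) < 3L || max(energy$energy_J) <= 0)
    stop("degenerate energy profile")
  if (cfg$registration == "metadata") {
    if (is.null(offset_mm))
      stop("metadata registration requires offset_mm")
  } else {
    e_peak <- energy$position_mm[which.max(energy$energy_J)]
    d_peak <- damage$lateral_mm[damage$defined][
      which.max(damage$depth_mm[damage$defined])]
    offset_mm <- e_peak - d_peak
  }
  # image-frame lateral position of each sensor grid point
  img_pos <- energy$position_mm - offset_mm
  center_img <- img_pos[which.min(abs(img_pos - mean(range(
    damage$lateral_mm[damage$defined]))))]
  res <- resample_profile(damage, pitch_mm = attr(energy, "pitch_mm"),
                          center_mm = center_img)
  # match resampled grid onto the energy grid by position
  key <- round((res$lateral_mm + offset_mm) / attr(energy, "pitch_mm"), 6)
  ekey <- round(energy$position_mm / attr(energy, "pitch_mm"), 6)
  hit <- match(ekey, key)
  def <- res$defined[ifelse(is.na(hit), 1L, hit)]
  if (undefined_as_zero) def <- def | energy$energy_J > 0
  ok <- !is.na(hit) & def
  if (sum(ok) < 3L) stop("registration error: overlap below 3 points")
  out <- data.frame(position_mm = energy$position_mm[ok],
                    depth_mm = res$depth_mm[hit[ok]],
                    width_mm = res$width_mm[hit[ok]],
                    energy_J = energy$energy_J[ok])
  structure(out, class = c("paired_profiles", "data.frame"),
            offset_mm = offset_mm)
}

#' Mask sensing points below the biological yield force
#'
#' Points whose peak contact force over the effective frames never reached
#' the yield force did not bruise; with `cfg$mask_sub_yield` they are
#' excluded from the paired series (otherwise the input is returned
#' unchanged).
#'
#' @param paired A [register_profiles()] result.
#' @param peak_force Per-point peak force (N) aligned with `paired` rows
#'   (e.g. from [peak_force_profile()], matched by `position_mm`).
#' @param cfg An [analysis_config()].
#' @return A `paired_profiles` data.frame with attribute `masked_points`.
#' @export
apply_yield_mask <- function(paired, peak_force, cfg) {
  if (length(peak_force) != nrow(paired))
    stop("peak_force must align with the paired series")
  if (!cfg$mask_sub_yield) {
    attr(paired, "masked_points") <- 0L
    return(paired)
  }
  keep <- peak_force >= cfg$yield_force_N
  if (!any(keep)) stop("degenerate series: all points below yield force")
  out <- paired[keep, , drop = FALSE]
  attr(out, "offset_mm") <- attr(paired, "offset_mm")
  attr(out, "masked_points") <- sum(!keep)
  class(out) <- class(paired)
  out
}

#' Correlate registered depth/width against energy
#'
#' @param paired A (possibly yield-masked) `paired_profiles` data.frame.
#' @param height_m Drop height of the sample, carried into the result.
#' @param cfg An [analysis_config()].
#' @return An object of class `correlation_result`: list with `r_depth`,
#'   `r_width`, `n_points`, `masked_points`, `height_m`.
#' @export
correlate_profiles <- function(paired, height_m = NA_real_,
                               cfg = analysis_config()) {
  if (nrow(paired) < 3L) stop("need at least 3 paired points")
  r_d <- pearson_r(paired$depth_mm, paired$energy_J, method = cfg$method)
  r_w <- pearson_r(paired$width_mm, paired$energy_J, method = cfg$method)
  structure(list(r_depth = as.numeric(r_d), r_width = as.numeric(r_w),
                 n_points = nrow(paired),
                 masked_points = attr(paired, "masked_points") %||% 0L,
                 height_m = height_m),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "<correlation_result> h = %g m: r_depth = %.3f, r_width = %.3f (n = %d, masked = %d)\n",
    x$height_m, x$r_depth, x$r_width, x$n_points, x$masked_points))
  invisible(x)
}

#' Summarise correlation results by drop height
#'
#' @param results List of `correlation_result` objects.
#' @return Data frame with one row per height: `height_m`, `n_samples`, and
#'   min/mean/max of `r_depth` and `r_width`.
#' @export
summarize_by_height <- function(results) {
  if (length(results) == 0L) stop("no correlation results")
  df <- data.frame(height_m = vapply(results, `[[`, 0, "height_m"),
                   r_depth = vapply(results, `[[`, 0, "r_depth"),
                   r_width = vapply(results, `[[`, 0, "r_width"))
  out <- do.call(rbind, lapply(split(df, df$height_m), function(g) {
    data.frame(height_m = g$height_m[1], n_samples = nrow(g),
               r_depth_min = min(g$r_depth), r_depth_mean = mean(g$r_depth),
               r_depth_max = max(g$r_depth),
               r_width_min = min(g$r_width), r_width_mean = mean(g$r_width),
               r_width_max = max(g$r_width))
  }))
  rownames(out) <- NULL
  out[order(out$height_m), , drop = FALSE]
}
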