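#' Section-image renderer parameters
#'
#' Parameters for rendering a synthetic stained-section micrograph with
#' exactly known ground truth: a pale low-saturation tissue mosaic under a
#' gray glass background, a circular-arc peel surface, sparse blue speckle
#' (isolated dead cells from section preparation), and a high-saturation
#' blue death band whose centre sits `depth(x)` below the peel with local
#' thickness `width(x)`.
#'
#' The cell mosaic emulates the size structure of apple tissue: small
#' tightly packed cells down to 1.2 mm below the peel (epidermis and
#' sclerenchyma), larger parenchyma cells beyond.
#'
#' @param width_px,height_px Image size in pixels.
#' @param scale_mm_per_px Physical pixel size (default 0.02 mm).
#' @param peel_row_px Row of the peel surface at the lateral centre.
#' @param peel_radius_mm Radius of the circular-arc peel (default 200 mm;
#'   `Inf` for a flat peel). The arc is convex toward the top of the image.
#' @param depth_profile Death-zone depth in mm: a single number, a function
#'   of lateral position (mm), or a vector per column. Must be >= 1.2 mm
#'   wherever the band is present (the zone forms in the pulp).
#' @param width_profile Death-zone thickness in mm: number, function or
#'   per-column vector (> 0 where present).
#' @param gap_spec List of lateral intervals `c(lo, hi)` in mm where the
#'   band is absent (discontinuities); may be empty.
#' @param stain_noise Noise level: per-channel Gaussian sd, also scales the
#'   speckle density (default 0.05).
#' @param seed Integer seed; rendering is bit-deterministic given it.
#' @return An object of class `section_params`.
#' @export
section_params <- function(width_px = 640L, height_px = 240L,
                           scale_mm_per_px = 0.02, peel_row_px = 25,
                           peel_radius_mm = 200,
                           depth_profile = 2.5, width_profile = 0.8,
                           gap_spec = list(), stain_noise = 0.05,
                           seed = 1L) {
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 scale_mm_per_px = scale_mm_per_px,
                 peel_row_px = peel_row_px, peel_radius_mm = peel_radius_mm,
                 depth_profile = depth_profile,
                 width_profile = width_profile, gap_spec = gap_spec,
                 stain_noise = stain_noise, seed = as.integer(seed)),
            class = "section_params")
}

# evaluate a number / function / per-column vector profile at lateral mm
eval_profile <- function(prof, lateral_mm, n_col) {
  if (is.function(prof)) return(prof(lateral_mm))
  if (length(prof) == 1L) return(rep(prof, n_col))
  if (length(prof) != n_col)
    stop("per-column profile length must equal width_px")
  prof
}

# block-mosaic multiplicative brightness field (jittered cell tessellation)
mosaic_field <- function(nr, nc, cell_px, amplitude = 0.08) {
  bi <- (seq_len(nr) - 1L) %/% cell_px + 1L
  bj <- (seq_len(nc) - 1L) %/% cell_px + 1L
  vals <- matrix(stats::runif(max(bi) * max(bj), 1 - amplitude, 1 + amplitude),
                 max(bi), max(bj))
  vals[cbind(rep(bi, times = nc), rep(bj, each = nr))] |>
    matrix(nr, nc)
}

#' Render a synthetic stained-section image
#'
#' @param p A [section_params()].
#' @return A list of class `section_render`:
#'   * `image`: the [section_image()] (peel side `"top"`),
#'   * `peel_truth`: exact peel row per column (fractional pixels),
#'   * `damage_truth`: analytic `damage_profile` data.frame (unquantised
#'     depth/width in mm per column, `defined` where the band is present),
#'   * `band_mask`: logical ground-truth mask of the rendered band.
#' @export
render_section <- function(p) {
  if (!inherits(p, "section_params")) stop("p must be section_params")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(p$seed)
  nr <- p$height_px; nc <- p$width_px; sc <- p$scale_mm_per_px
  lateral <- (seq_len(nc) - 0.5) * sc

  # peel surface: circular arc, convex toward the image top
  xc <- mean(range(lateral))
  sag_mm <- if (is.finite(p$peel_radius_mm)) {
    R <- p$peel_radius_mm
    if (R < (max(lateral) - xc)) stop("peel_radius_mm smaller than half-width")
    R - sqrt(R^2 - (lateral - xc)^2)
  } else rep(0, nc)
  y_peel <- p$peel_row_px + sag_mm / sc

  d_mm <- eval_profile(p$depth_profile, lateral, nc)
  w_mm <- eval_profile(p$width_profile, lateral, nc)
  present <- rep(TRUE, nc)
  for (g in p$gap_spec) present[lateral >= g[1] & lateral <= g[2]] <- FALSE
  present <- present & is.finite(d_mm) & is.finite(w_mm) & w_mm > 0
  if (any(present & d_mm < 1.2))
    stop("depth_profile must be >= 1.2 mm where the band is present")
  if (any(present & (y_peel + (d_mm + w_mm / 2) / sc > nr)))
    stop("band extends outside the image")

  rows <- matrix(seq_len(nr), nr, nc)
  peel_m <- matrix(y_peel, nr, nc, byrow = TRUE)
  tissue <- rows >= peel_m
  depth_px_m <- matrix((d_mm / sc), nr, nc, byrow = TRUE)
  half_px_m <- matrix((w_mm / 2 / sc), nr, nc, byrow = TRUE)
  pres_m <- matrix(present, nr, nc, byrow = TRUE)
  band <- pres_m & abs(rows - (peel_m + depth_px_m)) <= half_px_m & tissue

  # colours: glass background, pale tissue, saturated blue band
  col_bg <- c(0.55, 0.55, 0.56)
  col_tissue <- c(0.82, 0.78, 0.62)
  col_band <- c(0.25, 0.28, 0.80)

  # depth-dependent cell mosaic: fine near the surface, coarse in the pulp
  fine <- mosaic_field(nr, nc, cell_px = max(2L, round(0.08 / sc)))
  coarse <- mosaic_field(nr, nc, cell_px = max(4L, round(0.25 / sc)))
  deep <- (rows - peel_m) * sc > 1.2
  mos <- ifelse(deep, coarse, fine)

  img <- array(0, dim = c(nr, nc, 3))
  for (ch in 1:3) {
    plane <- matrix(col_bg[ch], nr, nc)
    plane[tissue] <- (col_tissue[ch] * mos)[tissue]
    plane[band] <- col_band[ch]
    img[, , ch] <- plane
  }

  # sparse blue speckle in the tissue (section-prep cell death)
  n_spk <- round(nr * nc * p$stain_noise * 0.01)
  if (n_spk > 0) {
    si <- sample.int(nr, n_spk, replace = TRUE)
    sj <- sample.int(nc, n_spk, replace = TRUE)
    keep <- si > (y_peel[sj] + 2)
    si <- si[keep]; sj <- sj[keep]
    for (off in list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))) {
      ii <- pmin(si + off[1], nr); jj <- pmin(sj + off[2], nc)
      for (ch in 1:3) img[cbind(ii, jj, ch)] <- col_band[ch]
    }
  }
  if (p$stain_noise > 0)
    img <- img + stats::rnorm(length(img), 0, p$stain_noise)
  img[img < 0] <- 0; img[img > 1] <- 1

  damage_truth <- structure(
    data.frame(lateral_mm = lateral,
               depth_mm = ifelse(present, d_mm, 0),
               width_mm = ifelse(present, w_mm, 0),
               defined = present),
    class = c("damage_profile", "data.frame"))
  structure(list(image = section_image(img, sc, "top"),
                 peel_truth = y_peel, damage_truth = damage_truth,
                 band_mask = band, params = p),
            class = "section_render")
}

#' @export
print.section_render <- function(x, ...) {
  cat(sprintf("<section_render> %d x %d px, band in %d/%d columns\n",
              x$params$height_px, x$params$width_px,
              sum(x$damage_truth$defined), x$params$width_px))
  invisible(x)
}
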