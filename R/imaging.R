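#' Stained tissue-section image
#'
#' An RGB micrograph of a stained tissue section with its physical scale and
#' the side of the image the peel surface faces. Channels are normalised to
#' [0, 1] internally.
#'
#' @param rgb Numeric array `height x width x 3` in [0, 1] (values in
#'   [0, 255] are rescaled).
#' @param scale_mm_per_px Physical size of one pixel, in mm (> 0).
#' @param peel_side Which image edge the peel faces: `"top"` (default) or
#'   `"bottom"`.
#' @return An object of class `section_image`.
#' @export
section_image <- function(rgb, scale_mm_per_px, peel_side = c("top", "bottom")) {
  peel_side <- match.arg(peel_side)
  if (length(dim(rgb)) != 3L || dim(rgb)[3] < 3L)
    stop("rgb must be a height x width x 3 array")
  rgb <- rgb[, , 1:3, drop = FALSE]
  if (max(rgb) > 1) rgb <- rgb / 255
  if (min(rgb) < 0) stop("negative pixel values")
  if (!is.finite(scale_mm_per_px) || scale_mm_per_px <= 0)
    stop("scale_mm_per_px must be > 0")
  structure(list(rgb = rgb, scale_mm_per_px = scale_mm_per_px,
                 peel_side = peel_side),
            class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$rgb)
  cat(sprintf("<section_image> %d x %d px, %.4g mm/px, peel side: %s\n",
              d[1], d[2], x$scale_mm_per_px, x$peel_side))
  invisible(x)
}

#' Read a section image (PNG + sidecar metadata)
#'
#' Reads an RGB PNG together with a JSON sidecar (`<image>.json`) holding
#' `scale_mm_per_px` and `peel_side`.
#'
#' @param path PNG file path.
#' @param scale_mm_per_px,peel_side Override the sidecar (required if no
#'   sidecar exists).
#' @return A [section_image()].
#' @export
read_section_image <- function(path, scale_mm_per_px = NULL, peel_side = NULL) {
  img <- png::readPNG(path)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  scale <- scale_mm_per_px %||% meta$scale_mm_per_px
  ps <- peel_side %||% meta$peel_side %||% "top"
  if (is.null(scale)) stop("scale_mm_per_px not given and no sidecar found")
  if (length(dim(img)) == 2L) stop("image is grayscale; RGB required")
  section_image(img, as.numeric(scale), ps)
}

#' Write a section image as PNG + sidecar metadata
#'
#' @param img A [section_image()].
#' @param path Output PNG path; a JSON sidecar `<path>.json` is written too.
#' @return `path`, invisibly.
#' @export
write_section_image <- function(img, path) {
  png::writePNG(img$rgb, path)
  jsonlite::write_json(list(scale_mm_per_px = img$scale_mm_per_px,
                            peel_side = img$peel_side),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Saturation channel of a section image
#'
#' Converts the RGB image to HSV and returns the S (saturation) channel,
#' the discriminant that separates the trypan-blue-stained cell death zone
#' from the surrounding tissue.
#'
#' @param img A [section_image()] (or a raw `h x w x 3` array in [0, 1]).
#' @return Numeric matrix in [0, 1], same height/width as the image.
#' @export
saturation_channel <- function(img) {
  rgb <- if (inherits(img, "section_image")) img$rgb else img
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L) stop("RGB input required")
  d <- dim(rgb)
  m <- rbind(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]),
             as.vector(rgb[, , 3]))
  s <- grDevices::rgb2hsv(m, maxColorValue = 1)[2L, ]
  matrix(s, d[1], d[2])
}

#' Otsu threshold of a grayscale image
#'
#' Maximises between-class variance over a 256-bin histogram of values in
#' [0, 1].
#'
#' @param x Numeric matrix/vector in [0, 1].
#' @return Threshold value in (0, 1).
#' @export
otsu_threshold <- function(x) {
  v <- as.vector(x)
  v <- v[is.finite(v)]
  h <- tabulate(pmin(pmax(floor(v * 256) + 1L, 1L), 256L), 256L)
  p <- h / sum(h)
  levels <- (seq_len(256) - 0.5) / 256
  w0 <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  levels[which.max(sb)] + 0.5 / 256
}

# --- binary morphology on logical matrices (disk structuring elements) ------

disk_offsets <- function(radius) {
  r <- seq(-radius, radius)
  g <- expand.grid(dr = r, dc = r)
  g[g$dr^2 + g$dc^2 <= radius^2 + 1e-9, , drop = FALSE]
}

# shift-accumulate count of set neighbours under the structuring element
se_count <- function(m, off) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- max(abs(off))
  big <- matrix(0L, nr + 2 * pad, nc + 2 * pad)
  acc <- matrix(0L, nr, nc)
  mi <- (pad + 1):(pad + nr); mj <- (pad + 1):(pad + nc)
  big[mi, mj] <- m
  for (k in seq_len(nrow(off)))
    acc <- acc + big[mi + off$dr[k], mj + off$dc[k]]
  acc
}

#' Binary erosion / dilation / opening / closing with a disk
#'
#' Minimal morphology on logical matrices using a disk structuring element of
#' the given pixel radius (pixels outside the image count as background).
#'
#' @param m Logical matrix.
#' @param radius Disk radius in pixels; `0` is a no-op.
#' @return Logical matrix of the same shape.
#' @name morphology
NULL

#' @rdname morphology
#' @export
binary_erode <- function(m, radius) {
  if (radius <= 0) return(m)
  off <- disk_offsets(radius)
  se_count(m, off) == nrow(off)
}

#' @rdname morphology
#' @export
binary_dilate <- function(m, radius) {
  if (radius <= 0) return(m)
  se_count(m, disk_offsets(radius)) > 0L
}

#' @rdname morphology
#' @export
binary_open <- function(m, radius) binary_dilate(binary_erode(m, radius), radius)

#' @rdname morphology
#' @export
binary_close <- function(m, radius) binary_erode(binary_dilate(m, radius), radius)

# --- connected components via the pixel adjacency graph ---------------------

# labels of connected foreground components; connectivity 4 or 8
label_components <- function(m, connectivity = 8L) {
  idx <- which(m)
  n <- length(idx)
  lab <- matrix(0L, nrow(m), ncol(m))
  if (n == 0L) return(lab)
  node <- matrix(0L, nrow(m), ncol(m))
  node[idx] <- seq_len(n)
  nr <- nrow(m); nc <- ncol(m)
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  ai <- ((idx - 1L) %% nr) + 1L
  aj <- ((idx - 1L) %/% nr) + 1L
  from <- integer(0); to <- integer(0)
  for (s in shifts) {
    bi <- ai + s[1]; bj <- aj + s[2]
    ok <- bi >= 1L & bi <= nr & bj >= 1L & bj <= nc
    nb <- node[cbind(bi[ok], bj[ok])]
    sel <- nb > 0L
    from <- c(from, node[idx[ok]][sel])
    to <- c(to, nb[sel])
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  comp <- igraph::components(g)
  lab[idx] <- comp$membership
  lab
}

keep_largest_component <- function(m, connectivity = 8L) {
  lab <- label_components(m, connectivity)
  if (max(lab) == 0L) return(m & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

# fill holes: background regions (4-connected) not touching the image border
fill_holes <- function(m) {
  bg <- !m
  lab <- label_components(bg, connectivity = 4L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  m | !(lab %in% border | lab == 0L)
}

#' Segment the cell death zone from the saturation channel
#'
#' Threshold segmentation of the S channel followed by morphological opening
#' and closing with disk elements, extraction of the largest 8-connected
#' component, and hole filling. The result is a single connected, hole-free
#' binary mask of the death zone.
#'
#' @param s_channel Saturation matrix in [0, 1], from [saturation_channel()].
#' @param threshold `"otsu"` (default) or a numeric threshold in (0, 1).
#' @param open_radius,close_radius Disk radii (px) for opening and closing.
#' @return An object of class `death_zone_mask`: list with `mask` (logical
#'   matrix) and `provenance` (parameters actually used).
#' @export
segment_death_zone <- function(s_channel, threshold = "otsu",
                               open_radius = 3L, close_radius = 5L) {
  if (min(s_channel) < 0 || max(s_channel) > 1)
    stop("s_channel must be in [0, 1]")
  thr <- if (identical(threshold, "otsu")) otsu_threshold(s_channel)
         else as.numeric(threshold)
  m <- s_channel > thr
  if (!any(m)) stop("no zone detected: empty foreground after thresholding")
  m <- binary_open(m, open_radius)
  m <- binary_close(m, close_radius)
  if (!any(m)) stop("no zone detected: foreground removed by morphology")
  m <- keep_largest_component(m, 8L)
  m <- fill_holes(m)
  structure(list(mask = m,
                 provenance = list(threshold = thr,
                                   threshold_method =
                                     if (identical(threshold, "otsu")) "otsu"
                                     else "manual",
                                   open_radius = open_radius,
                                   close_radius = close_radius,
                                   connectivity = 8L)),
            class = "death_zone_mask")
}

#' @export
print.death_zone_mask <- function(x, ...) {
  cat(sprintf("<death_zone_mask> %d x %d px, %d foreground px, thr = %.3f\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              x$provenance$threshold))
  invisible(x)
}

#' Write a death-zone mask as an 8-bit PNG
#'
#' @param mask A `death_zone_mask` (or logical matrix).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- if (inherits(mask, "death_zone_mask")) mask$mask else mask
  png::writePNG(m * 1, path)
  invisible(path)
}

# separable 3x3 box blur with replicated edges
box_blur3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m <- (m + rbind(m[1, ], m[-nr, , drop = FALSE]) +
          rbind(m[-1, , drop = FALSE], m[nr, ])) / 3
  (m + cbind(m[, 1], m[, -nc, drop = FALSE]) +
     cbind(m[, -1, drop = FALSE], m[, nc])) / 3
}

#' Trace the peel surface
#'
#' For each image column, scanning from the peel side, finds the first pixel
#' whose tissue score (saturation x value, robust against the low-saturation
#' glass background) exceeds `tissue_threshold` for `min_run` consecutive
#' pixels, then smooths the curve with a running median.
#'
#' @param img A [section_image()].
#' @param tissue_threshold Tissue score threshold (default 0.12; glass
#'   background scores ~0.05, tissue ~0.2).
#' @param min_run Consecutive super-threshold pixels required (default 3).
#' @param smooth_window Running-median window in columns (odd, default 11).
#' @return An object of class `peel_curve`: numeric vector of length
#'   `width`, `y_peel` in pixel rows counted from the top of the image
#'   regardless of `peel_side`; `NA` for columns without tissue.
#' @export
trace_peel <- function(img, tissue_threshold = 0.12, min_run = 3L,
                       smooth_window = 11L) {
  # blur the channels before the (nonlinear) HSV conversion: stain noise on
  # a gray background otherwise reads as spurious saturation
  blur <- img$rgb
  for (ch in 1:3) blur[, , ch] <- box_blur3(img$rgb[, , ch])
  s <- saturation_channel(blur)
  v <- pmax(blur[, , 1], pmax(blur[, , 2], blur[, , 3])) # HSV value
  dim(v) <- dim(s)
  score <- s * v
  if (img$peel_side == "bottom") score <- score[rev(seq_len(nrow(score))), ]
  hit <- score > tissue_threshold
  nr <- nrow(hit)
  # run of min_run consecutive TRUEs starting at each row
  runs <- hit
  if (min_run > 1L) for (k in seq_len(min_run - 1L))
    runs <- runs & rbind(hit[-seq_len(k), , drop = FALSE],
                         matrix(FALSE, k, ncol(hit)))
  y <- apply(runs, 2L, function(col) {
    w <- which(col)
    if (length(w)) w[1] else NA_real_
  })
  if (all(is.na(y))) stop("no tissue found in image")
  def <- which(!is.na(y))
  if (length(def) >= smooth_window) {
    ys <- stats::runmed(y[def], k = smooth_window, endrule = "median")
    # the shrinking end windows of the running median flatten a curved
    # surface; re-estimate the ends from a local linear fit instead
    half <- (smooth_window - 1L) %/% 2L
    fit_n <- min(4L * smooth_window, length(ys))
    if (length(ys) > 2L * half + 4L) {
      head_i <- seq_len(half)
      fi <- seq_len(fit_n)
      ys[head_i] <- stats::predict(stats::lm(ys[fi] ~ fi),
                                   data.frame(fi = head_i))
      tail_i <- length(ys) - half + seq_len(half)
      fi2 <- length(ys) - fit_n + seq_len(fit_n)
      ys[tail_i] <- stats::predict(stats::lm(ys[fi2] ~ fi2),
                                   data.frame(fi2 = tail_i))
    }
    y[def] <- ys
  }
  if (img$peel_side == "bottom") y <- nr + 1 - y
  structure(y, class = "peel_curve")
}
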