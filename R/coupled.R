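#' Depth-energy coupling parameters
#'
#' Ground-truth coupling used by [make_coupled_sample()]: the death-zone
#' depth below the peel tracks the reconstructed per-point impact energy
#' linearly, `depth(x) = depth0 + alpha * E(x) + N(0, sigma(h))`, on the
#' sensing points whose peak contact force reaches the yield-equivalent
#' threshold; the band is absent elsewhere. The noise sd decreases with drop
#' height, `sigma(h) = sigma0 * (h_ref / h)`, encoding the larger
#' apple-to-apple scatter seen at low drop heights. Width is drawn
#' log-normally, independent of energy (the null width-energy relation).
#'
#' Defaults are stated once for the package's synthetic world: `alpha` =
#' 250 mm/J and `depth0` = 1.2 mm put depths in the 1.2-5 mm range over the
#' simulator's 7-15 mJ per-point energies; `yield_equiv_N` = 0.02 N is the
#' sub-yield cutoff on the simulator's force scale (the 8.75 N analogue);
#' `sigma0` = 0.2 mm at `h_ref` = 0.2 m.
#'
#' @param alpha_mm_per_J Depth gained per joule of per-point energy.
#' @param depth0_mm Baseline depth of the band (>= 1.2 mm, the peel/pulp
#'   boundary).
#' @param sigma0_mm Depth noise sd at the reference height.
#' @param h_ref_m Reference height for the noise model.
#' @param yield_equiv_N Per-point peak-force threshold below which no band
#'   forms (yield-force analogue on the simulator force scale).
#' @param width_logmean,width_logsd Log-normal width parameters (mm).
#' @param width_range_mm Width clip range.
#' @param offset_range_mm Image-to-sensor lateral offset is drawn uniformly
#'   in `[-offset_range_mm, offset_range_mm]`.
#' @return An object of class `coupling_params`.
#' @export
coupling_params <- function(alpha_mm_per_J = 250, depth0_mm = 1.2,
                            sigma0_mm = 0.2, h_ref_m = 0.2,
                            yield_equiv_N = 0.02,
                            width_logmean = log(0.8), width_logsd = 0.25,
                            width_range_mm = c(0.3, 2),
                            offset_range_mm = 2) {
  if (alpha_mm_per_J <= 0) stop("alpha_mm_per_J must be > 0")
  if (depth0_mm < 1.2) stop("depth0_mm must be >= 1.2 (zone forms in pulp)")
  if (sigma0_mm < 0) stop("sigma0_mm must be >= 0")
  structure(list(alpha_mm_per_J = alpha_mm_per_J, depth0_mm = depth0_mm,
                 sigma0_mm = sigma0_mm, h_ref_m = h_ref_m,
                 yield_equiv_N = yield_equiv_N,
                 width_logmean = width_logmean, width_logsd = width_logsd,
                 width_range_mm = width_range_mm,
                 offset_range_mm = offset_range_mm),
            class = "coupling_params")
}

#' Generate a coupled pressure + section sample with known truth
#'
#' Runs the drop-impact simulator, reconstructs the sensor-rate energy
#' profile through the impact centre (the quantity the experiment measures
#' and correlates), and builds a death-zone depth profile coupled to it per
#' [coupling_params()]. Optionally renders the corresponding stained-section
#' image.
#'
#' @param sim_params A [simulator_params()].
#' @param coupling A [coupling_params()].
#' @param seed Integer seed for the coupling noise, width draw and lateral
#'   offset.
#' @param sim Optionally a precomputed [simulate_impact()] result for
#'   `sim_params` (the hammer dynamics are height-deterministic, so one
#'   simulation can serve many samples).
#' @param render Render the section image too (default `FALSE`).
#' @param section_scale_mm_per_px Pixel size for rendering (default 0.05).
#' @param stain_noise Renderer noise level (default 0.05).
#' @return A list of class `coupled_sample`:
#'   * `stack`: the [frame_stack()] (untrimmed sensor frames),
#'   * `energy_profile`: reconstructed [energy_profile()] along the slice,
#'   * `peak_force`: per-point peak-force profile on the slice,
#'   * `truth`: list with `damage_profile` (analytic, image lateral frame),
#'     `offset_mm` (image to sensor), `sigma_mm`, `support` (logical per
#'     slice point), `yield_equiv_N`, `height_m`, `seed`,
#'   * `section`: the `section_render` result (when `render = TRUE`).
#' @export
make_coupled_sample <- function(sim_params, coupling = coupling_params(),
                                seed = 1L, sim = NULL, render = FALSE,
                                section_scale_mm_per_px = 0.05,
                                stain_noise = 0.05) {
  if (is.null(sim)) sim <- simulate_impact(sim_params)
  h <- sim_params$drop_height_m
  st <- trim_to_effective_frames(sim$stack)
  kin <- velocity_series(st, impact_config(h, sim_params$hammer_mass_kg))
  em <- energy_map(st, kin)
  cen <- impact_center(em)
  eprof <- energy_profile(em, axis = "row", center = cen)
  pf <- peak_force_profile(st, axis = "row", center = cen)

  support <- pf$peak_force_N >= coupling$yield_equiv_N
  if (sum(support) < 3L) stop("degenerate energy profile: support < 3 points")

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  sigma <- coupling$sigma0_mm * coupling$h_ref_m / h
  n <- nrow(eprof)
  depth <- coupling$depth0_mm + coupling$alpha_mm_per_J * eprof$energy_J +
    stats::rnorm(n, 0, sigma)
  depth <- pmax(depth, coupling$depth0_mm)
  width <- exp(stats::rnorm(n, coupling$width_logmean, coupling$width_logsd))
  width <- pmin(pmax(width, coupling$width_range_mm[1]),
                coupling$width_range_mm[2])
  offset_mm <- stats::runif(1, -coupling$offset_range_mm,
                            coupling$offset_range_mm)

  # analytic damage profile in the image lateral frame
  damage <- structure(
    data.frame(lateral_mm = eprof$position_mm - offset_mm,
               depth_mm = ifelse(support, depth, 0),
               width_mm = ifelse(support, width, 0),
               defined = support),
    class = c("damage_profile", "data.frame"))

  out <- list(stack = sim$stack, energy_profile = eprof, peak_force = pf,
              sim = sim,
              truth = list(damage_profile = damage, offset_mm = offset_mm,
                           sigma_mm = sigma,
                           alpha_mm_per_J = coupling$alpha_mm_per_J,
                           support = support,
                           yield_equiv_N = coupling$yield_equiv_N,
                           height_m = h, seed = seed))
  if (render) {
    sc <- section_scale_mm_per_px
    sup_pos <- damage$lateral_mm[support]
    margin <- 4 # mm beyond the band on each side
    x0 <- min(sup_pos) - margin
    width_px <- ceiling((max(sup_pos) - min(sup_pos) + 2 * margin) / sc)
    dsup <- damage[support, , drop = FALSE]
    dfun <- function(x) stats::approx(dsup$lateral_mm + (-x0), dsup$depth_mm,
                                      xout = x, rule = 1)$y
    wfun <- function(x) stats::approx(dsup$lateral_mm + (-x0), dsup$width_mm,
                                      xout = x, rule = 1)$y
    max_d <- max(dsup$depth_mm + dsup$width_mm / 2)
    height_px <- ceiling((max_d + 3) / sc) + 25L
    sp <- section_params(width_px = width_px, height_px = height_px,
                         scale_mm_per_px = sc, peel_row_px = 20,
                         peel_radius_mm = 200,
                         depth_profile = dfun, width_profile = wfun,
                         stain_noise = stain_noise, seed = seed)
    out$section <- render_section(sp)
    # rendered image's lateral origin sits at x0 in the sample image frame
    out$truth$section_origin_mm <- x0
    out$truth$section_offset_mm <- offset_mm + x0
  }
  class(out) <- "coupled_sample"
  out
}

#' @export
print.coupled_sample <- function(x, ...) {
  cat(sprintf(
    "<coupled_sample> h = %g m, %d support point(s), sigma = %.3g mm, offset = %.3g mm\n",
    x$truth$height_m, sum(x$truth$support), x$truth$sigma_mm,
    x$truth$offset_mm))
  invisible(x)
}

#' Write a coupled sample to disk
#'
#' Emits exactly the formats the readers consume: the long-format frame CSV,
#' a unit calibration CSV, the section PNG with sidecar (when rendered), and
#' a `truth.json` with all ground-truth parameters.
#'
#' @param sample A [make_coupled_sample()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_coupled_sample <- function(sample, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_frame_stack(sample$stack, file.path(dir, "frames.csv"))
  sn <- sample$stack$sensor
  write_calibration(calibration_table(matrix(1, sn$rows, sn$cols)),
                    file.path(dir, "calibration.csv"))
  if (!is.null(sample$section))
    write_section_image(sample$section$image, file.path(dir, "section.png"))
  tr <- sample$truth
  tr$damage_profile <- as.list(as.data.frame(tr$damage_profile))
  jsonlite::write_json(
    c(tr, list(sensor = unclass(sn))),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
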