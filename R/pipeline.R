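#' Run configuration for a single-sample analysis
#'
#' Bundles everything [run_sample()] needs: input locations, sensor and
#' impact metadata, segmentation and analysis parameters, output directory
#' and seed. Round-trips losslessly through JSON.
#'
#' @param input Sample directory (holding `frames.csv`, optional
#'   `calibration.csv`, optional `section.png` + sidecar, optional
#'   `truth.json`).
#' @param out_dir Output directory for reports and intermediates.
#' @param height_m Drop height of the sample in metres.
#' @param hammer_mass_kg Hammer mass (default 0.5 kg).
#' @param sensor A [sensor_spec()].
#' @param force_floor Effective-frame floor in N (default 0.1).
#' @param threshold,open_radius,close_radius Segmentation parameters (see
#'   [segment_death_zone()]).
#' @param analysis An [analysis_config()].
#' @param seed Integer seed recorded in provenance.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input, out_dir, height_m, hammer_mass_kg = 0.5,
                       sensor = sensor_spec(), force_floor = 0.1,
                       threshold = "otsu", open_radius = 3L,
                       close_radius = 5L, analysis = analysis_config(),
                       seed = 1L) {
  structure(list(input = input, out_dir = out_dir, height_m = height_m,
                 hammer_mass_kg = hammer_mass_kg, sensor = sensor,
                 force_floor = force_floor, threshold = threshold,
                 open_radius = open_radius, close_radius = close_radius,
                 analysis = analysis, seed = as.integer(seed)),
            class = "run_config")
}

#' Analyse one sample end to end
#'
#' Executes the full single-sample pipeline: read frames, calibrate, trim to
#' effective frames, reconstruct kinematics and the energy map/profile,
#' segment the section image (when present), measure depth/width, register
#' against the energy profile, apply optional sub-yield masking, and
#' correlate. All intermediates are written as CSV (plus the mask PNG and a
#' provenance JSON) under `cfg$out_dir`.
#'
#' When the sample carries a `truth.json` with an analytic damage profile
#' but no section image, the truth profile is correlated directly (the
#' "truth route" used by synthetic studies).
#'
#' @param cfg A [run_config()].
#' @return A report list with `r_depth`, `r_width`, `n_points`,
#'   `masked_points`, `height_m`, `files` (paths written).
#' @export
run_sample <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  fr_path <- file.path(cfg$input, "frames.csv")
  if (!file.exists(fr_path)) stop("[read] frames.csv not found in ", cfg$input)
  raw <- read_frame_stack(fr_path, cfg$sensor)
  cal_path <- file.path(cfg$input, "calibration.csv")
  stack <- if (file.exists(cal_path))
    apply_calibration(raw, read_calibration(cal_path, cfg$sensor)) else raw
  stack <- trim_to_effective_frames(stack, cfg$force_floor)
  kin <- velocity_series(stack, impact_config(cfg$height_m,
                                              cfg$hammer_mass_kg))
  em <- energy_map(stack, kin)
  cen <- impact_center(em)
  eprof <- energy_profile(em, axis = "row", center = cen)
  pf <- peak_force_profile(stack, axis = "row", center = cen)

  files <- character(0)
  wr <- function(obj, name, writer) {
    path <- file.path(cfg$out_dir, name)
    writer(obj, path)
    files <<- c(files, path)
    path
  }
  wr(data.frame(frame = seq_len(kin$n_frames), velocity_mps = kin$velocity,
                displacement_m = kin$displacement),
     "kinematics.csv", function(o, p) data.table::fwrite(o, p))
  wr(em, "energy_map.csv", write_energy_map)
  wr(eprof, "energy_profile.csv", write_energy_profile)

  truth_path <- file.path(cfg$input, "truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::read_json(truth_path,
                                                            simplifyVector = TRUE)
  img_path <- file.path(cfg$input, "section.png")
  if (file.exists(img_path)) {
    img <- read_section_image(img_path)
    s <- saturation_channel(img)
    mask <- segment_death_zone(s, cfg$threshold, cfg$open_radius,
                               cfg$close_radius)
    peel <- trace_peel(img)
    damage <- depth_and_width(column_segments(mask), peel,
                              img$scale_mm_per_px)
    wr(mask, "mask.png", write_mask)
    offset <- if (!is.null(truth$section_offset_mm))
      truth$section_offset_mm else NULL
  } else if (!is.null(truth$damage_profile)) {
    damage <- as.data.frame(truth$damage_profile)
    class(damage) <- c("damage_profile", "data.frame")
    offset <- truth$offset_mm
  } else {
    stop("[section] no section.png or truth damage profile in ", cfg$input)
  }
  wr(damage, "damage_profile.csv", write_damage_profile)

  paired <- register_profiles(damage, eprof, cfg$analysis, offset_mm = offset)
  pk <- pf$peak_force_N[match(round(paired$position_mm, 6),
                              round(pf$position_mm, 6))]
  paired <- apply_yield_mask(paired, pk, cfg$analysis)
  res <- correlate_profiles(paired, height_m = cfg$height_m, cfg$analysis)

  wr(data.frame(height_m = res$height_m, r_depth = res$r_depth,
                r_width = res$r_width, n_points = res$n_points,
                masked_points = res$masked_points),
     "correlation.csv", function(o, p) data.table::fwrite(o, p))
  prov <- list(package = "applebruise",
               version = as.character(utils::packageVersion("applebruise")),
               seed = cfg$seed, height_m = cfg$height_m,
               force_floor = cfg$force_floor,
               threshold = if (identical(cfg$threshold, "otsu")) "otsu"
                           else cfg$threshold,
               open_radius = cfg$open_radius, close_radius = cfg$close_radius,
               analysis = unclass(cfg$analysis))
  prov_path <- file.path(cfg$out_dir, "provenance.json")
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, digits = NA)
  files <- c(files, prov_path)

  list(r_depth = res$r_depth, r_width = res$r_width, n_points = res$n_points,
       masked_points = res$masked_points, height_m = cfg$height_m,
       result = res, files = files)
}

# deterministic per-sample seed below 2^31
derive_seed <- function(base, i) {
  as.integer((as.numeric(base) * 100003 + i * 7919) %% 2147483647)
}

#' Run a synthetic multi-height study
#'
#' Generates `n_per_height` coupled synthetic samples per drop height,
#' analyses each (through the rendered-image route or the fast analytic
#' truth route), and summarises the per-height correlation distributions.
#' One hammer simulation is reused per height (the hammer dynamics are
#' height-deterministic); apple-to-apple variability enters through the
#' coupling noise, widths and lateral offsets.
#'
#' Failed samples are recorded and skipped; the study continues.
#'
#' @param heights Drop heights in metres.
#' @param n_per_height Samples per height.
#' @param coupling A [coupling_params()].
#' @param route `"truth"` (correlate analytic profiles; default) or
#'   `"image"` (render, segment and measure each section image).
#' @param analysis An [analysis_config()]; its `yield_force_N` should sit on
#'   the generator's force scale for synthetic studies (default: the
#'   coupling's `yield_equiv_N`).
#' @param base_seed Base seed; per-sample seeds are derived from it.
#' @param out_dir Optional directory: per-sample outputs plus
#'   `study_results.csv` and `study_summary.csv` are written there.
#' @param sim_args Extra arguments passed to [simulator_params()].
#' @return A list of class `study_report`: `results` (per-sample data.frame),
#'   `summary` (per-height, from [summarize_by_height()]), `failures`.
#' @export
run_study <- function(heights, n_per_height, coupling = coupling_params(),
                      route = c("truth", "image"),
                      analysis = NULL, base_seed = 1L, out_dir = NULL,
                      sim_args = list()) {
  route <- match.arg(route)
  if (is.null(analysis))
    analysis <- analysis_config(yield_force_N = coupling$yield_equiv_N)
  results <- list()
  rows <- list()
  failures <- list()
  sample_id <- 0L
  for (hi in seq_along(heights)) {
    h <- heights[hi]
    sp <- do.call(simulator_params, c(list(drop_height_m = h), sim_args))
    sim <- simulate_impact(sp)
    for (si in seq_len(n_per_height)) {
      sample_id <- sample_id + 1L
      seed <- derive_seed(base_seed, sample_id)
      id <- sprintf("h%03.0f_s%02d", h * 1000, si)
      res <- tryCatch({
        cs <- make_coupled_sample(sp, coupling, seed = seed, sim = sim,
                                  render = (route == "image"))
        if (route == "image") {
          if (!is.null(out_dir)) {
            sdir <- file.path(out_dir, "samples", id)
            write_coupled_sample(cs, sdir)
            cfg <- run_config(sdir, file.path(out_dir, "reports", id),
                              height_m = h,
                              sensor = sp$sensor, analysis = analysis,
                              seed = seed)
            run_sample(cfg)$result
          } else {
            analyze_coupled_image(cs, analysis)
          }
        } else {
          analyze_coupled_truth(cs, analysis)
        }
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[id]] <- conditionMessage(res)
      } else {
        results[[id]] <- res
        rows[[id]] <- data.frame(sample_id = id, height_m = h,
                                 r_depth = res$r_depth,
                                 r_width = res$r_width,
                                 n_points = res$n_points,
                                 masked_points = res$masked_points)
      }
    }
  }
  if (length(results) == 0L) stop("study failed: no valid samples")
  res_df <- do.call(rbind, rows)
  rownames(res_df) <- NULL
  summ <- summarize_by_height(results)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(res_df, file.path(out_dir, "study_results.csv"))
    data.table::fwrite(summ, file.path(out_dir, "study_summary.csv"))
  }
  structure(list(results = res_df, summary = summ, failures = failures),
            class = "study_report")
}

#' Analyse a batch of sample directories
#'
#' Runs [run_sample()] over a set of sample directories; a failing sample is
#' recorded with its stage error and the batch continues.
#'
#' @param sample_dirs Character vector of sample directories.
#' @param heights_m Drop height per sample (recycled if length 1).
#' @param out_dir Reports are written under `out_dir/<sample name>`.
#' @param ... Further arguments passed to [run_config()].
#' @return List with `reports` (named list of successful reports) and
#'   `failures` (named character vector of error messages).
#' @export
run_batch <- function(sample_dirs, heights_m, out_dir, ...) {
  heights_m <- rep_len(heights_m, length(sample_dirs))
  reports <- list()
  failures <- character(0)
  for (k in seq_along(sample_dirs)) {
    id <- basename(sample_dirs[k])
    res <- tryCatch(
      run_sample(run_config(sample_dirs[k], file.path(out_dir, id),
                            heights_m[k], ...)),
      error = function(e) e)
    if (inherits(res, "error"))
      failures[id] <- conditionMessage(res)
    else reports[[id]] <- res
  }
  list(reports = reports, failures = failures)
}

# correlate a coupled sample through its analytic truth profiles
analyze_coupled_truth <- function(cs, analysis) {
  paired <- register_profiles(cs$truth$damage_profile, cs$energy_profile,
                              analysis, offset_mm = cs$truth$offset_mm)
  pk <- cs$peak_force$peak_force_N[match(round(paired$position_mm, 6),
                                         round(cs$peak_force$position_mm, 6))]
  paired <- apply_yield_mask(paired, pk, analysis)
  correlate_profiles(paired, height_m = cs$truth$height_m, analysis)
}

# segment + measure the rendered section, then correlate
analyze_coupled_image <- function(cs, analysis) {
  img <- cs$section$image
  s <- saturation_channel(img)
  mask <- segment_death_zone(s)
  peel <- trace_peel(img)
  damage <- depth_and_width(column_segments(mask), peel, img$scale_mm_per_px)
  paired <- register_profiles(damage, cs$energy_profile, analysis,
                              offset_mm = cs$truth$section_offset_mm)
  pk <- cs$peak_force$peak_force_N[match(round(paired$position_mm, 6),
                                         round(cs$peak_force$position_mm, 6))]
  paired <- apply_yield_mask(paired, pk, analysis)
  correlate_profiles(paired, height_m = cs$truth$height_m, analysis)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d sample(s), %d failure(s)\n",
              nrow(x$results), length(x$failures)))
  print(x$summary)
  invisible(x)
}
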