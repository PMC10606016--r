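test_that("undamped simulation conserves energy at the fine step", {
  p <- simulator_params(0.1, damping = 0, steps_per_frame = 200L)
  sim <- simulate_impact(p)
  kin <- sim$kinematics
  m <- p$hammer_mass_kg; k <- p$contact_stiffness
  ke <- 0.5 * m * kin$v_mps^2
  pe <- 0.4 * k * kin$delta_m^2.5 # Hertz elastic energy (2/5) k d^(5/2)
  e0 <- 0.5 * m * sim$v1^2
  expect_lt(max(abs(ke + pe - e0)) / e0, 0.001)
})

test_that("peak force grows with drop height", {
  peaks <- vapply(c(0.05, 0.1, 0.2), function(h)
    max(quick_sim(h)$kinematics$force_N), 0)
  expect_true(all(diff(peaks) > 0))
})

test_that("deposited energy never exceeds the free-fall kinetic energy", {
  set.seed(31)
  for (rep in 1:5) {
    h <- runif(1, 0.05, 0.2)
    p <- simulator_params(h, contact_stiffness = runif(1, 30, 200),
                          damping = runif(1, 0, 8), steps_per_frame = 150L)
    sim <- simulate_impact(p)
    expect_lte(sum(sim$truth_energy), 0.5 * 9.8 * h * (1 + 1e-6))
  }
})

test_that("generators are seed-deterministic and satisfy the readers", {
  p <- simulator_params(0.1, noise_sd = 0.02, seed = 42L,
                        steps_per_frame = 150L)
  s1 <- simulate_impact(p)
  s2 <- simulate_impact(p)
  expect_identical(s1$stack$forces, s2$stack$forces)
  # reader round trip on generator output
  path <- withr::local_tempfile(fileext = ".csv")
  write_frame_stack(s1$stack, path)
  expect_equal(read_frame_stack(path, p$sensor)$forces, s1$stack$forces)

  r1 <- render_section(section_params(seed = 7))
  r2 <- render_section(section_params(seed = 7))
  expect_identical(r1$image$rgb, r2$image$rgb)
  expect_false(identical(
    r1$image$rgb, render_section(section_params(seed = 8))$image$rgb))

  c1 <- make_coupled_sample(p, seed = 5L, sim = s1)
  c2 <- make_coupled_sample(p, seed = 5L, sim = s1)
  expect_identical(c1$truth$damage_profile, c2$truth$damage_profile)
})

test_that("reconstructed total energy converges to the fine-dt truth with Z", {
  errs <- vapply(c(60, 240, 960), function(Z) {
    sn <- sensor_spec(frame_rate = Z)
    sim <- simulate_impact(simulator_params(0.1, sensor = sn,
                                            steps_per_frame =
                                              max(20L, 1200L %/% Z)))
    st <- trim_to_effective_frames(sim$stack)
    kin <- suppressWarnings(velocity_series(st, impact_config(0.1)))
    abs(sum(energy_map(st, kin)$energy) - sum(sim$truth_energy)) /
      sum(sim$truth_energy)
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("rendered gaps produce empty segments under a perfect segmenter", {
  sp <- section_params(seed = 11, gap_spec = list(c(4, 5.5)),
                       depth_profile = 2.5, width_profile = 0.8)
  rs <- render_section(sp)
  lateral <- rs$damage_truth$lateral_mm
  gap_cols <- lateral >= 4 & lateral <= 5.5
  expect_false(any(rs$damage_truth$defined[gap_cols]))
  segs <- column_segments(rs$band_mask) # truth mask = perfect segmenter
  expect_true(all(lengths(segs[gap_cols]) == 0))
  expect_true(all(lengths(segs[!gap_cols]) > 0))
})

test_that("renderer validates band geometry", {
  expect_error(render_section(section_params(depth_profile = 0.8)),
               ">= 1.2 mm")
  expect_error(render_section(section_params(depth_profile = 30)),
               "outside the image")
})

test_that("noise-free coupling gives exact depth-energy proportionality", {
  sp <- simulator_params(0.125, steps_per_frame = 200L)
  cp <- coupling_params(sigma0_mm = 0)
  cs <- make_coupled_sample(sp, cp, seed = 3L)
  sup <- cs$truth$support
  d <- cs$truth$damage_profile$depth_mm[sup]
  e <- cs$energy_profile$energy_J[sup]
  expect_equal(d, 1.2 + cp$alpha_mm_per_J * e, tolerance = 1e-12)
})

test_that("depth noise scales down and width stays independent as height grows", {
  cp <- coupling_params()
  s_low <- make_coupled_sample(simulator_params(0.05, steps_per_frame = 150L),
                               cp, seed = 1L)
  s_high <- make_coupled_sample(simulator_params(0.2, steps_per_frame = 150L),
                                cp, seed = 1L)
  expect_gt(s_low$truth$sigma_mm, s_high$truth$sigma_mm)
  expect_equal(s_low$truth$sigma_mm, 0.2 * 0.2 / 0.05)
})

test_that("coupled samples round-trip through the on-disk formats", {
  sp <- simulator_params(0.1, steps_per_frame = 150L)
  cs <- make_coupled_sample(sp, seed = 9L, render = TRUE)
  dir <- withr::local_tempdir()
  write_coupled_sample(cs, dir)
  expect_true(all(file.exists(file.path(
    dir, c("frames.csv", "calibration.csv", "section.png",
           "section.png.json", "truth.json")))))
  st <- read_frame_stack(file.path(dir, "frames.csv"), sp$sensor)
  expect_equal(st$forces, cs$stack$forces)
  tr <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  expect_equal(tr$offset_mm, cs$truth$offset_mm)
  expect_equal(tr$damage_profile$depth_mm,
               cs$truth$damage_profile$depth_mm)
})
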