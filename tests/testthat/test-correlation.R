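test_that("pearson_r matches the covariance-formula oracle", {
  x <- 1:10
  expect_equal(as.numeric(pearson_r(x, 2 * x + 1)), 1.0)
  expect_equal(as.numeric(pearson_r(x, -x)), -1.0)
  set.seed(21)
  a <- rnorm(20); b <- rnorm(20)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(as.numeric(pearson_r(a, b)), oracle, tolerance = 1e-12)
  expect_error(pearson_r(1:4, 1:5), "lengths differ")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("zero-variance series give a flagged undefined r", {
  r <- pearson_r(rep(1, 5), 1:5)
  expect_true(is.na(r))
  expect_false(attr(r, "defined"))
})

test_that("pearson_r is affine-invariant and sign-flips under negation", {
  set.seed(22)
  x <- rnorm(15); y <- rnorm(15)
  r0 <- as.numeric(pearson_r(x, y))
  expect_equal(as.numeric(pearson_r(3 * x + 2, 0.5 * y - 1)), r0)
  expect_equal(as.numeric(pearson_r(-x, y)), -r0)
})

make_energy_profile <- function(e, pitch = 1.9) {
  structure(data.frame(position_mm = (seq_along(e) - 1) * pitch,
                       energy_J = e),
            class = c("energy_profile", "data.frame"),
            center_index = which.max(e),
            center_mm = (which.max(e) - 1) * pitch,
            axis = "row", pitch_mm = pitch)
}

test_that("metadata registration with coincident frames is positional identity", {
  e <- c(0, 1, 3, 8, 12, 8, 3, 1, 0, 0)
  ep <- make_energy_profile(e)
  damage <- structure(
    data.frame(lateral_mm = ep$position_mm, depth_mm = 1.2 + e,
               width_mm = 1, defined = TRUE),
    class = c("damage_profile", "data.frame"))
  paired <- register_profiles(damage, ep, analysis_config(), offset_mm = 0)
  expect_equal(paired$depth_mm, 1.2 + paired$energy_J)
  expect_equal(as.numeric(pearson_r(paired$depth_mm, paired$energy_J)), 1)
})

test_that("peak alignment recovers a constructed shift", {
  e <- c(0, 1, 3, 8, 12, 8, 3, 1, 0, 0)
  ep <- make_energy_profile(e)
  shift <- 2 * 1.9
  damage <- structure(
    data.frame(lateral_mm = ep$position_mm - shift, depth_mm = 1.2 + e,
               width_mm = 1, defined = TRUE),
    class = c("damage_profile", "data.frame"))
  cfg <- analysis_config(registration = "peak_align")
  paired <- register_profiles(damage, ep, cfg)
  expect_equal(attr(paired, "offset_mm"), shift)
  expect_equal(as.numeric(pearson_r(paired$depth_mm, paired$energy_J)), 1)
})

test_that("registration rejects degenerate overlap", {
  ep <- make_energy_profile(c(0, 2, 5, 2, 0))
  damage <- structure(
    data.frame(lateral_mm = c(0, 1.9), depth_mm = c(2, 2.1), width_mm = 1,
               defined = TRUE),
    class = c("damage_profile", "data.frame"))
  expect_error(register_profiles(damage, ep, analysis_config(),
                                 offset_mm = 100), "overlap")
})

test_that("yield masking removes exactly the sub-yield points", {
  e <- c(2, 4, 6, 8, 10)
  paired <- structure(
    data.frame(position_mm = (0:4) * 1.9, depth_mm = 1 + e, width_mm = 1,
               energy_J = e),
    class = c("paired_profiles", "data.frame"))
  cfg_on <- analysis_config(mask_sub_yield = TRUE)
  # all at or above yield: no-op
  same <- apply_yield_mask(paired, rep(9, 5), cfg_on)
  expect_equal(nrow(same), 5L)
  expect_equal(attr(same, "masked_points"), 0L)
  # mixed: 8.75 N default cutoff keeps 3 of 5
  out <- apply_yield_mask(paired, c(5, 9, 10, 3, 12), cfg_on)
  expect_equal(nrow(out), 3L)
  expect_equal(attr(out, "masked_points"), 2L)
  # masking off: untouched
  off <- apply_yield_mask(paired, c(5, 9, 10, 3, 12),
                          analysis_config(mask_sub_yield = FALSE))
  expect_equal(nrow(off), 5L)
  expect_error(apply_yield_mask(paired, rep(0, 5), cfg_on), "degenerate")
  expect_error(apply_yield_mask(paired, rep(9, 4), cfg_on), "align")
})

test_that("sub-yield zero-depth sites distort r; masking restores the relation", {
  # the never-bruised sites carry depth 0 against nonzero energy, breaking
  # the otherwise exact linear depth-energy relation; masking them recovers
  # r = 1 exactly in the noise-free sample
  sp <- simulator_params(0.05, steps_per_frame = 200L)
  sim <- simulate_impact(sp)
  cp <- coupling_params(sigma0_mm = 0)
  cfg_off <- analysis_config(yield_force_N = cp$yield_equiv_N,
                             mask_sub_yield = FALSE)
  cfg_on <- analysis_config(yield_force_N = cp$yield_equiv_N,
                            mask_sub_yield = TRUE)
  cs <- make_coupled_sample(sp, cp, seed = 2L, sim = sim)
  paired <- register_profiles(cs$truth$damage_profile, cs$energy_profile,
                              cfg_off, offset_mm = cs$truth$offset_mm,
                              undefined_as_zero = TRUE)
  pk <- cs$peak_force$peak_force_N[match(round(paired$position_mm, 6),
                                         round(cs$peak_force$position_mm, 6))]
  r_off <- correlate_profiles(paired, 0.05, cfg_off)$r_depth
  masked <- apply_yield_mask(paired, pk, cfg_on)
  r_on <- correlate_profiles(masked, 0.05, cfg_on)$r_depth
  expect_gt(attr(masked, "masked_points"), 0L)
  expect_equal(r_on, 1.0, tolerance = 1e-9)
  expect_lt(r_off, r_on)
})

test_that("height summaries aggregate r correctly", {
  mk <- function(h, rd, rw = 0.2)
    structure(list(r_depth = rd, r_width = rw, n_points = 10L,
                   masked_points = 0L, height_m = h),
              class = "correlation_result")
  one <- summarize_by_height(list(mk(0.1, 0.9)))
  expect_equal(one$r_depth_min, one$r_depth_max)
  expect_equal(one$r_depth_mean, 0.9)
  s <- summarize_by_height(list(mk(0.1, 0.4), mk(0.1, 0.6), mk(0.1, 0.8),
                                mk(0.2, 0.95)))
  expect_equal(s$r_depth_min[s$height_m == 0.1], 0.4)
  expect_equal(s$r_depth_mean[s$height_m == 0.1], 0.6)
  expect_equal(s$r_depth_max[s$height_m == 0.1], 0.8)
  expect_equal(nrow(s), 2L)
  expect_error(summarize_by_height(list()), "no correlation")
})
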