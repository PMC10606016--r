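test_that("first-frame velocity matches the free-fall closed form", {
  st <- stack_with_totals(c(1, 1))
  for (h in c(0.05, 0.1, 0.125, 0.2)) {
    kin <- velocity_series(st, impact_config(h))
    expect_equal(kin$velocity[1], sqrt(2 * 9.8 * h), tolerance = 1e-14)
  }
  expect_equal(velocity_series(st, impact_config(0.05))$velocity[1],
               0.98994949366, tolerance = 1e-9)
})

test_that("zero impulse leaves the velocity constant; S_f = V_f / Z", {
  sn <- small_sensor()
  st <- frame_stack(array(0, dim = c(sn$rows, sn$cols, 4L)), sn)
  kin <- velocity_series(st, impact_config(0.1))
  expect_equal(kin$velocity, rep(sqrt(2 * 9.8 * 0.1), 4L))
  expect_equal(kin$displacement, kin$velocity / sn$frame_rate)
})

test_that("series truncates when the impulse spends the incoming momentum", {
  h <- 0.05
  cfg <- impact_config(h)
  v1 <- sqrt(2 * 9.8 * h)
  Z <- 60
  # each frame removes exactly a quarter of m*v1: V hits 0 entering frame 5
  ftot <- rep(cfg$hammer_mass_kg * v1 * Z / 4, 6)
  st <- stack_with_totals(ftot)
  expect_warning(kin <- velocity_series(st, cfg), "truncated")
  expect_equal(kin$n_frames, 4L)
  expect_true(kin$truncated)
  # independent impulse bookkeeping oracle
  v_oracle <- v1
  for (f in 1:3) v_oracle <- c(v_oracle, v1 - sum(ftot[1:f]) / (0.5 * Z))
  expect_equal(kin$velocity, v_oracle)
  expect_true(all(diff(kin$velocity) <= 0))
})

test_that("energy map is the force-displacement sum per sensing point", {
  sn <- small_sensor()
  forces <- array(0, dim = c(sn$rows, sn$cols, 1L))
  forces[4, 5, 1] <- 1
  st <- frame_stack(forces, sn)
  kin <- velocity_series(st, impact_config(0.1))
  em <- energy_map(st, kin)
  expect_equal(em$energy[4, 5], 1 * kin$displacement[1])
  expect_equal(sum(em$energy > 0), 1L)

  # exchange-of-summation identity on a random stack
  st2 <- random_stack(n_frames = 5L, seed = 3)
  kin2 <- suppressWarnings(velocity_series(st2, impact_config(0.2)))
  em2 <- energy_map(st2, kin2)
  lp <- kin2$n_frames
  expect_equal(sum(em2$energy),
               sum(total_force(st2)[seq_len(lp)] *
                     kin2$displacement[seq_len(lp)]))
})

test_that("reconstruction agrees with the fine-dt work oracle per stated tolerance", {
  # 60 fps: within 10 %; 600 fps: within 1 %
  for (cse in list(list(Z = 60, tol = 0.10), list(Z = 600, tol = 0.01))) {
    sn <- sensor_spec(frame_rate = cse$Z)
    sim <- simulate_impact(simulator_params(0.1, sensor = sn,
                                            steps_per_frame = 200L))
    st <- trim_to_effective_frames(sim$stack)
    kin <- suppressWarnings(velocity_series(st, impact_config(0.1)))
    em <- energy_map(st, kin)
    oracle <- trapz(sim$kinematics$t,
                    sim$kinematics$force_N * sim$kinematics$v_mps)
    expect_lt(abs(sum(em$energy) - oracle) / oracle, cse$tol)
  }
})

test_that("energy is bounded by the free-fall kinetic energy plus the frame bound", {
  for (h in c(0.05, 0.2)) {
    sim <- quick_sim(h)
    st <- trim_to_effective_frames(sim$stack)
    cfg <- impact_config(h)
    kin <- suppressWarnings(velocity_series(st, cfg))
    em <- energy_map(st, kin)
    # discretization bound: (dt^2/m) * sum of squared frame forces
    Z <- st$sensor$frame_rate
    tot <- total_force(st)[seq_len(kin$n_frames)]
    bound <- sum(tot^2) / (Z^2 * cfg$hammer_mass_kg)
    mgh <- cfg$hammer_mass_kg * 9.8 * h
    expect_lte(sum(em$energy), mgh + bound + 1e-9)
    expect_true(all(em$energy >= 0))
  }
})

test_that("scaling forces down never increases energy at fixed kinematics", {
  st <- random_stack(n_frames = 4L, seed = 9)
  kin <- suppressWarnings(velocity_series(st, impact_config(0.2)))
  e1 <- energy_map(st, kin)$energy
  for (c_scale in c(0.2, 0.7, 1)) {
    st2 <- frame_stack(st$forces * c_scale, st$sensor)
    e2 <- energy_map(st2, kin)$energy
    expect_true(all(e2 <= e1 + 1e-12))
  }
})

test_that("energy profile slices through the impact centre", {
  sn <- small_sensor()
  e <- matrix(0, sn$rows, sn$cols)
  e[3, 6] <- 2
  em <- structure(list(energy = e, sensor = sn), class = "energy_map")
  expect_equal(impact_center(em), c(3L, 6L))
  prof <- energy_profile(em, axis = "row")
  expect_equal(nrow(prof), sn$cols)
  expect_equal(which.max(prof$energy_J), 6L)
  expect_equal(attr(prof, "center_mm"), (6 - 1) * 1.9)
  expect_equal(diff(prof$position_mm), rep(1.9, sn$cols - 1L))

  # symmetric map gives a symmetric profile
  x <- seq_len(sn$cols)
  g <- exp(-(x - 5)^2 / 4)
  em2 <- structure(list(energy = outer(g, g), sensor = sn),
                   class = "energy_map")
  p2 <- energy_profile(em2, axis = "row", center = c(5L, 5L))
  expect_equal(p2$energy_J[5 - 1:3], p2$energy_J[5 + 1:3], tolerance = 1e-12)

  em0 <- structure(list(energy = matrix(0, 8, 8), sensor = sn),
                   class = "energy_map")
  expect_error(energy_profile(em0), "no impact")
})

test_that("simulated impact peak sits at the configured contact centre", {
  sim <- simulate_impact(simulator_params(0.1, contact_center = c(4, 5),
                                          sensor = small_sensor(12L),
                                          steps_per_frame = 200L))
  st <- trim_to_effective_frames(sim$stack)
  kin <- suppressWarnings(velocity_series(st, impact_config(0.1)))
  expect_equal(impact_center(energy_map(st, kin)), c(4L, 5L))
})
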