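# Synthetic-trajectory generator: determinism, ground-truth consistency,
# separability.

test_that("identical seeds give bit-identical trajectories", {
  scn <- growth_scenario(box = c(15, 20, 30), z0 = 8, velocity = 1,
                         n_frames = 10, seed = 42)
  g1 <- generate_growth_trajectory(scn)
  g2 <- generate_growth_trajectory(scn)
  expect_identical(g1$traj$coords, g2$traj$coords)
  expect_identical(g1$truth$ice, g2$truth$ice)
  g3 <- generate_growth_trajectory(growth_scenario(box = c(15, 20, 30),
                                                   z0 = 8, velocity = 1,
                                                   n_frames = 10, seed = 43))
  expect_false(identical(g1$traj$coords, g3$traj$coords))
})

test_that("zero-velocity flat fronts give a constant ice fraction", {
  scn <- growth_scenario(box = c(15, 25, 35), front = "flat", z0 = 10,
                         velocity = 0, n_frames = 30, seed = 2)
  g <- generate_growth_trajectory(scn)
  lab <- classify_ice(g$traj)
  fr <- ice_fraction(lab, g$traj, region = c(2, Inf))
  expect_lt(diff(range(fr$fraction)), 0.02)
})

test_that("the advancing front recovered per frame grows at the set velocity", {
  v <- 2  # A/ns
  scn <- growth_scenario(box = c(12, 25, 50), front = "flat", z0 = 8,
                         velocity = v, n_frames = 60, seed = 6)
  g <- generate_growth_trajectory(scn)
  # recover the front per 10-frame block via occupancy + extraction
  blocks <- split(seq_len(60), rep(1:6, each = 10))
  h <- t_mid <- numeric(length(blocks))
  for (b in seq_along(blocks)) {
    fs <- extract_front(suppressWarnings(
      occupancy_map(g$traj, t_start = g$traj$time[blocks[[b]][1]],
                    t_end = g$traj$time[blocks[[b]][10]])),
      threshold = 0.85, seed_top_z = 1)
    h[b] <- mean(fs$height)
    t_mid[b] <- mean(g$traj$time[blocks[[b]]])
  }
  fit <- lm(h ~ t_mid)
  v_rec <- unname(coef(fit)[2]) * 1000  # A/ps -> A/ns
  expect_equal(v_rec, v, tolerance = 0.25)
})

test_that("ground-truth labels are consistent with the emitted coordinates", {
  scn <- growth_scenario(box = c(15, 20, 40), z0 = 10, velocity = 3,
                         n_frames = 25, seed = 9)
  g <- generate_growth_trajectory(scn)
  # ice-labelled waters sit within a few vibration SDs of their sites
  for (f in c(1, 12, 25)) {
    ice <- which(g$truth$ice[, f])
    site <- g$truth$site_of_water[ice]
    d <- g$traj$coords[ice, , f] - g$truth$site_xyz[site, ]
    expect_lt(max(abs(d)), 5 * scn$vibration)
  }
})

test_that("non-separable scenario parameters trigger warnings", {
  expect_warning(growth_scenario(vibration = 0.9), "not be separable|not below")
  expect_warning(growth_scenario(diffusion = 0.001), "separable")
  expect_error(growth_scenario(front = "cylindrical", radius = 20,
                               pin_spacing = 60), "arc")
})

test_that("the water budget must cover the sites that freeze", {
  expect_error(generate_growth_trajectory(
    growth_scenario(box = c(15, 20, 30), z0 = 12, n_waters = 50,
                    n_frames = 5, seed = 1)), "cannot cover")
})

test_that("bound-from-start and never-binding tracks behave as planted", {
  tr0 <- generate_binding_track(bind_time_ns = 0, pin_z = 25, seed = 3)
  expect_lt(sd(tr0$com_z), 0.5)
  expect_equal(tr0$truth$bind_time, 0)
  trN <- generate_binding_track(bind_time_ns = NULL, pin_z = 25, seed = 3)
  expect_true(is.na(trN$truth$bind_time))
  expect_true(all(trN$com_z >= 25 + 5 - 1e-9))
  # determinism
  trN2 <- generate_binding_track(bind_time_ns = NULL, pin_z = 25, seed = 3)
  expect_identical(trN$com_z, trN2$com_z)
})
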