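# Occupancy maps, front extraction and cylinder fitting.

test_that("an immobile lattice has unit occupancy at its voxels and zero elsewhere", {
  nf <- 5
  coords <- array(0, c(2, 3, nf))
  coords[1, , ] <- c(5.5, 5.5, 5.5)
  coords[2, , ] <- c(15.5, 15.5, 5.5)
  traj <- trajectory(coords, box = c(24, 24, 24), dt_frame = 100)
  occ <- suppressWarnings(occupancy_map(traj))
  expect_equal(occ$grid[6, 6, 6], 1)    # voxel centred on the atom
  expect_equal(occ$grid[16, 16, 6], 1)
  expect_equal(occ$grid[12, 12, 20], 0) # empty region
  expect_true(all(occ$grid >= 0 & occ$grid <= 1))
})

test_that("ideal-gas occupancy matches the Poisson closed form", {
  set.seed(12)
  n <- 150; nf <- 150
  box <- c(20, 20, 20)
  coords <- array(runif(n * 3 * nf) * 20, c(n, 3, nf))
  traj <- trajectory(coords, box = box, dt_frame = 100)
  occ <- occupancy_map(traj)
  # effective marked volume per atom: Minkowski sum of the 1 A voxel cube
  # and the 1.4 A sphere
  a <- 1; r <- 1.4
  v_eff <- a^3 + 6 * a^2 * r + 3 * pi * a * r^2 + 4 / 3 * pi * r^3
  p_hit <- 1 - (1 - v_eff / prod(box))^n
  se <- sd(occ$grid) / sqrt(length(occ$grid) / 50)  # conservative (corr.)
  expect_lt(abs(mean(occ$grid) - p_hit), max(3 * se, 0.02))
})

test_that("occupancy is invariant under whole-system voxel translation", {
  set.seed(13)
  n <- 60; nf <- 8
  coords <- array(runif(n * 3 * nf) * 18, c(n, 3, nf))
  traj <- trajectory(coords, box = c(18, 18, 18), dt_frame = 100)
  shifted <- coords
  shifted[, 1, ] <- (shifted[, 1, ] + 3) %% 18
  traj2 <- trajectory(shifted, box = c(18, 18, 18), dt_frame = 100)
  o1 <- suppressWarnings(occupancy_map(traj))
  o2 <- suppressWarnings(occupancy_map(traj2))
  expect_equal(sum(o1$grid), sum(o2$grid))
  # periodic x: the grid itself is circularly shifted by 3 voxels
  expect_equal(o2$grid[(((0:17) + 3) %% 18) + 1, , ], o1$grid,
               ignore_attr = TRUE)
})

test_that("zero-length occupancy windows are rejected", {
  coords <- array(0, c(1, 3, 3))
  traj <- trajectory(coords, box = c(5, 5, 5))
  expect_error(occupancy_map(traj, t_start = 900, t_end = 1000),
               "zero-length")
})

test_that("a flat frozen slab yields a flat height field at the slab top", {
  # dense immobile slab (grid spacing 2 A) filled to z = 10
  pts <- as.matrix(expand.grid(x = seq(0.5, 11.5, 2), y = seq(0.5, 29.5, 2),
                               z = seq(0.5, 9.5, 2)))
  nf <- 5
  coords <- array(rep(t(pts), nf), c(3, nrow(pts), nf))
  coords <- aperm(coords, c(2, 1, 3))
  traj <- trajectory(coords, box = c(12, 30, 30), dt_frame = 100)
  occ <- suppressWarnings(occupancy_map(traj))
  fs <- extract_front(occ, threshold = 0.85, seed_top_z = 1)
  expect_lt(max(abs(fs$height - 10)), 1 + occ$voxel)
  # lattice-based generator: flat verdict despite surface-site corrugation
  scn <- growth_scenario(box = c(12, 30, 30), front = "flat", z0 = 10,
                         n_frames = 50, seed = 14)
  g <- generate_growth_trajectory(scn)
  occ2 <- suppressWarnings(occupancy_map(g$traj))
  fs2 <- extract_front(occ2, threshold = 0.85, seed_top_z = 1)
  expect_lt(abs(mean(fs2$height) - 10), 1.5)
  fit <- fit_cylinder(fs2)
  expect_false(fit$finite)
  expect_identical(fit$radius, Inf)
})

test_that("raising the threshold gives a sparser above-threshold set", {
  scn <- growth_scenario(box = c(12, 20, 25), front = "flat", z0 = 8,
                         vibration = 0.45, n_frames = 40, seed = 15)
  g <- generate_growth_trajectory(scn)
  occ <- suppressWarnings(occupancy_map(g$traj))
  expect_lte(sum(occ$grid > 0.95), sum(occ$grid > 0.85))
  expect_error(extract_front(occ, threshold = 1), "no voxel above")
})

test_that("cylindrical pinned fronts are recovered within tolerance", {
  scn <- growth_scenario(box = c(12, 80, 60), front = "cylindrical",
                         z0 = 12, radius = 46, pin_spacing = 80,
                         front_noise_sd = 1, n_frames = 60, seed = 5)
  g <- generate_growth_trajectory(scn)
  occ <- suppressWarnings(occupancy_map(g$traj))
  fs <- extract_front(occ, threshold = 0.85, seed_top_z = 1)
  prof <- colMeans(fs$height)
  expect_lt(sqrt(mean((prof - g$truth$front[1, ])^2)), 1.5)
  fit <- fit_cylinder(fs)
  expect_true(fit$finite)
  expect_true(fit$convex_toward_liquid)
  expect_lt(abs(fit$radius - 46), 3)
})

test_that("exact profiles fit exactly and flat profiles report no finite curvature", {
  y <- seq(-40, 40, 1)
  semi <- list(y = y, height = sqrt(50^2 - y^2))
  fit <- fit_cylinder(semi)
  expect_equal(fit$radius, 50, tolerance = 1e-9)
  expect_equal(fit$residual, 0, tolerance = 1e-9)
  flat <- fit_cylinder(list(y = y, height = rep(7, length(y))))
  expect_false(flat$finite)
  expect_error(fit_cylinder(list(y = 1:3, height = 1:3)), "at least 5")
})
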