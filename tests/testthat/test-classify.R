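# Mobility classification, ice fractions and equilibration statistics.

make_traj <- function(coords, box = c(20, 20, 20), roles = NULL, dt = 100) {
  trajectory(coords, box = box, dt_frame = dt, roles = roles)
}

test_that("stationary waters are ice and translating waters are liquid", {
  nf <- 6
  coords <- array(0, c(2, 3, nf))
  coords[1, , ] <- c(5, 5, 5)                      # perfectly still
  for (f in seq_len(nf)) coords[2, , f] <- c(5 + f * 1.0, 10, 10)  # 1 A/frame
  lab <- classify_ice(make_traj(coords))
  def <- seq_len(nf - 2)
  expect_true(all(lab$ice[1, def]))
  expect_true(all(!lab$ice[2, def]))
  expect_true(all(is.na(lab$ice[, (nf - 1):nf])))
})

test_that("displacements are unwrapped across the periodic boundary", {
  # drift crossing x = 0: raw positions jump by the box length
  nf <- 5
  coords <- array(0, c(1, 3, nf))
  x <- c(19.6, 19.9, 0.2, 0.5, 0.8)
  for (f in seq_len(nf)) coords[1, , f] <- c(x[f], 5, 5)
  lab <- classify_ice(make_traj(coords))
  expect_true(all(lab$ice[1, 1:3]))   # 0.3 A/frame drift stays under 0.8 A
})

test_that("the classifier is monotone in its threshold", {
  set.seed(4)
  coords <- array(runif(60 * 3 * 8, 0, 20), c(60, 3, 8))
  # mixture: half vibrate tightly, half diffuse
  for (i in 1:30) coords[i, , ] <- coords[i, , 1] +
      array(rnorm(3 * 8, 0, 0.25), c(3, 8))
  traj <- make_traj(coords)
  tight <- classify_ice(traj, disp_threshold = 0.6)
  loose <- classify_ice(traj, disp_threshold = 0.8)
  def <- !is.na(tight$ice)
  expect_true(all(!tight$ice[def] | loose$ice[def]))
})

test_that("time reversal mirrors the label matrix", {
  set.seed(5)
  coords <- array(runif(20 * 3 * 7, 0, 20), c(20, 3, 7))
  traj <- make_traj(coords)
  rev_traj <- make_traj(coords[, , 7:1])
  a <- classify_ice(traj)
  b <- classify_ice(rev_traj)
  w <- 3
  for (t0 in seq_len(7 - w + 1))
    expect_identical(b$ice[, t0], a$ice[, 7 - t0 - w + 2])
})

test_that("endpoint mode measures first-to-last displacement", {
  nf <- 4
  coords <- array(0, c(1, 3, nf))
  # oscillates: returns to start every 2 frames, excursion 0.6 A
  for (f in seq_len(nf)) coords[1, , f] <- c(5 + 0.6 * (f %% 2), 5, 5)
  lab_m <- classify_ice(make_traj(coords), mode = "mean")
  lab_e <- classify_ice(make_traj(coords), mode = "endpoint")
  expect_true(all(lab_e$ice[1, 1:2]))  # endpoints coincide
  expect_true(all(lab_m$ice[1, 1:2]))  # excursion below threshold too
})

test_that("window longer than the trajectory is an error", {
  coords <- array(0, c(1, 3, 2))
  expect_error(classify_ice(make_traj(coords), window_frames = 3),
               "at least")
})

test_that("ice fraction is exact on constructed regions", {
  nf <- 5
  coords <- array(0, c(8, 3, nf))
  for (i in 1:4) coords[i, , ] <- c(i * 2, 5, 12)       # frozen, in region
  for (i in 5:8) for (f in seq_len(nf))
    coords[i, , f] <- c(i * 2, 5 + 1.5 * f, 15)          # mobile, in region
  roles <- rep("water", 8)
  traj <- make_traj(coords, roles = roles)
  lab <- classify_ice(traj)
  fr <- ice_fraction(lab, traj, region = c(10, Inf))
  expect_equal(fr$fraction, rep(0.5, nrow(fr)))
  # fully frozen region
  fr1 <- ice_fraction(lab, traj, region = c(10, 13))
  expect_equal(fr1$fraction, rep(1, nrow(fr1)))
  expect_error(ice_fraction(lab, traj, region = c(40, Inf)), "no waters")
  expect_error(ice_fraction(lab, traj, region = c(10, 5)), "empty region")
  # default region needs seed atoms
  expect_error(ice_fraction(lab, traj), "seed")
})

test_that("synthetic advancing front gives a non-decreasing fraction that matches truth", {
  scn <- growth_scenario(box = c(20, 30, 50), z0 = 10, velocity = 2,
                         n_frames = 40, n_waters = 700, seed = 8)
  g <- generate_growth_trajectory(scn)
  lab <- classify_ice(g$traj)
  fr <- ice_fraction(lab, g$traj, region = c(10, Inf))
  expect_true(all(diff(fr$fraction) > -0.03))
  def <- which(colSums(!is.na(lab$ice)) > 0)
  last <- max(def)
  z <- g$traj$coords[, 3, last]
  inr <- z > 10
  truth_frac <- mean(g$truth$ice[inr, last])
  expect_equal(fr$fraction[fr$time == g$traj$time[last]], truth_frac,
               tolerance = 0.02)
})

test_that("equilibrium statistics are exact on noiseless series", {
  t <- seq(0, 5000, 100)
  const <- data.frame(time = t, fraction = rep(0.3, length(t)))
  s <- equilibrium_stats(const)
  expect_equal(s$sd, 0)
  expect_equal(s$slope, 0, tolerance = 1e-12)
  ramp <- data.frame(time = t, fraction = 1e-4 * t)
  s2 <- equilibrium_stats(ramp)
  expect_equal(s2$slope, 1e-4, tolerance = 1e-12)
  expect_false(s2$equilibrated)
  expect_error(equilibrium_stats(ramp, 0, 400), "at least 10")
})

test_that("equilibrated synthetic fractions recover the generator mean", {
  set.seed(21)
  t <- seq(0, 2e4, 100)
  frac <- rnorm(length(t), 0.46, 0.01)
  s <- equilibrium_stats(data.frame(time = t, fraction = frac))
  expect_lt(abs(s$mean - 0.46), 3 * 0.01)
  expect_true(s$equilibrated)
  expect_equal(s$sd, 0.01, tolerance = 0.25)
})
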