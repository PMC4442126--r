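# Seed tilting, barrier, solvation and AFP placement.

make_lattice <- function(box, thickness = 6, seed = 3) {
  spec <- lattice_spec(n_a = ceiling(box[1] / 4.5) + 1L,
                       n_b = ceiling((box[2] + 20) / 7.4) + 1L,
                       n_c = max(1L, ceiling((thickness + 6) /
                                               (sqrt(3) * 4.5))),
                       proton_seed = seed)
  assign_protons(build_ice_lattice(spec), seed = seed)
}

test_that("zero tilt with no step leaves the prism plane parallel to y", {
  box <- c(25, 50, 40)
  lat <- make_lattice(box)
  s <- tilt_seed(lat, seed_spec(tilt_angle = 0, step_height = 0,
                                mode = "exact"), box)
  expect_equal(s$tilt_angle, 0)
  # prism plane parallel to y: top-face z does not drift with y
  top <- s$xyz[s$xyz_lat[, 3] > max(s$xyz_lat[, 3]) - 0.1, ]
  expect_lt(diff(range(top[, 3])), 1e-6)
})

test_that("the computed tilt angle follows the closed-form arctangent", {
  d_layer <- 4.5 * sqrt(3) / 2
  expect_equal(d_layer, 3.897, tolerance = 1e-3)
  expect_equal(computed_tilt_angle(1, d_layer, 126.6), 1.76,
               tolerance = 0.005)
})

test_that("snapped tilt makes the y-periodic image land an integer number of layers up", {
  box <- c(25, 60, 40)
  lat <- make_lattice(box)
  s <- tilt_seed(lat, seed_spec(tilt_angle = 4.3), box)
  pc <- periodic_consistency(s)
  expect_true(pc$ok)
  expect_lt(pc$rmsd, 0.1)
  expect_equal(pc$layer_offset, s$n_layers, tolerance = 1e-9)
  expect_gte(s$n_layers, 1L)
})

test_that("exact mode rejects angles incompatible with the periodic boundary", {
  box <- c(25, 126.6, 60)
  lat <- make_lattice(box)
  expect_error(tilt_seed(lat, seed_spec(tilt_angle = 4.3, mode = "exact"),
                         box),
               "not consistent with the y-periodic boundary")
})

test_that("a lattice smaller than the box footprint is rejected", {
  lat <- make_lattice(c(20, 30, 40))
  expect_error(tilt_seed(lat, seed_spec(), c(60, 200, 60)), "smaller than")
})

test_that("barrier layer fills at target density, clash-free", {
  box <- c(25, 40, 40)
  b <- build_barrier(box, thickness = 5, seed = 2)
  n_expect <- 997 / 0.018 * N_AVOGADRO * 1e-30 * 25 * 40 * 5
  expect_equal(nrow(b), round(n_expect))
  expect_true(all(b$z >= 0 & b$z <= 5))
  p <- as.matrix(b)
  dmin <- min(dist(p))  # non-periodic lower bound; periodic pairs checked below
  for (i in seq_len(nrow(p))) {
    d <- sweep(p, 2, p[i, ])
    d[, 1] <- d[, 1] - box[1] * round(d[, 1] / box[1])
    d[, 2] <- d[, 2] - box[2] * round(d[, 2] / box[2])
    dd <- sqrt(rowSums(d^2))
    expect_gte(min(dd[-i]), 2.2)
  }
  expect_identical(nrow(build_barrier(box, thickness = 0)), 0L)
})

test_that("solvation avoids existing atoms and reports zero when full", {
  box <- c(20, 20, 20)
  existing <- as.matrix(expand.grid(x = seq(1, 19, 2.8),
                                    y = seq(1, 19, 2.8),
                                    z = seq(1, 19, 2.8)))
  free <- solvate(existing, box, target_density = 997, seed = 4)
  if (nrow(free)) {
    for (i in seq_len(nrow(free))) {
      d <- sweep(existing, 2, as.numeric(free[i, ]))
      d[, 1] <- d[, 1] - box[1] * round(d[, 1] / box[1])
      d[, 2] <- d[, 2] - box[2] * round(d[, 2] / box[2])
      expect_gte(sqrt(min(rowSums(d^2))), 2.2)
    }
  }
  # already at target count: no free waters added
  n_tot <- round(997 / 0.018 * N_AVOGADRO * 1e-30 * prod(box))
  many <- matrix(runif(3 * n_tot), ncol = 3) * 20
  expect_identical(nrow(solvate(many, box)), 0L)
})

test_that("AFP lands at the requested height with its IBS facing the seed", {
  afp_path <- synthetic_afp_pdb(tempfile(fileext = ".pdb"))
  box <- c(40, 60, 70)
  placed <- place_afp(afp_path, seed_top = 15, box = box, height = 20)
  expect_equal(placed$com[3] - 15, 20, tolerance = 0.5)
  og1 <- placed$xyz[placed$ibs_idx, ]
  # hydroxyl plane below the body centre, facing the seed
  expect_lt(mean(og1[, 3]), placed$com[3])
  # threonine row aligned with the a-axis (x): x spread dominates
  expect_gt(diff(range(og1[, 1])), 5 * diff(range(og1[, 2])))
  # orientation off leaves coordinates rigidly translated only
  pdb <- bio3d::read.pdb(afp_path)
  p2 <- place_afp(pdb, seed_top = 15, box = box, height = 20,
                  orient_ibs_down = FALSE)
  ref <- as.matrix(pdb$atom[, c("x", "y", "z")])
  shift <- p2$xyz - ref
  expect_lt(max(abs(sweep(shift, 2, colMeans(shift)))), 1e-9)
  expect_error(place_afp(afp_path, seed_top = 15, box = c(10, 10, 30),
                         height = 5), "fit")
})

test_that("missing IBS residues are reported", {
  afp_path <- synthetic_afp_pdb(tempfile(fileext = ".pdb"))
  expect_error(place_afp(afp_path, seed_top = 10, box = c(40, 60, 70),
                         ibs_residues = c(7, 23, 999)), "999")
})

test_that("deleted waters match a brute-force distance scan", {
  set.seed(9)
  box <- c(20, 20, 30)
  waters <- data.frame(x = runif(300) * 20, y = runif(300) * 20,
                       z = runif(300) * 30)
  atoms <- matrix(runif(30) * c(20, 20, 30), ncol = 3, byrow = TRUE)
  kept <- delete_overlapping_waters(waters, atoms, box, cutoff = 2.4)
  # oracle: direct O(N^2) scan with minimum image in x, y
  bad <- rep(FALSE, nrow(waters))
  for (i in seq_len(nrow(waters))) for (k in seq_len(nrow(atoms))) {
    d <- as.numeric(waters[i, ]) - atoms[k, ]
    d[1] <- d[1] - box[1] * round(d[1] / box[1])
    d[2] <- d[2] - box[2] * round(d[2] / box[2])
    if (sqrt(sum(d^2)) < 2.4) bad[i] <- TRUE
  }
  expect_identical(attr(kept, "n_deleted"), sum(bad))
  expect_identical(nrow(kept), sum(!bad))
})
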