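# Gibbs-Thomson critical-radius theory.

test_that("worked critical-radius examples reproduce at 1% tolerance", {
  r_sph <- critical_radius(water_model("real"), 1, "spherical")
  expect_equal(r_sph$R_angstrom, 518, tolerance = 0.01)
  expect_equal(r_sph$volume, 5.82e8, tolerance = 0.01)
  expect_equal(r_sph$n_waters, 1.8e7, tolerance = 0.01)
  r_cyl <- critical_radius(water_model("tip4p"), 5, "cylindrical")
  expect_equal(r_cyl$R_angstrom, 46, tolerance = 0.01)
})

test_that("cylindrical radius is half the spherical radius", {
  for (wm in list(water_model("real"), water_model("tip4p"),
                  water_model("x", M_w = 0.018, sigma = 0.02, L = 5e3,
                              rho_i = 930, T0 = 260))) {
    for (dT in c(0.5, 1, 5, 20)) {
      s <- critical_radius(wm, dT, "spherical")
      c <- critical_radius(wm, dT, "cylindrical")
      expect_equal(c$R_m, s$R_m / 2)
    }
  }
})

test_that("R is an exact hyperbola in supercooling", {
  wm <- water_model("tip4p")
  dTs <- c(0.1, 0.7, 2, 5, 11, 30)
  prods <- vapply(dTs, function(dT)
    critical_radius(wm, dT, "spherical")$R_m * dT, numeric(1))
  expect_true(all(abs(prods - prods[1]) / prods[1] < 1e-12))
  # strictly decreasing in supercooling
  Rs <- vapply(dTs, function(dT)
    critical_radius(wm, dT, "spherical")$R_m, numeric(1))
  expect_true(all(diff(Rs) < 0))
})

test_that("supercooling recomputed from a returned radius round-trips", {
  wm <- water_model("real")
  for (dT in c(0.25, 1, 8)) {
    r <- critical_radius(wm, dT, "cylindrical")
    dT_back <- r$A_g * wm$M_w * wm$sigma * wm$T0 / (wm$L * wm$rho_i * r$R_m)
    expect_equal(dT_back, dT, tolerance = 1e-9)
  }
})

test_that("embryo size matches an independent mass calculation", {
  wm <- water_model("real")
  emb <- embryo_size(518, wm)
  # hand calculation: volume in m^3 times ice density over molar mass
  vol_hand <- 4 / 3 * pi * 518^3
  n_hand <- vol_hand * 1e-30 * 917 / 0.018 * N_AVOGADRO
  expect_equal(emb$volume, vol_hand)
  expect_equal(emb$n_waters / n_hand, 1, tolerance = 1e-3)
  expect_identical(embryo_size(0, wm), list(volume = 0, n_waters = 0))
})

test_that("invalid thermodynamic inputs are rejected", {
  wm <- water_model("real")
  expect_error(critical_radius(wm, 0, "spherical"), "supercooling")
  expect_error(critical_radius(wm, -3, "spherical"), "supercooling")
  expect_error(critical_radius(wm, 280, "spherical"), "T0")
  expect_error(embryo_size(-1, wm), ">= 0")
  expect_error(water_model("nosuch"), "unknown water model")
  expect_error(water_model("p", M_w = 0.018, sigma = 0.02, L = 5e3,
                           rho_i = 930, T0 = 500), "plausible")
  expect_error(water_model("p", M_w = 0.018, sigma = -0.02, L = 5e3,
                           rho_i = 930, T0 = 260), "positive")
})

test_that("custom water models load from a YAML config", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("water_models:",
               "  mymodel:",
               "    M_w: 0.018", "    sigma: 0.025", "    L: 5000",
               "    rho_i: 930", "    T0: 250"), cfg)
  models <- read_water_models(cfg)
  expect_named(models, "mymodel")
  r <- critical_radius(models$mymodel, 2, "spherical")
  expect_equal(r$R_m, 2 * 0.018 * 0.025 * 250 / (5000 * 930 * 2))
})

test_that("gibbs-thomson comparison is dimensionless and propagates fits", {
  wm <- water_model("tip4p")
  cmp <- compare_gibbs_thomson(46, wm, 5)
  expect_equal(cmp$ratio, 46 / critical_radius(wm, 5, "cylindrical")$R_angstrom)
  cmp2 <- compare_gibbs_thomson(2 * cmp$theoretical_radius, wm, 5)
  expect_equal(cmp2$ratio, 2, tolerance = 1e-12)
  # unit invariance: scaling both radii by the same factor leaves the ratio
  wm_nm <- wm
  expect_equal(compare_gibbs_thomson(4.6, wm, 5)$ratio * 10, cmp$ratio,
               tolerance = 1e-12)
})
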