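# Geometric hydrogen-bond detection and ordered bridging waters.

test_that("textbook linear bonds are detected and far pairs are not", {
  # donor at origin with H pointing at the acceptor
  mk <- function(oo_dist) md_frame(
    mol = c(1, 1, 1, 2), elem = c("O", "H", "H", "O"), kind = "water",
    x = c(0, 0.96, -0.3, oo_dist), y = c(0, 0, 0.9, 0), z = 0)
  hb <- detect_hbonds(mk(2.8))
  expect_identical(nrow(hb), 1L)
  expect_equal(hb$donor_mol, 1L)
  expect_equal(hb$acceptor_mol, 2L)
  expect_equal(hb$dist, 2.8)
  expect_equal(hb$angle, 0, tolerance = 1e-9)
  expect_identical(nrow(detect_hbonds(mk(4.0))), 0L)
  # bent beyond 30 degrees: H at 45 degrees off the O-O axis
  bent <- md_frame(mol = c(1, 1, 1, 2), elem = c("O", "H", "H", "O"),
                   kind = "water",
                   x = c(0, 0.68, -0.3, 2.8), y = c(0, 0.68, 0.9, 0), z = 0)
  expect_identical(nrow(detect_hbonds(bent)), 0L)
})

test_that("a frame without hydrogens is rejected", {
  f <- md_frame(mol = 1:2, elem = c("O", "O"), kind = "water",
                x = c(0, 2.8), y = 0, z = 0)
  expect_error(detect_hbonds(f), "no hydrogens")
})

test_that("bond lists agree exactly with the brute-force all-pairs oracle", {
  for (seed in c(3, 17)) {
    f <- random_water_frame(40, box = c(12, 12, 12), seed = seed)
    got <- detect_hbonds(f, box = c(12, 12, 12))
    want <- oracle_hbonds(f, box = c(12, 12, 12))
    key <- function(d) sort(paste(d$donor_mol, d$acceptor_mol))
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_identical(key(got), key(want))
    }
  }
  # and on a compact non-periodic cluster
  f2 <- random_water_frame(25, box = c(8, 8, 8), seed = 5)
  expect_identical(sort(paste(detect_hbonds(f2)$donor_mol,
                              detect_hbonds(f2)$acceptor_mol)),
                   sort(paste(oracle_hbonds(f2)$donor_mol,
                              oracle_hbonds(f2)$acceptor_mol)))
})

test_that("the planted bridging array is recovered exactly and fully coordinated", {
  fx <- generate_ordered_water_fixture(n_bridge = 6, spacing = 4.5)
  ow <- detect_ordered_waters(fx$frame, fx$ice_mols, fx$ibs_mols,
                              lattice_sites = fx$lattice_sites)
  expect_identical(ow$n_members, 6L)
  expect_setequal(ow$members$mol, fx$truth$bridge_mols)
  expect_true(all(ow$members$n_hb_ice == 2))
  expect_true(all(ow$members$n_hb_ibs == 2))
  expect_true(all(ow$members$fully_coordinated))
  expect_equal(ow$mean_spacing, 4.5, tolerance = 0.05)
  # bridging sites are distinct from bulk-ice lattice positions
  expect_true(all(ow$members$dist_to_lattice > 1))
})

test_that("no waters near the IBS yields an empty set; empty IBS errors", {
  fx <- generate_ordered_water_fixture(n_bridge = 0)
  ow <- detect_ordered_waters(fx$frame, fx$ice_mols, fx$ibs_mols)
  expect_identical(ow$n_members, 0L)
  expect_true(is.na(ow$mean_spacing))
  expect_error(detect_ordered_waters(fx$frame, fx$ice_mols, integer(0)),
               "empty ice-binding-surface")
})

test_that("infeasible planted geometry is rejected", {
  expect_error(generate_ordered_water_fixture(spacing = 12), "infeasible")
})
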