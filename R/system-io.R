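## Structure-file output of assembled systems, and a synthetic AFP
## stand-in structure for examples and tests.

# Random-orientation rigid water hydrogens for oxygens without assigned
# protons (barrier and free waters). HOH angle 104.52 deg, O-H 0.9572 A.
.random_water_hydrogens <- function(oxy, r_OH = 0.9572,
                                    angle = 104.52 * pi / 180) {
  n <- nrow(oxy)
  if (!n) return(matrix(numeric(0), 0, 3))
  # random orthonormal pair (e1, e2) per molecule
  u <- matrix(stats::rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u * u))
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v <- v - u * rowSums(u * v)
  v <- v / sqrt(rowSums(v * v))
  h1 <- u
  h2 <- u * cos(angle) + v * sin(angle)
  H <- matrix(NA_real_, 2 * n, 3)
  H[seq(1, 2 * n, 2), ] <- as.matrix(oxy) + r_OH * h1
  H[seq(2, 2 * n, 2), ] <- as.matrix(oxy) + r_OH * h2
  H
}

#' Write an assembled system to PDB with constraint annotations
#'
#' Writes `<prefix>.pdb` (waters and protein; the B-factor column encodes
#' the restraint flag: 1.0 = harmonically constrained seed/barrier water,
#' 0.0 = free, the common MD-engine restraint convention),
#' `<prefix>_constraints.csv` (constrained atom indices and reference
#' positions) and `<prefix>_run.yaml` (box, counts, provenance, and a
#' run-settings stub recording the intended MD ensemble for users handing
#' the system to an engine). Seed waters carry their ice-rule hydrogens;
#' barrier and free waters get random-orientation rigid-water hydrogens.
#'
#' Chain IDs: S = seed, B = barrier, W = free water, A = protein.
#'
#' @param system A `simulation_system` from [build_system()].
#' @param prefix Output path prefix.
#' @param hydrogen_seed RNG seed for the random water orientations.
#' @return Invisibly, the paths written.
#' @export
write_system <- function(system, prefix, hydrogen_seed = 1L) {
  stopifnot(inherits(system, "simulation_system"))
  set.seed(hydrogen_seed)
  seed_o <- system$seed$xyz
  seed_h <- system$seed$protons
  bar_o <- as.matrix(system$barrier)
  free_o <- as.matrix(system$free)
  bar_h <- .random_water_hydrogens(bar_o)
  free_h <- .random_water_hydrogens(free_o)
  water_block <- function(o, h, proton_of = NULL) {
    n <- nrow(o)
    if (!n) return(NULL)
    xyz <- matrix(NA_real_, 3 * n, 3)
    xyz[seq(1, 3 * n, 3), ] <- o
    if (is.null(proton_of)) {
      xyz[seq(2, 3 * n, 3), ] <- h[seq(1, 2 * n, 2), ]
      xyz[seq(3, 3 * n, 3), ] <- h[seq(2, 2 * n, 2), ]
    } else {
      # protons sorted by owning oxygen, two each
      ord <- order(proton_of)
      h <- h[ord, , drop = FALSE]
      xyz[seq(2, 3 * n, 3), ] <- h[seq(1, 2 * n, 2), ]
      xyz[seq(3, 3 * n, 3), ] <- h[seq(2, 2 * n, 2), ]
    }
    list(xyz = xyz, elety = rep(c("O", "H1", "H2"), n),
         resno = rep(seq_len(n), each = 3))
  }
  blocks <- list(
    S = water_block(seed_o, seed_h, system$seed$proton_of),
    B = water_block(bar_o, bar_h),
    W = water_block(free_o, free_h))
  xyz <- do.call(rbind, lapply(blocks, `[[`, "xyz"))
  elety <- unlist(lapply(blocks, `[[`, "elety"))
  resno <- unlist(lapply(blocks, `[[`, "resno"))
  chain <- rep(names(blocks), vapply(blocks, function(b)
    if (is.null(b)) 0L else length(b$elety), integer(1)))
  resid <- rep("HOH", length(elety))
  b <- ifelse(chain %in% c("S", "B"), 1, 0)
  if (!is.null(system$afp)) {
    at <- system$afp$atom
    xyz <- rbind(xyz, system$afp$xyz)
    elety <- c(elety, at$elety)
    resno <- c(resno, at$resno)
    chain <- c(chain, rep("A", nrow(at)))
    resid <- c(resid, at$resid)
    b <- c(b, rep(0, nrow(at)))
  }
  if (any(abs(xyz) >= 10000 - 1) || any(xyz <= -1000))
    stop("coordinates exceed the fixed-column PDB field width")
  pdb_file <- paste0(prefix, ".pdb")
  bio3d::write.pdb(file = pdb_file, xyz = as.vector(t(xyz)),
                   resno = resno %% 10000L, resid = resid, elety = elety,
                   chain = chain, b = b, o = rep(1, length(elety)))
  con_file <- paste0(prefix, "_constraints.csv")
  idx <- which(b > 0.5)
  utils::write.csv(data.frame(atom_index = idx, chain = chain[idx],
                              elety = elety[idx],
                              x = round(xyz[idx, 1], 3),
                              y = round(xyz[idx, 2], 3),
                              z = round(xyz[idx, 3], 3)),
                   con_file, row.names = FALSE)
  meta_file <- paste0(prefix, "_run.yaml")
  n <- water_counts(system)
  yaml::write_yaml(list(
    generator = list(package = "icegrowth",
                     version = as.character(utils::packageVersion("icegrowth")),
                     rng_seed = system$rng_seed),
    box = as.list(stats::setNames(system$box, c("x", "y", "z"))),
    counts = as.list(n),
    seed_tilt = list(angle_deg = system$seed$tilt_angle,
                     layer_offset = system$seed$n_layers),
    run_settings_stub = list(
      ensemble = "NPT", pressure_bar = 1,
      thermostat = "Langevin", barostat = "Nose-Hoover Langevin piston",
      timestep_fs = 2, constraints = "SHAKE (hydrogens)",
      electrostatics = "PME, 1 A grid", cutoff_A = 12,
      water_model = "TIP4P", pbc = "xyz, xy constant",
      frame_interval_ps = 100)), meta_file)
  invisible(c(pdb = pdb_file, constraints = con_file, metadata = meta_file))
}

#' Read a system PDB written by [write_system()]
#'
#' @param pdb_file Path to the PDB file.
#' @return List with `waters` (data.frame `x,y,z,elety,role,constrained`),
#'   `afp` (bio3d atom table subset or NULL) and `n_waters`.
#' @export
read_system <- function(pdb_file) {
  pdb <- bio3d::read.pdb(pdb_file)
  at <- pdb$atom
  w <- at[at$resid == "HOH", ]
  role <- c(S = "seed", B = "barrier", W = "free")[w$chain]
  waters <- data.frame(x = w$x, y = w$y, z = w$z, elety = w$elety,
                       role = unname(role), constrained = w$b > 0.5)
  afp <- at[at$resid != "HOH", ]
  if (!nrow(afp)) afp <- NULL
  list(waters = waters, afp = afp,
       n_waters = sum(waters$elety == "O"))
}

#' Generate a synthetic AFP stand-in structure
#'
#' Writes a small synthetic protein structure whose ice-binding surface
#' mimics the beta-helical AFP arrangement used throughout the package: a
#' row of threonine residues (numbered 7, 23, 39, 54, 69, 84 and 101, the
#' conserved IBS numbering) whose OG1 hydroxyl oxygens lie in a plane,
#' spaced one ice a-axis repeat apart, beneath a compact body of filler
#' residues. This is NOT an experimental structure; it exists so that
#' placement and ordered-water analyses can be exercised without any
#' external structure file. Any user-supplied PDB can be used instead.
#'
#' @param path Output PDB path (default a tempfile).
#' @param spacing IBS hydroxyl spacing along x, angstroms (default 4.5).
#' @param zigzag Alternating lateral offset of the hydroxyl row, angstroms
#'   (default 0.8; keeps the IBS plane well-defined).
#' @return The path written, invisibly; attribute `ibs_residues` lists the
#'   threonine numbering.
#' @export
synthetic_afp_pdb <- function(path = tempfile(fileext = ".pdb"),
                              spacing = 4.5, zigzag = 0.8) {
  resnos <- c(7, 23, 39, 54, 69, 84, 101)
  xyz <- NULL; elety <- character(); resno <- integer(); resid <- character()
  add <- function(e, rn, rid, p) {
    xyz <<- rbind(xyz, p); elety <<- c(elety, e)
    resno <<- c(resno, rn); resid <<- c(resid, rid)
  }
  for (k in seq_along(resnos)) {
    x <- spacing * (k - 1)
    y <- zigzag * (-1)^k
    add("N",   resnos[k], "THR", c(x - 0.7, y + 0.3, 3.8))
    add("CA",  resnos[k], "THR", c(x, y, 3.2))
    add("C",   resnos[k], "THR", c(x + 0.9, y - 0.2, 3.9))
    add("O",   resnos[k], "THR", c(x + 1.0, y - 0.4, 5.1))
    add("CB",  resnos[k], "THR", c(x, y, 1.7))
    add("OG1", resnos[k], "THR", c(x, y, 0))
    add("HG1", resnos[k], "THR", c(x + 0.6, y, -0.6))
  }
  # compact body above the IBS so the centre of mass sits behind it
  set.seed(104729L)
  for (k in 1:24) {
    x <- stats::runif(1, 0, spacing * 6)
    y <- stats::runif(1, -4, 4)
    z <- stats::runif(1, 6, 14)
    add("CA", 200 + k, "GLY", c(x, y, z))
  }
  bio3d::write.pdb(file = path, xyz = as.vector(t(xyz)), resno = resno,
                   resid = resid, elety = elety,
                   chain = rep("A", length(elety)),
                   o = rep(1, length(elety)), b = rep(0, length(elety)))
  attr(path, "ibs_residues") <- resnos
  invisible(path)
}
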