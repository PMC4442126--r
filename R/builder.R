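## Assembly of the tilted-seed ice/water interface system: a proton-
## disordered ice Ih slab whose prism face is inclined to the long (y) box
## axis so that, across the periodic boundary, the face reappears an integer
## number of prism layers higher -- a continual step-growth mechanism -- plus
## a constrained disordered barrier layer below, solvating free water, and
## an optionally placed AFP above the seed.

#' Specification of the tilted seed slab
#'
#' @param tilt_angle Inclination of the prism face to the long box axis,
#'   degrees (default 4.3). `NULL` derives the angle from `step_height`
#'   prism-layer rises across the box length.
#' @param step_height Number of extra prism layers in the growth step
#'   (default 1).
#' @param step_extent Fraction of the box length covered by the step patch
#'   (default 0.5, centred mid-box).
#' @param slab_thickness Seed slab thickness normal to the prism face,
#'   angstroms (default 8.5).
#' @param mode `"snap"` (default): replace the requested angle by the
#'   nearest angle commensurate with the y-periodic boundary (an even
#'   integer number of prism layers across one box length, with a small
#'   strain of the c repeat), so that the wrapped seed superimposes on
#'   itself exactly. `"exact"`: use the angle as given and fail if the
#'   implied layer offset is further than 0.25 layers from an integer.
#' @return Object of class `seed_spec`.
#' @export
seed_spec <- function(tilt_angle = 4.3, step_height = 1L, step_extent = 0.5,
                      slab_thickness = 8.5, mode = c("snap", "exact")) {
  mode <- match.arg(mode)
  if (!is.null(tilt_angle) && (tilt_angle < 0 || tilt_angle >= 90))
    stop("tilt_angle must be in [0, 90) degrees")
  if (step_height < 0) stop("step_height must be >= 0")
  if (step_extent < 0 || step_extent > 1)
    stop("step_extent must be a fraction in [0, 1]")
  structure(list(tilt_angle = tilt_angle, step_height = as.integer(step_height),
                 step_extent = step_extent, slab_thickness = slab_thickness,
                 mode = mode), class = "seed_spec")
}

#' Tilt angle implied by an integer prism-layer rise across the box
#'
#' @param n_layers Number of prism interlayer spacings gained across the box
#'   length.
#' @param d_layer Prism interlayer spacing, angstroms (`sqrt(3)/2 * a`).
#' @param L_y Box length along the long axis, angstroms.
#' @return Angle in degrees, `atan(n_layers * d_layer / L_y)`.
#' @export
computed_tilt_angle <- function(n_layers, d_layer, L_y) {
  atan(n_layers * d_layer / L_y) * 180 / pi
}

# Commensuration of the tilt with the y-periodic boundary. In ice Ih
# successive prism layers are offset by half a cell along the a-axis, so
# site-level periodic registry requires an even layer offset n; the box
# translation (0, L_y, 0) then equals the lattice vector
# (0, j*c_eff, -n*d_layer) when j*c_eff = sqrt(L_y^2 - (n*d_layer)^2),
# absorbing a <1% strain of the c repeat into c_eff.
.commensurate_tilt <- function(tilt_deg, step_height, d_layer, c0, L_y,
                               mode) {
  if (is.null(tilt_deg))
    tilt_deg <- computed_tilt_angle(max(1L, step_height), d_layer, L_y)
  theta <- tilt_deg * pi / 180
  if (mode == "exact") {
    n_raw <- L_y * sin(theta) / d_layer
    if (abs(n_raw - round(n_raw)) > 0.25)
      stop("tilt angle ", tilt_deg, " deg implies a rise of ",
           signif(n_raw, 3), " prism layers across L_y = ", L_y,
           " A; further than 0.25 layers from an integer, so the seed is ",
           "not consistent with the y-periodic boundary")
    return(list(theta = theta, n = as.integer(round(n_raw)),
                j = NA_integer_, c_eff = c0, snapped = FALSE))
  }
  n_raw <- L_y * sin(theta) / d_layer
  n <- 2L * max(1L, as.integer(round(n_raw / 2)))
  while (n * d_layer >= L_y) n <- n - 2L
  jc <- sqrt(L_y^2 - (n * d_layer)^2)
  j <- max(1L, as.integer(round(jc / c0)))
  c_eff <- jc / j
  list(theta = atan2(n * d_layer, jc), n = n, j = j, c_eff = c_eff,
       snapped = TRUE)
}

#' Tilt and trim an ice lattice into the seed slab of the interface model
#'
#' Rotates the lattice about the x-axis so the prism face makes the
#' specified angle with the long (y) axis, trims it to a slab of the given
#' thickness (measured normal to the prism face), adds the growth-step
#' patch, and cuts the result to the box. In the default `"snap"` mode the
#' angle is adjusted to the nearest commensurate value so that the seed,
#' continued across the y-periodic boundary, lands exactly an (even)
#' integer number of prism layers higher -- the continual step-growth
#' arrangement.
#'
#' @param lattice A proton-assigned `ice_lattice` covering at least the box
#'   footprint (see [build_ice_lattice()], [assign_protons()]).
#' @param spec A [seed_spec()].
#' @param box Box dimensions `c(L_x, L_y, L_z)`, angstroms.
#' @param z_base Height of the lowest seed atom after placement, angstroms.
#' @param x_margin Gap left before the (incommensurate) x boundary to keep
#'   the 2.2 A clash invariant across the x wrap, angstroms.
#' @return Object of class `ice_seed`: oxygen coordinates `xyz`, hydrogen
#'   coordinates `protons` and `proton_of`, lattice-frame coordinates
#'   `xyz_lat`, tilt metadata (`tilt_angle` deg, `n_layers`, `j`, `c_eff`,
#'   `d_layer`), `box`, and `seed_top` (highest oxygen z).
#' @export
tilt_seed <- function(lattice, spec = seed_spec(), box, z_base = 7.2,
                      x_margin = 2.3) {
  stopifnot(inherits(lattice, "ice_lattice"), inherits(spec, "seed_spec"))
  a <- lattice$spec$a; c0 <- lattice$spec$c
  d_layer <- lattice$d_layer
  cm <- .commensurate_tilt(spec$tilt_angle, spec$step_height, d_layer, c0,
                           box[2], spec$mode)
  theta <- cm$theta
  xyz <- lattice$xyz
  # strain c to the commensurate repeat
  yscale <- cm$c_eff / c0
  xyz[, 2] <- xyz[, 2] * yscale
  H <- lattice$protons
  if (is.null(H)) stop("assign protons before tilting the seed")
  H[, 2] <- H[, 2] * yscale
  t_slab <- spec$slab_thickness
  z_step <- t_slab + spec$step_height * d_layer
  need_y <- box[2] / cos(theta) + z_step * tan(theta) + 2
  if (max(xyz[, 1]) - min(xyz[, 1]) + a / 2 < box[1] - x_margin ||
      max(xyz[, 2]) - min(xyz[, 2]) + c0 / 2 < need_y)
    stop("lattice block smaller than the box footprint: need >= ",
         round(box[1]), " A along x and >= ", round(need_y), " A along y")
  if (max(xyz[, 3]) - min(xyz[, 3]) + d_layer < z_step)
    stop("lattice block thinner than slab + step")
  zr <- xyz[, 3] - min(xyz[, 3])
  in_slab <- zr < t_slab - 1e-9
  in_step <- zr >= t_slab - 1e-9 & zr < z_step - 1e-9
  # rotate about x so the prism face rises with +y
  rot <- function(m) {
    cbind(m[, 1],
          m[, 2] * cos(theta) - m[, 3] * sin(theta),
          m[, 2] * sin(theta) + m[, 3] * cos(theta))
  }
  xyz_lat <- cbind(xyz[, 1], xyz[, 2], zr)
  r <- rot(cbind(xyz[, 1], xyz[, 2], zr))
  rH <- rot(cbind(H[, 1], H[, 2], H[, 3] - min(xyz[, 3])))
  # shift into the box: x from 0, y from 0, z so the slab bottom sits at z_base
  x0 <- min(r[, 1]); y0 <- min(r[, 2])
  r[, 1] <- r[, 1] - x0; rH[, 1] <- rH[, 1] - x0
  r[, 2] <- r[, 2] - y0; rH[, 2] <- rH[, 2] - y0
  keep_xy <- r[, 1] >= 0 & r[, 1] <= box[1] - x_margin &
    r[, 2] >= 0 & r[, 2] < box[2] - 1e-9
  y_mid <- box[2] / 2
  half <- spec$step_extent * box[2] / 2
  in_patch <- abs(r[, 2] - y_mid) <= half
  keep <- keep_xy & (in_slab | (in_step & in_patch))
  if (!any(keep)) stop("no seed atoms survive trimming; check box and spec")
  zmin <- min(r[keep, 3])
  r[, 3] <- r[, 3] - zmin + z_base
  rH[, 3] <- rH[, 3] - zmin + z_base
  keepH <- keep[lattice$proton_of]
  old2new <- cumsum(keep)
  seed <- structure(list(
    xyz = r[keep, , drop = FALSE],
    xyz_lat = xyz_lat[keep, , drop = FALSE],
    protons = rH[keepH, , drop = FALSE],
    proton_of = old2new[lattice$proton_of[keepH]],
    box = box,
    tilt_angle = theta * 180 / pi,
    n_layers = cm$n, j = cm$j, c_eff = cm$c_eff, d_layer = d_layer,
    a = a, snapped = cm$snapped,
    spec = spec,
    seed_top = max(r[keep, 3])), class = "ice_seed")
  seed
}

#' Check y-periodic consistency of a tilted seed
#'
#' The seed is consistent with the y-periodic boundary when translating it
#' by one box length along y maps every oxygen onto an exact site of the
#' same (infinite) ice lattice, shifted down by an integer number of prism
#' layers -- the continual step-growth arrangement. This verifies, on the
#' generated coordinates, that the box translation expressed in the lattice
#' frame lands on lattice sites.
#'
#' @param seed An `ice_seed` from [tilt_seed()].
#' @param n_sample Number of seed oxygens checked (all if fewer).
#' @param tol RMSD threshold for the `ok` verdict, angstroms.
#' @return List with `n_checked`, `rmsd` (distance of wrapped atoms from
#'   the nearest lattice site), `layer_offset` (implied prism-layer rise
#'   across the boundary) and `ok` (RMSD below `tol` and integer offset).
#' @export
periodic_consistency <- function(seed, n_sample = 200L, tol = 0.1) {
  stopifnot(inherits(seed, "ice_seed"))
  box <- seed$box
  theta <- seed$tilt_angle * pi / 180
  a <- seed$a
  c_eff <- seed$c_eff
  cell1 <- c(a, c_eff, sqrt(3) * a)
  basis <- sweep(.ice_basis, 2, c(1, 1, 1), `*`)
  basis_cart <- sweep(basis, 2, cell1, `*`)
  basis_cart[, 3] <- basis_cart[, 3] - min(basis_cart[, 3])
  # box-length y translation expressed in the (unrotated) lattice frame
  T_lat <- c(0, box[2] * cos(theta), -box[2] * sin(theta))
  n <- nrow(seed$xyz_lat)
  idx <- if (n > n_sample) sort(sample.int(n, n_sample)) else seq_len(n)
  pts <- seed$xyz_lat[idx, , drop = FALSE] +
    matrix(T_lat, length(idx), 3, byrow = TRUE)
  dmin <- vapply(seq_len(nrow(pts)), function(k) {
    g <- sweep(-basis_cart, 2, pts[k, ], `+`)   # pts - basis
    r <- sweep(g, 2, cell1, `/`)
    res <- sweep(r - round(r), 2, cell1, `*`)
    sqrt(min(rowSums(res * res)))
  }, numeric(1))
  layer_offset <- box[2] * sin(theta) / seed$d_layer
  rmsd <- sqrt(mean(dmin^2))
  list(n_checked = length(idx), rmsd = rmsd, layer_offset = layer_offset,
       ok = rmsd < tol && abs(layer_offset - round(layer_offset)) < 0.05)
}

#' Build the constrained disordered barrier layer
#'
#' Randomly places clash-free waters (oxygen positions) in a thin layer at
#' the bottom of the box; in the assembled system these are harmonically
#' constrained and act as an ice barrier preventing downward growth.
#'
#' @param box Box dimensions, angstroms.
#' @param thickness Layer thickness, angstroms (default 5).
#' @param target_density Mass density, kg/m^3 (default 997).
#' @param seed RNG seed.
#' @param cutoff Minimum O-O separation, angstroms (default 2.2).
#' @return data.frame `x`, `y`, `z` of oxygen positions.
#' @export
build_barrier <- function(box, thickness = 5, target_density = 997,
                          seed = 1L, cutoff = 2.2) {
  if (thickness < 0) stop("thickness must be >= 0")
  if (thickness >= box[3] / 4)
    stop("barrier thickness must be < L_z / 4")
  n <- round(.number_density(target_density) * box[1] * box[2] * thickness)
  if (n == 0) return(data.frame(x = numeric(), y = numeric(), z = numeric()))
  set.seed(seed)
  pts <- .rsa_fill(n, box, 0, thickness, cutoff = cutoff)
  data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3])
}

#' Solvate the assembled interface with free water
#'
#' Fills the remaining box volume with clash-free waters at the target
#' density, excluding positions within the cutoff of any existing oxygen or
#' protein atom.
#'
#' @param existing Matrix or data.frame of existing heavy-atom positions
#'   (seed and barrier oxygens, AFP atoms).
#' @param box Box dimensions, angstroms.
#' @param target_density Mass density, kg/m^3.
#' @param seed RNG seed.
#' @param cutoff Minimum separation, angstroms.
#' @return data.frame `x`, `y`, `z` of free-water oxygen positions.
#' @export
solvate <- function(existing, box, target_density = 997, seed = 1L,
                    cutoff = 2.2) {
  existing <- as.matrix(existing)
  n_total <- round(.number_density(target_density) * prod(box))
  n_free <- n_total - nrow(existing)
  if (n_free <= 0)
    return(data.frame(x = numeric(), y = numeric(), z = numeric()))
  set.seed(seed)
  pts <- .rsa_fill(n_free, box, 0, box[3], existing = existing,
                   cutoff = cutoff)
  data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3])
}

#' Place an AFP above the seed with its ice-binding surface facing down
#'
#' Positions the protein centre of mass at the requested height above the
#' topmost seed oxygen and (optionally) orients it so that the plane of the
#' ice-binding-surface (IBS) threonine hydroxyl oxygens faces the seed with
#' the threonine rows aligned to the crystallographic a-axis (x).
#'
#' @param pdb A `bio3d` pdb object or path to a PDB file.
#' @param seed_top Height of the topmost seed oxygen, angstroms.
#' @param box Box dimensions, angstroms.
#' @param height Centre-of-mass height above the seed top, A (default 20).
#' @param orient_ibs_down Rotate the IBS to face the seed (default TRUE).
#' @param ibs_residues Residue numbers of the conserved IBS threonines
#'   (default 7, 23, 39, 54, 69, 84, 101).
#' @return List with `xyz` (atom coordinates), `atom` (bio3d atom table),
#'   `ibs_idx` (row indices of the IBS hydroxyl oxygens, atom name OG1) and
#'   `com`.
#' @export
place_afp <- function(pdb, seed_top, box, height = 20,
                      orient_ibs_down = TRUE,
                      ibs_residues = c(7, 23, 39, 54, 69, 84, 101)) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  at <- pdb$atom
  xyz <- as.matrix(at[, c("x", "y", "z")])
  og1 <- which(at$elety == "OG1" & at$resno %in% ibs_residues)
  found <- unique(at$resno[og1])
  if (length(setdiff(ibs_residues, found)))
    stop("IBS threonine hydroxyls missing for residues: ",
         paste(setdiff(ibs_residues, found), collapse = ", "))
  com <- colMeans(xyz)
  if (orient_ibs_down) {
    P <- xyz[og1, , drop = FALSE]
    ctr <- colMeans(P)
    sv <- svd(sweep(P, 2, ctr))
    normal <- sv$v[, 3]
    if (sum(normal * (ctr - com)) < 0) normal <- -normal  # outward through IBS
    row_dir <- sv$v[, 1]
    # rotation sending `normal` to -z and `row_dir` into the x axis
    zt <- -normal
    xt <- row_dir - sum(row_dir * zt) * zt
    xt <- xt / sqrt(sum(xt^2))
    yt <- c(zt[2] * xt[3] - zt[3] * xt[2],
            zt[3] * xt[1] - zt[1] * xt[3],
            zt[1] * xt[2] - zt[2] * xt[1])
    # rows of the target frame expressed in old coordinates: R maps xt->x
    R <- rbind(xt, yt, zt)
    xyz <- sweep(xyz, 2, com)
    xyz <- xyz %*% t(R)
    xyz <- sweep(xyz, 2, com, `+`)
  }
  dimnames(xyz) <- NULL
  com <- colMeans(xyz)
  target <- c(box[1] / 2, box[2] / 2, seed_top + height)
  xyz <- sweep(xyz, 2, target - com, `+`)
  if (any(xyz[, 1] < 0 | xyz[, 1] > box[1] |
          xyz[, 2] < 0 | xyz[, 2] > box[2] |
          xyz[, 3] < 0 | xyz[, 3] > box[3]))
    stop("AFP does not fit in the box at the requested height")
  list(xyz = xyz, atom = at, ibs_idx = og1, com = colMeans(xyz))
}

#' Remove waters overlapping a set of atoms
#'
#' @param waters data.frame with `x`, `y`, `z` oxygen positions.
#' @param atoms Matrix of atom positions.
#' @param box Box dimensions (periodic x, y).
#' @param cutoff Deletion distance, angstroms.
#' @return The waters data.frame with overlapping rows removed; the number
#'   removed is in attribute `n_deleted`.
#' @export
delete_overlapping_waters <- function(waters, atoms, box, cutoff = 2.2) {
  if (!nrow(waters) || !NROW(atoms)) {
    attr(waters, "n_deleted") <- 0L
    return(waters)
  }
  atoms <- as.matrix(atoms)
  w <- as.matrix(waters[, c("x", "y", "z")])
  bad <- logical(nrow(w))
  for (k in seq_len(nrow(atoms))) {
    d <- sweep(w, 2, atoms[k, ])
    d <- .min_image(d, box, c(TRUE, TRUE, FALSE))
    bad <- bad | rowSums(d * d) < cutoff^2
  }
  out <- waters[!bad, , drop = FALSE]
  attr(out, "n_deleted") <- sum(bad)
  out
}

#' Assemble the full ice/water interface simulation system
#'
#' Convenience orchestrator: builds a lattice sized to the box, assigns
#' protons, tilts and trims the seed, fills the barrier layer, solvates,
#' and optionally places an AFP (deleting overlapping waters).
#'
#' @param box Box dimensions, angstroms (default the 51.5 x 126.6 x 83.9
#'   interface box).
#' @param lat_spec A [lattice_spec()]; repeat counts are overridden to cover
#'   the box.
#' @param sd_spec A [seed_spec()].
#' @param barrier_thickness Barrier layer thickness, angstroms (default 5).
#' @param target_density Liquid density for barrier and solvation, kg/m^3.
#' @param afp Optional PDB path or bio3d object.
#' @param afp_height AFP centre-of-mass height above the seed, A.
#' @param seed RNG seed controlling proton disorder and water placement.
#' @return Object of class `simulation_system`.
#' @export
build_system <- function(box = c(51.5, 126.6, 83.9),
                         lat_spec = lattice_spec(),
                         sd_spec = seed_spec(),
                         barrier_thickness = 5,
                         target_density = 997,
                         afp = NULL, afp_height = 20, seed = 1L) {
  a <- lat_spec$a; c0 <- lat_spec$c
  d_layer <- sqrt(3) / 2 * a
  z_need <- sd_spec$slab_thickness + sd_spec$step_height * d_layer + 1
  spec <- lattice_spec(a = a, c = c0,
                       n_a = ceiling(box[1] / a) + 1L,
                       n_b = ceiling((box[2] + 20) / c0) + 1L,
                       n_c = max(1L, ceiling(z_need / (sqrt(3) * a))),
                       proton_seed = seed)
  lat <- build_ice_lattice(spec)
  lat <- assign_protons(lat, seed = seed)
  ice <- tilt_seed(lat, sd_spec, box, z_base = barrier_thickness + 2.2)
  barrier <- build_barrier(box, barrier_thickness, target_density,
                           seed = seed + 1L)
  afp_placed <- NULL
  existing <- rbind(as.matrix(barrier), ice$xyz)
  if (!is.null(afp)) {
    afp_placed <- place_afp(afp, ice$seed_top, box, height = afp_height)
    existing <- rbind(existing, afp_placed$xyz)
  }
  free <- solvate(existing, box, target_density, seed = seed + 2L)
  structure(list(box = box, seed = ice, barrier = barrier, free = free,
                 afp = afp_placed,
                 target_density = target_density,
                 rng_seed = seed), class = "simulation_system")
}

#' Total water count of an assembled system
#' @param system A `simulation_system`.
#' @return Named integer vector with seed, barrier, free and total counts.
#' @export
water_counts <- function(system) {
  stopifnot(inherits(system, "simulation_system"))
  n_seed <- nrow(system$seed$xyz)
  n_bar <- nrow(system$barrier)
  n_free <- nrow(system$free)
  c(seed = n_seed, barrier = n_bar, free = n_free,
    total = n_seed + n_bar + n_free)
}

#' @export
print.simulation_system <- function(x, ...) {
  n <- water_counts(x)
  cat(sprintf("ice/water interface system, box %.1f x %.1f x %.1f A\n",
              x$box[1], x$box[2], x$box[3]))
  cat(sprintf("  seed waters    %5d (constrained, tilt %.2f deg, %d-layer wrap)\n",
              n["seed"], x$seed$tilt_angle, x$seed$n_layers))
  cat(sprintf("  barrier waters %5d (constrained, disordered)\n", n["barrier"]))
  cat(sprintf("  free waters    %5d\n", n["free"]))
  cat(sprintf("  total          %5d\n", n["total"]))
  if (!is.null(x$afp))
    cat(sprintf("  AFP: %d atoms, COM z = %.1f A (seed top %.1f A)\n",
                nrow(x$afp$xyz), x$afp$com[3], x$seed$seed_top))
  invisible(x)
}
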