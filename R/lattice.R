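## Hexagonal ice (Ih) lattice generation with Bernal-Fowler proton disorder.
##
## Axis convention throughout the package: x is the crystallographic a-axis,
## y the c-axis, z the prism-layer stacking direction (normal to the primary
## prism face). The orthorhombic generating cell is a x c x sqrt(3)*a and
## holds 8 oxygens (two 4-molecule hexagonal cells).

# Oxygen basis, fractional coordinates of the (a, c, sqrt(3) a) cell.
.ice_basis <- cbind(
  x = c(0, 0, 0.5, 0.5, 0.5, 0.5, 0, 0),
  y = c(1, 7, 9, 15, 1, 7, 9, 15) / 16,
  z = c(1, 1, 0.5, 0.5, 2.5, 2.5, 2, 2) / 3
)

#' Specification of an ice-Ih lattice block
#'
#' @param a a-axis repeat in angstroms (default 4.5, the rounded prism-face
#'   repeat; the crystallographic value 4.497 is also physical).
#' @param c c-axis repeat in angstroms (default 7.4).
#' @param n_a,n_b,n_c Repeat counts of the orthorhombic generating cell
#'   along the a-axis (x), c-axis (y) and stacking (z) directions.
#' @param proton_seed RNG seed used by [assign_protons()].
#' @return Object of class `lattice_spec`.
#' @export
lattice_spec <- function(a = 4.5, c = 7.4, n_a = 3L, n_b = 3L, n_c = 2L,
                         proton_seed = 1L) {
  if (a <= 0 || c <= 0) stop("lattice constants must be positive")
  if (any(c(n_a, n_b, n_c) < 1)) stop("repeat counts must be >= 1")
  structure(list(a = a, c = c, n_a = as.integer(n_a), n_b = as.integer(n_b),
                 n_c = as.integer(n_c), proton_seed = as.integer(proton_seed)),
            class = "lattice_spec")
}

#' Build the oxygen sublattice of hexagonal ice Ih
#'
#' Generates a periodic block of the wurtzite-like oxygen sublattice of
#' ordinary hexagonal ice. Each interior oxygen has four hydrogen-bonded
#' neighbours in a tetrahedral arrangement that appears hexagonal when
#' viewed down the c-axis. Protons are left unassigned (see
#' [assign_protons()]).
#'
#' @param spec A [lattice_spec()].
#' @return Object of class `ice_lattice`: `xyz` (oxygen coordinates, N x 3,
#'   angstroms), `cell` (block dimensions), `spec`, `axes` (unit vectors of
#'   the a- and c-axes and the stacking direction), `bonds` (O-O adjacency,
#'   see [ice_bonds()]), `protons` (`NULL` until assigned).
#' @examples
#' lat <- build_ice_lattice(lattice_spec(n_a = 2, n_b = 2, n_c = 1))
#' nrow(lat$xyz)  # 8 oxygens per cell
#' @export
build_ice_lattice <- function(spec = lattice_spec()) {
  stopifnot(inherits(spec, "lattice_spec"))
  ca <- spec$c / spec$a
  if (ca < 1.4 || ca > 1.9)
    warning("c/a ratio ", signif(ca, 4), " outside [1.4, 1.9]; ideal ice has ",
            "c/a ~ 1.63")
  cell1 <- c(spec$a, spec$c, sqrt(3) * spec$a)
  reps <- expand.grid(ix = seq_len(spec$n_a) - 1L,
                      iy = seq_len(spec$n_b) - 1L,
                      iz = seq_len(spec$n_c) - 1L)
  n_cells <- nrow(reps)
  frac <- .ice_basis[rep(seq_len(8L), times = n_cells), , drop = FALSE]
  shift <- as.matrix(reps)[rep(seq_len(n_cells), each = 8L), , drop = FALSE]
  xyz <- sweep(frac + shift, 2, cell1, `*`)
  dimnames(xyz) <- NULL
  lat <- structure(list(
    xyz = xyz,
    cell = cell1 * c(spec$n_a, spec$n_b, spec$n_c),
    cell1 = cell1,
    spec = spec,
    axes = list(a = c(1, 0, 0), c = c(0, 1, 0), stacking = c(0, 0, 1)),
    d_layer = sqrt(3) / 2 * spec$a,
    bonds = NULL, protons = NULL), class = "ice_lattice")
  lat$bonds <- ice_bonds(lat)
  lat
}

#' Hydrogen-bond adjacency of an ice lattice
#'
#' Finds all nearest-neighbour O-O pairs under full periodic boundary
#' conditions of the block. When any box dimension is shorter than twice the
#' bond cutoff (e.g. a single unit cell) the search is image-resolved, so a
#' pair of oxygens may carry several distinct bonds through different
#' periodic images; ice rules are then enforced per bond instance.
#'
#' @param lattice An `ice_lattice`.
#' @return data.frame with columns `i`, `j` (oxygen indices), `sx,sy,sz`
#'   (periodic image shift of `j`), `dx,dy,dz` (bond vector i -> j, A) and
#'   `d` (bond length, A).
#' @export
ice_bonds <- function(lattice) {
  stopifnot(inherits(lattice, "ice_lattice"))
  xyz <- lattice$xyz
  box <- lattice$cell
  # nearest-neighbour distance from the two crystallographically distinct
  # bonds; cutoff safely below the next-nearest distance (~a)
  d_c <- 3 / 8 * lattice$spec$c
  d_lat <- sqrt((lattice$spec$a / 2)^2 + (lattice$spec$c / 8)^2 +
                  (sqrt(3) * lattice$spec$a / 6)^2)
  cutoff <- 1.15 * max(d_c, d_lat)
  if (all(box > 2 * cutoff)) {
    p <- .pairs_within(xyz, cutoff, box = box)
    # recover image shifts from raw vs minimum-image displacement
    raw <- xyz[p$j, , drop = FALSE] - xyz[p$i, , drop = FALSE]
    p$sx <- round((p$dx - raw[, 1]) / box[1])
    p$sy <- round((p$dy - raw[, 2]) / box[2])
    p$sz <- round((p$dz - raw[, 3]) / box[3])
    p <- p[, c("i", "j", "sx", "sy", "sz", "dx", "dy", "dz", "d")]
  } else {
    p <- .pairs_within_images(xyz, cutoff, box)
  }
  rownames(p) <- NULL
  p
}

#' Assign protons to an ice lattice under the Bernal-Fowler rules
#'
#' Produces a proton-disordered configuration obeying both ice rules: every
#' oxygen bears exactly two covalent hydrogens, and every hydrogen-bonded
#' O-O pair carries exactly one proton. A random assignment of bond
#' directions is repaired by defect-migration Monte Carlo (randomly flipping
#' bonds at over-/under-coordinated oxygens until no defects remain), after
#' which directed-loop reversals -- which preserve the ice rules exactly --
#' are applied until the net dipole per molecule falls below
#' `dipole_threshold` (in units of a single molecular dipole).
#'
#' @param lattice An `ice_lattice` with bonds computed.
#' @param seed RNG seed (default from the lattice spec); fixed seed gives a
#'   reproducible configuration.
#' @param dipole_threshold Maximum residual net dipole per molecule,
#'   fraction of one molecular dipole (default 0.1).
#' @param max_iter Defect-walk step budget (default `2000 * n_oxygens`).
#' @param r_OH Covalent O-H distance along the bond, angstroms.
#' @return The lattice with `protons` (2N x 3 H coordinates), `proton_of`
#'   (oxygen index of each H), `bond_dir` (+1 if `i` donates to `j`) and
#'   `dipole_per_molecule` filled in.
#' @export
assign_protons <- function(lattice, seed = lattice$spec$proton_seed,
                           dipole_threshold = 0.1, max_iter = NULL,
                           r_OH = 0.9572) {
  stopifnot(inherits(lattice, "ice_lattice"))
  bonds <- lattice$bonds
  if (is.null(bonds) || !nrow(bonds)) stop("lattice has no bonds")
  n <- nrow(lattice$xyz)
  nb <- nrow(bonds)
  if (is.null(max_iter)) max_iter <- 2000L * n
  set.seed(seed)
  u <- as.matrix(bonds[, c("dx", "dy", "dz")]) / bonds$d
  # incidence: per oxygen, indices of bonds and their orientation sign
  fac <- factor(c(bonds$i, bonds$j), levels = seq_len(n))
  inc_b <- split(c(seq_len(nb), seq_len(nb)), fac)
  inc_s <- split(c(rep(1L, nb), rep(-1L, nb)), fac)
  deg <- vapply(inc_b, length, integer(1))
  if (!all(deg == 4L))
    stop("oxygen coordination is not uniformly 4 (range ",
         paste(range(deg), collapse = "-"), "); protons can only be ",
         "assigned on a fully periodic block")
  dir <- sample(c(-1L, 1L), nb, replace = TRUE)   # +1: i donates to j
  outdeg <- function() {
    o <- integer(n)
    tab_i <- tapply(dir == 1L, bonds$i, sum)
    tab_j <- tapply(dir == -1L, bonds$j, sum)
    o[as.integer(names(tab_i))] <- o[as.integer(names(tab_i))] + tab_i
    o[as.integer(names(tab_j))] <- o[as.integer(names(tab_j))] + tab_j
    o
  }
  out <- outdeg()
  iter <- 0L
  while (any(out != 2L)) {
    if (iter >= max_iter)
      stop("proton assignment failed to converge within ", max_iter,
           " steps; ", sum(abs(out - 2L)), " coordination defects remain")
    defects <- which(out != 2L)
    v <- defects[sample.int(length(defects), 1L)]
    bs <- inc_b[[v]]; ss <- inc_s[[v]]
    donated <- (dir[bs] * ss) == 1L
    if (out[v] > 2L) pick <- which(donated) else pick <- which(!donated)
    k <- pick[sample.int(length(pick), 1L)]
    b <- bs[k]
    other <- if (ss[k] == 1L) bonds$j[b] else bonds$i[b]
    dir[b] <- -dir[b]
    if (out[v] > 2L) { out[v] <- out[v] - 1L; out[other] <- out[other] + 1L }
    else             { out[v] <- out[v] + 1L; out[other] <- out[other] - 1L }
    iter <- iter + 1L
  }
  # dipole minimisation by directed-loop reversal
  mol_dip <- 2 * cos(acos(-1 / 3) / 2)   # |sum of two OH unit vectors|
  M <- colSums(u * dir)
  # per-oxygen outgoing bonds for walk
  walk_next <- function(v) {
    bs <- inc_b[[v]]; ss <- inc_s[[v]]
    outs <- bs[(dir[bs] * ss) == 1L]
    outs[sample.int(length(outs), 1L)]
  }
  max_loops <- 200L * n
  loops <- 0L
  while (sqrt(sum(M^2)) / (mol_dip * n) > dipole_threshold &&
         loops < max_loops) {
    v0 <- sample.int(n, 1L)
    path_v <- integer(0); path_b <- integer(0)
    pos <- integer(n)   # 0 = unvisited, else index in path
    v <- v0
    repeat {
      if (pos[v] > 0L) break
      pos[v] <- length(path_v) + 1L
      path_v <- c(path_v, v)
      b <- walk_next(v)
      path_b <- c(path_b, b)
      v <- if (bonds$i[b] == v) bonds$j[b] else bonds$i[b]
    }
    cyc <- path_b[pos[v]:length(path_b)]
    dM <- -2 * colSums(u[cyc, , drop = FALSE] * dir[cyc])
    if (sum((M + dM)^2) < sum(M^2)) {
      dir[cyc] <- -dir[cyc]
      M <- M + dM
    }
    loops <- loops + 1L
  }
  if (sqrt(sum(M^2)) / (mol_dip * n) > dipole_threshold)
    warning("net dipole per molecule ",
            signif(sqrt(sum(M^2)) / (mol_dip * n), 3),
            " above threshold after loop-move budget")
  # place hydrogens along donated bond directions
  don_o <- c(bonds$i[dir == 1L], bonds$j[dir == -1L])
  don_u <- rbind(u[dir == 1L, , drop = FALSE], -u[dir == -1L, , drop = FALSE])
  ord <- order(don_o)
  don_o <- don_o[ord]; don_u <- don_u[ord, , drop = FALSE]
  protons <- lattice$xyz[don_o, , drop = FALSE] + r_OH * don_u
  lattice$protons <- protons
  lattice$proton_of <- don_o
  lattice$bond_dir <- dir
  lattice$dipole_per_molecule <- sqrt(sum(M^2)) / (mol_dip * n)
  lattice
}

#' Measure the translation period of a lattice along an axis
#'
#' Finds the smallest translation along a crystal axis that maps the
#' generated oxygen coordinates onto themselves (points translated past the
#' block edge are ignored). This measures the repeat distance from the
#' output coordinates rather than reporting the specification value.
#'
#' @param lattice An `ice_lattice`.
#' @param axis `"a"`, `"c"` or `"stacking"`, or a length-3 unit vector.
#' @param tol Matching tolerance in angstroms.
#' @return The measured repeat distance in angstroms.
#' @export
measure_lattice_repeat <- function(lattice, axis = "a", tol = 1e-4) {
  stopifnot(inherits(lattice, "ice_lattice"))
  u <- if (is.character(axis)) lattice$axes[[match.arg(axis,
    c("a", "c", "stacking"))]] else axis / sqrt(sum(axis^2))
  xyz <- lattice$xyz
  proj <- drop(xyz %*% u)
  span <- max(proj) - min(proj)
  cands <- sort(unique(round(proj - min(proj), 6)))
  cands <- cands[cands > tol & cands <= 0.75 * span + tol]
  for (t in cands) {
    shifted <- xyz + matrix(u * t, nrow(xyz), 3, byrow = TRUE)
    inside <- proj + t <= max(proj) + tol
    if (sum(inside) < 4L) next
    ok <- TRUE
    for (r in which(inside)) {
      d2 <- rowSums((xyz - matrix(shifted[r, ], nrow(xyz), 3,
                                  byrow = TRUE))^2)
      if (min(d2) > tol^2) { ok <- FALSE; break }
    }
    if (ok) return(t)
  }
  stop("no translation period found along the given axis")
}

#' Mass density of an ice lattice block
#'
#' @param lattice An `ice_lattice`.
#' @param M_w Molecular weight, kg/mol.
#' @return Density in g/cm^3 computed from the molecule count and the
#'   periodic block volume.
#' @export
lattice_density <- function(lattice, M_w = 0.018) {
  stopifnot(inherits(lattice, "ice_lattice"))
  n <- nrow(lattice$xyz)
  vol_cm3 <- prod(lattice$cell) * 1e-24
  n * (M_w * 1000 / .N_A) / vol_cm3
}

#' Check the Bernal-Fowler ice rules on an assigned lattice
#'
#' @param lattice An `ice_lattice` after [assign_protons()].
#' @return List with `protons_per_oxygen` (table), `protons_per_bond`
#'   (table) and `valid` (TRUE iff exactly 2 per oxygen and 1 per bond).
#' @export
check_ice_rules <- function(lattice) {
  stopifnot(inherits(lattice, "ice_lattice"))
  if (is.null(lattice$protons)) stop("protons not assigned")
  per_o <- tabulate(lattice$proton_of, nbins = nrow(lattice$xyz))
  # geometric count: match each H direction against the bonds of its oxygen
  bonds <- lattice$bonds
  u <- as.matrix(bonds[, c("dx", "dy", "dz")]) / bonds$d
  per_b <- integer(nrow(bonds))
  fac <- factor(c(bonds$i, bonds$j), levels = seq_len(nrow(lattice$xyz)))
  inc_b <- split(c(seq_len(nrow(bonds)), seq_len(nrow(bonds))), fac)
  inc_s <- split(c(rep(1, nrow(bonds)), rep(-1, nrow(bonds))), fac)
  for (h in seq_len(nrow(lattice$protons))) {
    o <- lattice$proton_of[h]
    v <- lattice$protons[h, ] - lattice$xyz[o, ]
    v <- v / sqrt(sum(v^2))
    bs <- inc_b[[o]]; ss <- inc_s[[o]]
    dots <- drop((u[bs, , drop = FALSE] * ss) %*% v)
    k <- which.max(dots)
    if (dots[k] > 0.99) per_b[bs[k]] <- per_b[bs[k]] + 1L
  }
  list(protons_per_oxygen = per_o,
       protons_per_bond = per_b,
       valid = all(per_o == 2L) && all(per_b == 1L))
}

#' @export
print.ice_lattice <- function(x, ...) {
  cat(sprintf("ice Ih lattice: %d oxygens, block %.2f x %.2f x %.2f A\n",
              nrow(x$xyz), x$cell[1], x$cell[2], x$cell[3]))
  cat(sprintf("  a = %.3f A (x), c = %.3f A (y), prism layer spacing %.3f A\n",
              x$spec$a, x$spec$c, x$d_layer))
  cat(sprintf("  protons: %s\n",
              if (is.null(x$protons)) "unassigned" else
                sprintf("assigned (net dipole %.3f per molecule)",
                        x$dipole_per_molecule)))
  invisible(x)
}
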