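## Synthetic trajectories with known ground truth.
##
## The generator emulates the statistical structure the trajectory analyses
## assume -- an immobile ice slab of lattice waters vibrating about their
## sites below an advancing (optionally curved) front, diffusing liquid
## above it, and an AFP track that is diffusive and then pinned -- without
## any interacting dynamics. Liquid motion is uncorrelated Gaussian
## displacement; this is deliberately non-physical but sufficient to test
## mobility classification, occupancy mapping and front extraction against
## exact ground truth.

#' Specification of a synthetic growth scenario
#'
#' @param box Box dimensions, angstroms.
#' @param front Front model: `"flat"` (height `z0 + v t`), `"tilted"`
#'   (adds `y tan(tilt)`), or `"cylindrical"` (circular arcs of the given
#'   radius bulging toward the liquid between pinning sites spaced
#'   `pin_spacing` along y).
#' @param z0 Initial front height at `y = 0`, angstroms.
#' @param velocity Front growth velocity, angstroms/ns (default 0).
#' @param tilt Front tilt for the tilted model, degrees.
#' @param radius Arc radius for the cylindrical model, angstroms (default
#'   46, the TIP4P critical cylindrical radius at 5 K supercooling).
#' @param pin_spacing Distance between pinning sites along y, angstroms
#'   (default the box length: one pinned site through the periodic
#'   boundary); must not exceed twice the radius.
#' @param vibration Ice vibration amplitude (Gaussian SD about the lattice
#'   site), angstroms (default 0.2).
#' @param diffusion Liquid diffusion coefficient, A^2/ps (default 0.1).
#' @param front_noise_sd Quenched per-site roughness of the front height,
#'   angstroms (default 0).
#' @param n_waters Total number of waters; must cover the lattice sites
#'   that ever freeze (default `NULL`: sites plus 20% liquid).
#' @param dt_frame Inter-frame time, ps (default 100, the capture interval
#'   the classifier window is defined for).
#' @param n_frames Number of frames (default 100).
#' @param a,c Ice lattice constants, angstroms.
#' @param seed RNG seed; identical seeds give bit-identical trajectories.
#' @return Object of class `growth_scenario`.
#' @export
growth_scenario <- function(box = c(30, 60, 60),
                            front = c("flat", "tilted", "cylindrical"),
                            z0 = 15, velocity = 0, tilt = 0, radius = 46,
                            pin_spacing = NULL, vibration = 0.2,
                            diffusion = 0.1, front_noise_sd = 0,
                            n_waters = NULL, dt_frame = 100,
                            n_frames = 100L, a = 4.5, c = 7.4, seed = 1L) {
  front <- match.arg(front)
  if (is.null(pin_spacing)) pin_spacing <- box[2]
  if (front == "cylindrical" && pin_spacing > 2 * radius)
    stop("pin_spacing exceeds the arc diameter: no circular arc connects ",
         "the pinning sites")
  if (vibration >= 0.8)
    warning("ice vibration amplitude ", vibration, " A is not below the ",
            "0.8 A classifier threshold; phases will not be separable")
  step <- sqrt(2 * diffusion * dt_frame)
  if (step <= 0.8)
    warning("liquid per-frame diffusive step ", signif(step, 3),
            " A is not above the 0.8 A classifier threshold; phases may ",
            "not be separable")
  structure(list(box = box, front = front, z0 = z0, velocity = velocity,
                 tilt = tilt, radius = radius, pin_spacing = pin_spacing,
                 vibration = vibration, diffusion = diffusion,
                 front_noise_sd = front_noise_sd, n_waters = n_waters,
                 dt_frame = dt_frame, n_frames = as.integer(n_frames),
                 a = a, c = c, seed = as.integer(seed)),
            class = "growth_scenario")
}

# Front height at positions y (vector) and time t (ps).
.front_height <- function(scn, y, t_ps) {
  v <- scn$velocity / 1000   # A per ps
  base <- scn$z0 + v * t_ps
  switch(scn$front,
    flat = rep(base, length(y)),
    tilted = base + y * tan(scn$tilt * pi / 180),
    cylindrical = {
      s <- scn$pin_spacing
      yy <- y %% s
      sag <- sqrt(scn$radius^2 - (s / 2)^2)
      base + pmax(0, sqrt(pmax(0, scn$radius^2 - (yy - s / 2)^2)) - sag)
    })
}

#' Generate a synthetic growth trajectory with ground truth
#'
#' Waters below the front vibrate about ice-lattice sites (Gaussian with
#' the scenario amplitude); waters above diffuse with reflective walls in z
#' and periodic x, y. As the front advances past a site, the water assigned
#' to that site freezes onto it. The returned ground truth records the
#' per-water per-frame phase label and the front height field per frame.
#'
#' @param scn A [growth_scenario()].
#' @return List with `traj` (an `md_trajectory`) and `truth` (list:
#'   `ice` logical matrix `n_waters x n_frames`, `front` matrix
#'   `n_frames x length(y_grid)`, `y_grid`, `site_xyz`, `site_of_water`).
#' @export
generate_growth_trajectory <- function(scn) {
  stopifnot(inherits(scn, "growth_scenario"))
  set.seed(scn$seed)
  box <- scn$box
  times <- (seq_len(scn$n_frames) - 1) * scn$dt_frame
  t_end <- times[length(times)]
  # candidate ice sites covering the frozen region
  spec <- lattice_spec(a = scn$a, c = scn$c,
                       n_a = max(1L, ceiling(box[1] / scn$a)),
                       n_b = max(1L, ceiling(box[2] / scn$c)),
                       n_c = max(1L, ceiling(
                         (max(.front_height(scn, seq(0, box[2], 1), t_end)) +
                            3 * scn$front_noise_sd + 2) /
                           (sqrt(3) * scn$a))))
  lat <- build_ice_lattice(spec)
  sites <- lat$xyz
  sites <- sites[sites[, 1] < box[1] & sites[, 2] < box[2] &
                   sites[, 3] < box[3], , drop = FALSE]
  eps <- if (scn$front_noise_sd > 0)
    stats::rnorm(nrow(sites), 0, scn$front_noise_sd) else numeric(nrow(sites))
  # freeze frame per site: first frame with site below the (noisy) front
  h_end <- .front_height(scn, sites[, 2], t_end) + eps
  ever <- sites[, 3] <= h_end
  sites <- sites[ever, , drop = FALSE]
  eps <- eps[ever]
  n_sites <- nrow(sites)
  freeze_frame <- rep(NA_integer_, n_sites)
  for (f in seq_along(times)) {
    h <- .front_height(scn, sites[, 2], times[f]) + eps
    new <- is.na(freeze_frame) & sites[, 3] <= h
    freeze_frame[new] <- f
  }
  freeze_frame[is.na(freeze_frame)] <- length(times) + 1L
  n_waters <- if (is.null(scn$n_waters)) ceiling(1.2 * n_sites)
    else scn$n_waters
  if (n_waters < n_sites)
    stop("n_waters = ", n_waters, " cannot cover the ", n_sites,
         " lattice sites that freeze during the run; the front would exit ",
         "the water budget")
  n_liq <- n_waters - n_sites
  nf <- length(times)
  coords <- array(NA_real_, c(n_waters, 3, nf))
  ice_truth <- matrix(FALSE, n_waters, nf)
  step_sd <- sqrt(2 * scn$diffusion * scn$dt_frame)
  # initial liquid positions above the initial front
  h0 <- function(y) .front_height(scn, y, times[1])
  init_liquid <- function(n) {
    p <- cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]), 0)
    lo <- h0(p[, 2]) + 0.5
    p[, 3] <- stats::runif(n, lo, box[3])
    p
  }
  pos <- init_liquid(n_waters)
  frozen <- rep(FALSE, n_waters)
  ff_all <- c(freeze_frame, rep(Inf, n_liq))
  for (f in seq_len(nf)) {
    newly <- which(!frozen & ff_all <= f)
    frozen[newly] <- TRUE
    liq <- which(!frozen)
    if (f > 1 && length(liq)) {
      stp <- matrix(stats::rnorm(3 * length(liq), 0, step_sd),
                    length(liq), 3)
      p <- pos[liq, , drop = FALSE] + stp
      p[, 1] <- p[, 1] %% box[1]
      p[, 2] <- p[, 2] %% box[2]
      # reflect z between the local front and the box top
      lo <- .front_height(scn, p[, 2], times[f]) + 0.5
      z <- p[, 3]
      z <- ifelse(z > box[3], 2 * box[3] - z, z)
      z <- ifelse(z < lo, 2 * lo - z, z)
      p[, 3] <- pmin(pmax(z, lo), box[3])
      pos[liq, ] <- p
    }
    if (length(which(frozen))) {
      fr <- which(frozen)
      pos[fr, ] <- sites[fr, , drop = FALSE] +
        matrix(stats::rnorm(3 * length(fr), 0, scn$vibration),
               length(fr), 3)
    }
    coords[, , f] <- pos
    ice_truth[, f] <- frozen
  }
  y_grid <- seq(0.5, box[2] - 0.5, by = 1)
  front_grid <- t(vapply(times, function(t) .front_height(scn, y_grid, t),
                         numeric(length(y_grid))))
  traj <- trajectory(coords, box = box, dt_frame = scn$dt_frame,
                     roles = rep("water", n_waters), time = times)
  list(traj = traj,
       truth = list(ice = ice_truth, front = front_grid, y_grid = y_grid,
                    site_xyz = sites,
                    site_of_water = c(seq_len(n_sites),
                                      rep(NA_integer_, n_liq)),
                    freeze_frame = c(freeze_frame,
                                     rep(NA_integer_, n_liq))))
}

#' Generate a synthetic AFP centre-of-mass binding track
#'
#' A 1-D diffusive height track ahead of the front, optionally pinned at
#' `pin_z` (with small jitter) from `bind_time_ns` onward. A never-binding
#' (mutant-like) track is `bind_time_ns = NULL`.
#'
#' @param bind_time_ns Binding time in ns, 0 for bound-from-start, or
#'   `NULL` for a never-binding track.
#' @param diffusion Centre-of-mass diffusion coefficient, A^2/ps (default
#'   0.01; protein centre-of-mass diffusion is much slower than water).
#' @param pin_z Pinned height (the ice-front height), angstroms.
#' @param wander Range `c(lo, hi)` of the reflective diffusion corridor
#'   relative to `pin_z` (default `c(5, 60)`: diffusing ahead of the
#'   front).
#' @param jitter SD of the pinned-height jitter, angstroms (default 0.3).
#' @param n_frames Number of frames (default 500).
#' @param dt_frame Inter-frame time, ps (default 100).
#' @param seed RNG seed.
#' @return List with `time` (ps), `com_z`, `front_z` (= `pin_z`), and
#'   `truth` (`bind_time` in ps or `NA`).
#' @export
generate_binding_track <- function(bind_time_ns = NULL, diffusion = 0.01,
                                   pin_z = 20, wander = c(5, 60),
                                   jitter = 0.3, n_frames = 500L,
                                   dt_frame = 100, seed = 1L) {
  set.seed(seed)
  times <- (seq_len(n_frames) - 1) * dt_frame
  bind_ps <- if (is.null(bind_time_ns)) Inf else bind_time_ns * 1000
  step_sd <- sqrt(2 * diffusion * dt_frame)
  lo <- pin_z + wander[1]; hi <- pin_z + wander[2]
  z <- numeric(n_frames)
  z[1] <- if (bind_ps <= 0) pin_z else stats::runif(1, lo + 5, hi - 5)
  for (f in seq_len(n_frames)[-1]) {
    if (times[f] >= bind_ps) {
      z[f] <- pin_z + stats::rnorm(1, 0, jitter)
    } else {
      zn <- z[f - 1] + stats::rnorm(1, 0, step_sd)
      if (zn > hi) zn <- 2 * hi - zn
      if (zn < lo) zn <- 2 * lo - zn
      z[f] <- min(max(zn, lo), hi)
    }
  }
  if (bind_ps <= 0) z[1] <- pin_z + stats::rnorm(1, 0, jitter)
  list(time = times, com_z = z, front_z = pin_z,
       truth = list(bind_time = if (is.infinite(bind_ps)) NA_real_
                    else bind_ps))
}

#' Build a planted ordered-bridging-water fixture
#'
#' Constructs an idealised snapshot of the AFP ice-binding surface: a row
#' of `n_bridge + 1` threonine hydroxyls spaced `spacing` apart along the
#' a-axis (x) above a prism-face patch of ice waters, with `n_bridge`
#' bridging waters planted between them in the fully coordinated geometry
#' (each donates one hydrogen bond to an ice water and one to a threonine
#' hydroxyl, and accepts one from each), at exactly the lattice spacing.
#' All planted bonds are linear with donor-acceptor distance
#' `spacing / (2 sin(109.47 deg / 2))` (about 2.76 A at the default
#' spacing).
#'
#' @param n_bridge Number of bridging waters (default 6, the length of the
#'   bridging array observed between the seven conserved IBS threonines).
#' @param spacing Bridging-water spacing along the a-axis, angstroms
#'   (default 4.5, the ice a-axis repeat).
#' @param d_max H-bond distance cutoff the geometry must satisfy (default
#'   3.5); infeasible geometry raises an error.
#' @param n_decoy Extra non-bonded liquid waters placed far above (default 2).
#' @return List with `frame` (an [md_frame()]), `ice_mols`, `ibs_mols`,
#'   `lattice_sites` (bulk ice oxygen positions) and `truth` (planted
#'   bridging molecule ids).
#' @export
generate_ordered_water_fixture <- function(n_bridge = 6, spacing = 4.5,
                                           d_max = 3.5, n_decoy = 2) {
  if (n_bridge < 0) stop("n_bridge must be >= 0")
  s <- sin(acos(-1 / 3) / 2)   # tetrahedral half-angle components
  c5 <- cos(acos(-1 / 3) / 2)
  d_hb <- spacing / (2 * s)
  if (d_hb > d_max)
    stop("infeasible geometry: spacing ", spacing, " A requires a ",
         signif(d_hb, 3), " A donor-acceptor distance, beyond the ",
         d_max, " A cutoff")
  r_OH <- 0.9572
  rows <- list()
  mol <- 0L
  add_mol <- function(kind, atoms) {
    mol <<- mol + 1L
    for (a in atoms)
      rows[[length(rows) + 1L]] <<- data.frame(
        mol = mol, elem = a$elem, kind = kind,
        x = a$p[1], y = a$p[2], z = a$p[3])
    mol
  }
  water <- function(o, h1, h2, kind = "water")
    add_mol(kind, list(list(elem = "O", p = o),
                       list(elem = "H", p = o + r_OH * h1),
                       list(elem = "H", p = o + r_OH * h2)))
  hydroxyl <- function(o, hdir)
    add_mol("hydroxyl", list(list(elem = "O", p = o),
                             list(elem = "H", p = o + r_OH * hdir)))
  u_acc_ice <- c(0,  s, -c5)   # W donates along this to an ice acceptor
  u_don_ice <- c(0, -s, -c5)   # ice donor sits along this, H pointing back
  u_thr_r  <- c( s, 0,  c5)    # W donates to the right hydroxyl
  u_thr_l  <- c(-s, 0,  c5)    # left hydroxyl donates to W
  bridge_ids <- integer(0)
  ice_ids <- integer(0)
  ibs_ids <- integer(0)
  if (n_bridge > 0) {
    for (k in seq_len(n_bridge)) {
      W <- c(spacing * (k - 1), 0, 0)
      # ice acceptor below (+y side) and ice donor below (-y side)
      A <- W + d_hb * u_acc_ice
      D <- W + d_hb * u_don_ice
      ice_ids <- c(ice_ids,
                   water(A, c(0, 0, -1), c(1, 0, 0)),
                   water(D, -u_don_ice, c(0, 0, -1)))
      bridge_ids <- c(bridge_ids, water(W, u_acc_ice, u_thr_r))
    }
    for (j in 0:n_bridge) {
      O <- c(spacing * j - spacing / 2, 0, d_hb * c5)
      hdir <- if (j < n_bridge) c(s, 0, -c5) else c(0, 0, 1)
      ibs_ids <- c(ibs_ids, hydroxyl(O, hdir))
    }
  } else {
    # detector contract requires a non-empty IBS set even with no bridges
    ibs_ids <- hydroxyl(c(0, 0, 3), c(0, 0, 1))
  }
  for (k in seq_len(n_decoy)) {
    O <- c(spacing * (k - 1), 6, 10 + 3 * k)
    water(O, c(0, 0, 1), c(1, 0, 0))
  }
  frame <- do.call(rbind, rows)
  class(frame) <- c("md_frame", "data.frame")
  lattice_sites <- if (length(ice_ids)) {
    o <- frame[frame$elem == "O" & frame$mol %in% ice_ids, ]
    as.matrix(o[, c("x", "y", "z")])
  } else matrix(numeric(0), 0, 3)
  list(frame = frame, ice_mols = ice_ids, ibs_mols = ibs_ids,
       lattice_sites = lattice_sites,
       truth = list(bridge_mols = bridge_ids, spacing = spacing))
}
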