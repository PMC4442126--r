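## Shared geometry helpers: periodic minimum image, neighbour pairs,
## rejection-sampled clash-free placement.

# Apply minimum-image convention to a displacement matrix (n x 3).
# box: length-3 dims; pbc: logical length-3.
.min_image <- function(d, box, pbc = c(TRUE, TRUE, TRUE)) {
  for (k in which(pbc)) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

# All pairs (i < j) within `cutoff`, chunked all-pairs with optional periodic
# minimum image. Adequate for the block sizes used here (<= ~5e3 points).
# Returns data.frame(i, j, dx, dy, dz, d) with the displacement j - i
# (minimum image).
.pairs_within <- function(xyz, cutoff, box = NULL, pbc = c(TRUE, TRUE, TRUE),
                          chunk = 500L) {
  n <- nrow(xyz)
  out <- vector("list", 0L)
  i0 <- 1L
  while (i0 <= n - 1L) {
    i1 <- min(i0 + chunk - 1L, n - 1L)
    idx_i <- i0:i1
    for (i in idx_i) {
      js <- (i + 1L):n
      d <- xyz[js, , drop = FALSE] -
        matrix(xyz[i, ], length(js), 3, byrow = TRUE)
      if (!is.null(box)) d <- .min_image(d, box, pbc)
      dist2 <- rowSums(d * d)
      keep <- which(dist2 <= cutoff^2)
      if (length(keep))
        out[[length(out) + 1L]] <- data.frame(
          i = i, j = js[keep],
          dx = d[keep, 1], dy = d[keep, 2], dz = d[keep, 3],
          d = sqrt(dist2[keep]))
    }
    i0 <- i1 + 1L
  }
  if (!length(out))
    return(data.frame(i = integer(), j = integer(), dx = numeric(),
                      dy = numeric(), dz = numeric(), d = numeric()))
  do.call(rbind, out)
}

# Neighbour pairs with explicit image enumeration: needed when a periodic
# dimension is shorter than twice the cutoff (e.g. a single ice unit cell),
# where distinct periodic images of the same pair are distinct bonds.
# Returns data.frame(i, j, sx, sy, sz, dx, dy, dz, d): atom j in image shift
# (sx,sy,sz) of the box, displacement from i to that image.
.pairs_within_images <- function(xyz, cutoff, box, pbc = c(TRUE, TRUE, TRUE)) {
  n <- nrow(xyz)
  shifts <- expand.grid(sx = -1:1, sy = -1:1, sz = -1:1)
  for (k in 1:3) if (!pbc[k]) shifts <- shifts[shifts[[k]] == 0, ]
  res <- vector("list", 0L)
  for (s in seq_len(nrow(shifts))) {
    sv <- as.numeric(shifts[s, ]) * box
    for (i in seq_len(n)) {
      d <- xyz + matrix(sv, n, 3, byrow = TRUE) -
        matrix(xyz[i, ], n, 3, byrow = TRUE)
      dist2 <- rowSums(d * d)
      keep <- which(dist2 <= cutoff^2 & dist2 > 1e-12)
      if (length(keep))
        res[[length(res) + 1L]] <- data.frame(
          i = i, j = keep,
          sx = shifts[s, 1], sy = shifts[s, 2], sz = shifts[s, 3],
          dx = d[keep, 1], dy = d[keep, 2], dz = d[keep, 3],
          d = sqrt(dist2[keep]))
    }
  }
  allp <- do.call(rbind, res)
  # dedupe (i,j,shift) against (j,i,-shift): keep canonical orientation
  canon <- with(allp, i < j |
                  (i == j & (sx > 0 | (sx == 0 & sy > 0) |
                               (sx == 0 & sy == 0 & sz > 0))))
  allp[canon, , drop = FALSE]
}

# Random sequential placement of points with a hard-core exclusion distance,
# inside an axis-aligned region of a periodic box. `existing` points also
# exclude. Cell-list accelerated; deterministic given the RNG state.
.rsa_fill <- function(n_target, box, zmin, zmax, existing = NULL,
                      cutoff = 2.2, pbc = c(TRUE, TRUE, FALSE),
                      max_consecutive_fail = 5000L) {
  if (n_target <= 0) return(matrix(numeric(0), 0, 3))
  cell <- cutoff * 1.001
  nc <- pmax(1L, as.integer(floor(box / cell)))
  csz <- box / nc
  cell_id <- function(p) {
    ix <- pmin(nc[1] - 1L, pmax(0L, as.integer(floor(p[, 1] / csz[1]))))
    iy <- pmin(nc[2] - 1L, pmax(0L, as.integer(floor(p[, 2] / csz[2]))))
    iz <- pmin(nc[3] - 1L, pmax(0L, as.integer(floor(p[, 3] / csz[3]))))
    ix + nc[1] * (iy + nc[2] * iz)
  }
  grid <- vector("list", prod(nc))
  pts <- matrix(NA_real_, n_target + NROW(existing), 3)
  npts <- 0L
  add_point <- function(p) {
    npts <<- npts + 1L
    pts[npts, ] <<- p
    id <- cell_id(matrix(p, 1, 3)) + 1L
    grid[[id]] <<- c(grid[[id]], npts)
  }
  if (!is.null(existing) && NROW(existing))
    for (r in seq_len(NROW(existing))) add_point(existing[r, ])
  n_existing <- npts
  # neighbour cell offsets (27, wrapped along periodic dims)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  clashes <- function(p) {
    ic <- c(floor(p[1] / csz[1]), floor(p[2] / csz[2]), floor(p[3] / csz[3]))
    for (o in seq_len(27L)) {
      cc <- ic + offs[o, ]
      for (k in 1:3) {
        if (pbc[k]) cc[k] <- cc[k] %% nc[k]
        else if (cc[k] < 0 || cc[k] >= nc[k]) { cc[k] <- NA; break }
      }
      if (anyNA(cc)) next
      id <- cc[1] + nc[1] * (cc[2] + nc[2] * cc[3]) + 1L
      occ <- grid[[id]]
      if (is.null(occ)) next
      d <- pts[occ, , drop = FALSE] - matrix(p, length(occ), 3, byrow = TRUE)
      d <- .min_image(d, box, pbc)
      if (any(rowSums(d * d) < cutoff^2)) return(TRUE)
    }
    FALSE
  }
  placed <- 0L
  fails <- 0L
  while (placed < n_target) {
    p <- c(stats::runif(1, 0, box[1]), stats::runif(1, 0, box[2]),
           stats::runif(1, zmin, zmax))
    if (clashes(p)) {
      fails <- fails + 1L
      if (fails >= max_consecutive_fail)
        stop("placement budget exhausted after ", placed, " of ", n_target,
             " molecules: target density unreachable with a ", cutoff,
             " A exclusion distance")
      next
    }
    add_point(p)
    placed <- placed + 1L
    fails <- 0L
  }
  pts[(n_existing + 1L):npts, , drop = FALSE]
}

# Number density (molecules per A^3) of water at a mass density in kg/m^3.
.number_density <- function(density_kg_m3, M_w = 0.018) {
  density_kg_m3 / M_w * .N_A * 1e-30
}
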