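## Occupancy-averaged ice-front extraction and cylindrical curvature fit.
##
## The time-averaged ice front is the surface where voxel water occupancy
## exceeds a threshold (default 85% of frames); its y-z profile is compared
## with the theoretical Gibbs-Thomson cylindrical radius.

#' Time-averaged water occupancy grid
#'
#' Rasterises each water oxygen as a sphere of radius `r_atom` onto a cubic
#' voxel grid (a voxel counts as occupied in a frame when any part of its
#' cube intersects the oxygen sphere) and averages over frames.
#'
#' @param traj An `md_trajectory`.
#' @param t_start,t_end Time window, ps (default the whole trajectory).
#' @param voxel Voxel edge, angstroms (default 1.0).
#' @param r_atom Rasterisation radius, angstroms (default 1.4, a water
#'   oxygen van der Waals radius).
#' @param roles Atom roles included (default all water roles).
#' @return Object of class `occupancy_grid`: 3-D array `grid` (fractions in
#'   `[0, 1]`), `voxel`, `r_atom`, `box`, `n_frames`, and the axis voxel
#'   centres `x`, `y`, `z`.
#' @export
occupancy_map <- function(traj, t_start = -Inf, t_end = Inf, voxel = 1.0,
                          r_atom = 1.4,
                          roles = c("water", "seed", "barrier")) {
  stopifnot(inherits(traj, "md_trajectory"))
  frames <- which(traj$time >= t_start & traj$time <= t_end)
  if (!length(frames)) stop("zero-length occupancy window")
  if (length(frames) < 100)
    warning("occupancy averaged over only ", length(frames),
            " frames; >= 100 recommended")
  idx <- which(traj$roles %in% roles)
  if (!length(idx)) stop("no atoms with the requested roles")
  box <- traj$box
  nv <- pmax(1L, as.integer(floor(box / voxel)))
  span <- ceiling(r_atom / voxel + 0.5)
  offs <- as.matrix(expand.grid(dx = -span:span, dy = -span:span,
                                dz = -span:span))
  counts <- array(0, nv)
  for (f in frames) {
    p <- traj$coords[idx, , f, drop = FALSE][, , 1]
    if (is.null(dim(p))) p <- matrix(p, 1, 3)
    p[, 1] <- p[, 1] %% box[1]
    p[, 2] <- p[, 2] %% box[2]
    base <- floor(sweep(p, 2, rep(voxel, 3), `/`))
    marked <- integer(0)
    for (o in seq_len(nrow(offs))) {
      cand <- sweep(base, 2, offs[o, ], `+`)
      ctr <- (cand + 0.5) * voxel
      # voxel occupied when its cube intersects the atom sphere
      g <- pmax(abs(p - ctr) - voxel / 2, 0)
      d2 <- rowSums(g * g)
      sel <- d2 <= r_atom^2
      if (!any(sel)) next
      cc <- cand[sel, , drop = FALSE]
      cc[, 1] <- cc[, 1] %% nv[1]
      cc[, 2] <- cc[, 2] %% nv[2]
      inz <- cc[, 3] >= 0 & cc[, 3] < nv[3]
      if (!any(inz)) next
      cc <- cc[inz, , drop = FALSE]
      marked <- c(marked, cc[, 1] + nv[1] * (cc[, 2] + nv[2] * cc[, 3]) + 1L)
    }
    u <- unique(marked)
    counts[u] <- counts[u] + 1
  }
  structure(list(grid = counts / length(frames), voxel = voxel,
                 r_atom = r_atom, box = box, n_frames = length(frames),
                 x = (seq_len(nv[1]) - 0.5) * voxel,
                 y = (seq_len(nv[2]) - 0.5) * voxel,
                 z = (seq_len(nv[3]) - 0.5) * voxel),
            class = "occupancy_grid")
}

# 26-connected flood fill from a starting voxel layer, periodic in x and y.
.flood_from_seed <- function(mask, k_start, nv) {
  visited <- array(FALSE, nv)
  frontier <- which(mask & slice.index(mask, 3) <= k_start)
  visited[frontier] <- TRUE
  nxy <- nv[1] * nv[2]
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  while (length(frontier)) {
    id0 <- frontier - 1L
    ix <- id0 %% nv[1]
    iy <- (id0 %/% nv[1]) %% nv[2]
    iz <- id0 %/% nxy
    nb <- integer(0)
    for (o in seq_len(nrow(offs))) {
      jz <- iz + offs[o, 3]
      okz <- jz >= 0L & jz < nv[3]
      if (!any(okz)) next
      jx <- (ix[okz] + offs[o, 1]) %% nv[1]
      jy <- (iy[okz] + offs[o, 2]) %% nv[2]
      nb <- c(nb, jx + nv[1] * jy + nxy * jz[okz] + 1L)
    }
    nb <- unique(nb[mask[nb] & !visited[nb]])
    visited[nb] <- TRUE
    frontier <- nb
  }
  visited
}

#' Extract the ice-front height field from an occupancy grid
#'
#' Thresholds the occupancy grid, keeps the above-threshold region that is
#' contiguous with the seed (3-D flood fill, periodic in x and y -- internal
#' lattice voids do not break columns), and reports, per (x, y) column, the
#' top of that region. Column heights are corrected downward by
#' `height_offset`: rasterised coverage extends one `r_atom` beyond the
#' outermost oxygen centres, the reported discrete voxel face overshoots by
#' half a voxel on average, and the topmost occupied site plane lies about
#' half an interlayer spacing below the nominal phase boundary, so the
#' default correction is `r_atom - voxel` (the latter two terms roughly
#' cancelling one voxel). Columns with no above-threshold voxel are
#' interpolated along y. An optional moving-average smoothing kernel can be
#' applied along y.
#'
#' @param grid An `occupancy_grid`.
#' @param threshold Occupancy threshold (default 0.85).
#' @param seed_top_z Height of the seed top, angstroms; the flood fill
#'   starts from above-threshold voxels at or below this height (default
#'   one voxel layer above the grid bottom).
#' @param height_offset Downward correction of the reported heights, A
#'   (default `r_atom - voxel`).
#' @param smooth Half-width (in columns) of a moving-average smoothing of
#'   the height field along y; 0 (default) disables smoothing.
#' @return Object of class `front_surface`: `height` matrix (nx x ny, A),
#'   axis centres `x`, `y`, `threshold`, and `n_missing` interpolated
#'   columns.
#' @export
extract_front <- function(grid, threshold = 0.85, seed_top_z = NULL,
                          height_offset = NULL, smooth = 0L) {
  stopifnot(inherits(grid, "occupancy_grid"))
  if (is.null(height_offset)) height_offset <- grid$r_atom - grid$voxel
  mask <- grid$grid > threshold
  if (!any(mask))
    stop("no voxel above occupancy threshold ", threshold)
  nv <- dim(mask)
  if (is.null(seed_top_z)) seed_top_z <- grid$z[1]
  k_start <- max(1L, min(nv[3], ceiling(seed_top_z / grid$voxel) + 1L))
  visited <- .flood_from_seed(mask, k_start, nv)
  if (!any(visited))
    stop("no above-threshold voxel contiguous with the seed layer")
  height <- matrix(NA_real_, nv[1], nv[2])
  for (i in seq_len(nv[1])) for (j in seq_len(nv[2])) {
    ks <- which(visited[i, j, ])
    if (length(ks))
      height[i, j] <- ks[length(ks)] * grid$voxel - height_offset
  }
  n_missing <- sum(is.na(height))
  if (n_missing) {
    for (i in seq_len(nv[1])) {
      row <- height[i, ]
      if (all(is.na(row))) next
      if (anyNA(row))
        height[i, ] <- stats::approx(grid$y[!is.na(row)], row[!is.na(row)],
                                     xout = grid$y, rule = 2)$y
    }
    if (anyNA(height)) {
      colmean <- colMeans(height, na.rm = TRUE)
      for (i in seq_len(nv[1]))
        height[i, is.na(height[i, ])] <- colmean[is.na(height[i, ])]
    }
  }
  if (smooth > 0) {
    k <- 2L * as.integer(smooth) + 1L
    for (i in seq_len(nv[1]))
      height[i, ] <- stats::filter(height[i, ], rep(1 / k, k),
                                   circular = TRUE)
  }
  structure(list(height = height, x = grid$x, y = grid$y,
                 threshold = threshold, voxel = grid$voxel,
                 height_offset = height_offset, n_missing = n_missing),
            class = "front_surface")
}

#' Fit a cylinder (circle in the y-z plane) to an ice-front surface
#'
#' Averages the height field over x (the cylinder axis), then fits a circle
#' to the (y, height) profile by linear least squares. A profile with no
#' measurable curvature is reported as `finite = FALSE` ("no finite
#' curvature") rather than as an error.
#'
#' @param front A `front_surface`, or a list/data.frame with `y` and
#'   `height` vectors for a raw profile.
#' @param axis Cylinder axis; only `"x"` (the periodic a-axis direction of
#'   the interface model) is supported.
#' @param max_radius_factor Radii beyond this multiple of the profile span
#'   are reported as no finite curvature (default 25).
#' @return Object of class `cylinder_fit`: `radius` (A; `Inf` when not
#'   finite), `center` (y, z), `residual` (RMS, A), `finite`,
#'   `convex_toward_liquid` (TRUE when the ice bulges upward into the
#'   liquid), `n_points`.
#' @export
fit_cylinder <- function(front, axis = "x", max_radius_factor = 25) {
  if (!identical(axis, "x"))
    stop("only a cylinder axis along x is supported")
  if (inherits(front, "front_surface")) {
    y <- front$y
    z <- colMeans(front$height)
  } else {
    y <- front$y
    z <- front$height
  }
  ok <- is.finite(y) & is.finite(z)
  y <- y[ok]; z <- z[ok]
  n <- length(y)
  if (n < 5) stop("need at least 5 profile points for a circle fit")
  span <- max(max(y) - min(y), max(z) - min(z))
  # RMS of the profile about the best straight line: a circle is only
  # reported when it describes the profile clearly better than a line
  lin <- stats::lm.fit(cbind(1, y), z)
  rms_line <- sqrt(mean(lin$residuals^2))
  A <- cbind(2 * y, 2 * z, 1)
  b <- y^2 + z^2
  sol <- tryCatch(solve(crossprod(A), crossprod(A, b)),
                  error = function(e) NULL)
  not_finite <- function() structure(
    list(radius = Inf, center = c(NA_real_, NA_real_),
         residual = rms_line, finite = FALSE,
         convex_toward_liquid = NA, n_points = n), class = "cylinder_fit")
  if (rms_line < 0.05) return(not_finite())
  if (is.null(sol)) return(not_finite())
  y0 <- sol[1]; z0 <- sol[2]
  R2 <- sol[3] + y0^2 + z0^2
  if (!is.finite(R2) || R2 <= 0) return(not_finite())
  R <- sqrt(R2)
  if (R > max_radius_factor * span) return(not_finite())
  resid <- sqrt(mean((sqrt((y - y0)^2 + (z - z0)^2) - R)^2))
  if (resid >= 0.5 * rms_line) return(not_finite())
  structure(list(radius = R, center = c(y = y0, z = z0), residual = resid,
                 finite = TRUE, convex_toward_liquid = z0 < mean(z),
                 n_points = n), class = "cylinder_fit")
}

#' @export
print.cylinder_fit <- function(x, ...) {
  if (!x$finite) {
    cat("no finite curvature (flat front profile)\n")
  } else {
    cat(sprintf("cylinder fit: radius %.1f A, centre (y = %.1f, z = %.1f), RMS residual %.2f A\n",
                x$radius, x$center[1], x$center[2], x$residual))
    cat(sprintf("  convex toward liquid: %s\n", x$convex_toward_liquid))
  }
  invisible(x)
}
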