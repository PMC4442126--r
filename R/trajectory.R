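## Trajectory container and readers/writers.
##
## Coordinates are stored as an n_atoms x 3 x n_frames array with a fixed
## inter-frame time (default 100 ps, the capture interval assumed
## throughout). Atom roles: "water" (free water oxygen), "seed" and
## "barrier" (constrained water oxygens), "protein".

.role_tokens <- c(water = "OW", seed = "OWS", barrier = "OWB",
                  protein = "PRT")

#' Construct a trajectory object
#'
#' @param coords Numeric array `n_atoms x 3 x n_frames` (angstroms).
#' @param box Periodic box dimensions `c(L_x, L_y, L_z)`, angstroms; the
#'   box is treated as periodic in x and y (constant-XY slab geometry).
#' @param dt_frame Inter-frame time, ps (default 100).
#' @param roles Character vector per atom: `"water"`, `"seed"`,
#'   `"barrier"` or `"protein"` (default all `"water"`).
#' @param time Optional frame times, ps (default `0, dt, 2 dt, ...`).
#' @return Object of class `md_trajectory`.
#' @export
trajectory <- function(coords, box, dt_frame = 100, roles = NULL,
                       time = NULL) {
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    stop("coords must be an n_atoms x 3 x n_frames array")
  if (dt_frame <= 0) stop("dt_frame must be positive")
  n_atoms <- dim(coords)[1]
  n_frames <- dim(coords)[3]
  if (is.null(roles)) roles <- rep("water", n_atoms)
  if (length(roles) != n_atoms) stop("one role per atom required")
  bad <- setdiff(unique(roles), names(.role_tokens))
  if (length(bad)) stop("unknown atom roles: ", paste(bad, collapse = ", "))
  if (is.null(time)) time <- (seq_len(n_frames) - 1) * dt_frame
  structure(list(coords = coords, box = box, dt_frame = dt_frame,
                 roles = roles, time = time,
                 n_atoms = n_atoms, n_frames = n_frames),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d atoms, %d frames, dt = %g ps, box %.1f x %.1f x %.1f A\n",
              x$n_atoms, x$n_frames, x$dt_frame,
              x$box[1], x$box[2], x$box[3]))
  print(table(x$roles))
  invisible(x)
}

#' Write a trajectory in the annotated XYZ dialect
#'
#' Frame layout: an atom-count line; a comment line
#' `t= <ps> box= <Lx> <Ly> <Lz>`; then one `<role-token> x y z` line per
#' atom, with role tokens OW (free water oxygen), OWS (seed), OWB
#' (barrier), PRT (protein).
#'
#' @param traj An `md_trajectory`.
#' @param path Output path.
#' @param digits Coordinate decimals (default 4).
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path, digits = 4) {
  stopifnot(inherits(traj, "md_trajectory"))
  tokens <- .role_tokens[traj$roles]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(traj$n_frames)) {
    writeLines(as.character(traj$n_atoms), con)
    writeLines(sprintf("t= %g box= %g %g %g", traj$time[f],
                       traj$box[1], traj$box[2], traj$box[3]), con)
    m <- traj$coords[, , f, drop = FALSE]
    writeLines(sprintf("%s %.*f %.*f %.*f", tokens,
                       digits, m[, 1, 1], digits, m[, 2, 1],
                       digits, m[, 3, 1]), con)
  }
  invisible(path)
}

#' Read a trajectory in the annotated XYZ dialect
#'
#' @param path File written by [write_trajectory_xyz()] (or by any tool
#'   emitting the same dialect).
#' @return An `md_trajectory`.
#' @export
read_trajectory_xyz <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty trajectory file")
  n_atoms <- as.integer(lines[1])
  stride <- n_atoms + 2L
  if (length(lines) %% stride != 0)
    stop("malformed XYZ trajectory: line count not a multiple of ",
         "n_atoms + 2")
  n_frames <- length(lines) %/% stride
  coords <- array(NA_real_, c(n_atoms, 3, n_frames))
  time <- numeric(n_frames)
  box <- NULL
  roles <- NULL
  for (f in seq_len(n_frames)) {
    off <- (f - 1L) * stride
    hdr <- strsplit(trimws(lines[off + 2L]), "\\s+")[[1]]
    ti <- which(hdr == "t=");  bi <- which(hdr == "box=")
    if (!length(ti) || !length(bi))
      stop("frame ", f, ": comment line must carry 't= <ps> box= Lx Ly Lz'")
    time[f] <- as.numeric(hdr[ti + 1L])
    bx <- as.numeric(hdr[bi + 1:3])
    if (is.null(box)) box <- bx
    body <- lines[off + 2L + seq_len(n_atoms)]
    parts <- matrix(unlist(strsplit(trimws(body), "\\s+")), ncol = 4,
                    byrow = TRUE)
    if (is.null(roles)) {
      roles <- names(.role_tokens)[match(parts[, 1], .role_tokens)]
      if (anyNA(roles))
        stop("unknown atom token(s): ",
             paste(unique(parts[is.na(roles), 1]), collapse = ", "))
    }
    coords[, , f] <- as.numeric(parts[, 2:4])
  }
  dt <- if (n_frames > 1) diff(time)[1] else 100
  trajectory(coords, box = box, dt_frame = dt, roles = roles, time = time)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Water oxygens (residue HOH/TIP3/TIP4/WAT/SOL, atom name starting with O)
#' become water atoms, with chain S and B mapped to the seed and barrier
#' roles as written by [write_system()]; all non-water atoms are protein.
#' Water hydrogens are dropped (all mobility and occupancy analyses operate
#' on oxygen positions).
#'
#' @param path PDB file with MODEL/ENDMDL records.
#' @param box Box dimensions (required; PDB headers are not relied upon).
#' @param dt_frame Inter-frame time, ps (default 100).
#' @return An `md_trajectory`.
#' @export
read_trajectory_pdb <- function(path, box, dt_frame = 100) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  at <- pdb$atom
  water_res <- c("HOH", "TIP3", "TIP4", "WAT", "SOL")
  is_water <- at$resid %in% water_res
  keep <- !is_water | substr(at$elety, 1, 1) == "O"
  roles <- ifelse(!is_water[keep], "protein",
                  ifelse(at$chain[keep] %in% "S", "seed",
                         ifelse(at$chain[keep] %in% "B", "barrier", "water")))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_frames <- nrow(xyz)
  idx <- which(keep)
  coords <- array(NA_real_, c(length(idx), 3, n_frames))
  for (f in seq_len(n_frames)) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    coords[, , f] <- m[idx, , drop = FALSE]
  }
  trajectory(coords, box = box, dt_frame = dt_frame, roles = roles)
}

#' Read a DCD trajectory with a companion topology PDB
#'
#' Thin wrapper over [bio3d::read.dcd()]; roles are taken from the
#' companion PDB as in [read_trajectory_pdb()].
#'
#' @param dcd_path Binary DCD file.
#' @param top_path Topology PDB (single frame, same atom order).
#' @param box Box dimensions.
#' @param dt_frame Inter-frame time, ps.
#' @return An `md_trajectory`.
#' @export
read_trajectory_dcd <- function(dcd_path, top_path, box, dt_frame = 100) {
  top <- read_trajectory_pdb(top_path, box = box, dt_frame = dt_frame)
  xyz <- bio3d::read.dcd(dcd_path, verbose = FALSE)
  n_frames <- nrow(xyz)
  n_all <- ncol(xyz) / 3
  pdb <- bio3d::read.pdb(top_path)
  water_res <- c("HOH", "TIP3", "TIP4", "WAT", "SOL")
  at <- pdb$atom
  keep <- !(at$resid %in% water_res) | substr(at$elety, 1, 1) == "O"
  if (sum(keep) != top$n_atoms || n_all != nrow(at))
    stop("topology PDB does not match the DCD atom count")
  coords <- array(NA_real_, c(top$n_atoms, 3, n_frames))
  for (f in seq_len(n_frames)) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    coords[, , f] <- m[keep, , drop = FALSE]
  }
  trajectory(coords, box = box, dt_frame = dt_frame, roles = top$roles)
}

# Unwrap water displacements across periodic boundaries: cumulative
# minimum-image frame-to-frame displacements added to the first frame.
.unwrap_coords <- function(coords, box, pbc = c(TRUE, TRUE, FALSE)) {
  out <- coords
  n_frames <- dim(coords)[3]
  if (n_frames < 2) return(out)
  for (f in 2:n_frames) {
    d <- matrix(coords[, , f] - coords[, , f - 1], ncol = 3)
    d <- .min_image(d, box, pbc)
    out[, , f] <- matrix(out[, , f - 1], ncol = 3) + d
  }
  out
}

# Frame f of a coordinate array as an n x 3 matrix (robust to n = 1).
.frame_mat <- function(arr, f) matrix(arr[, , f], ncol = 3)
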