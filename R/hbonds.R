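## Geometric hydrogen-bond detection and ordered bridging-water analysis.
##
## An H-bond is recorded when the donor-O to acceptor-O distance is within
## d_max and the H-donor-acceptor angle is within angle_max (minimum image
## where a box is given) -- the standard geometric convention (3.5 A, 30 deg).

#' Construct a single-frame molecular snapshot
#'
#' @param mol Integer molecule id per atom.
#' @param elem `"O"` for a heavy (oxygen) site, `"H"` for a hydrogen.
#' @param kind Per-atom molecule kind: `"water"` or `"hydroxyl"` (threonine
#'   OG1/HG1 group); other kinds are ignored by the detectors.
#' @param x,y,z Coordinates, angstroms.
#' @return data.frame of class `md_frame`.
#' @export
md_frame <- function(mol, elem, kind, x, y, z) {
  d <- data.frame(mol = as.integer(mol), elem = elem, kind = kind,
                  x = x, y = y, z = z)
  class(d) <- c("md_frame", "data.frame")
  d
}

#' Detect hydrogen bonds in a snapshot
#'
#' Each hydrogen is assigned to the oxygen of its own molecule (the donor).
#' A bond donor -> acceptor is recorded when the O-O distance is at most
#' `d_max` and the H-donor-acceptor angle is at most `angle_max`.
#'
#' @param frame An [md_frame()] (or data.frame with the same columns).
#' @param d_max Donor-acceptor O-O cutoff, angstroms (default 3.5).
#' @param angle_max H-donor-acceptor angle cutoff, degrees (default 30).
#' @param box Optional periodic box (minimum image in x, y, z when given).
#' @param pbc Periodic dimensions (default all, when `box` is given).
#' @return data.frame with `donor_mol`, `acceptor_mol`, `dist` (O-O, A)
#'   and `angle` (deg), one row per bond.
#' @export
detect_hbonds <- function(frame, d_max = 3.5, angle_max = 30, box = NULL,
                          pbc = c(TRUE, TRUE, TRUE)) {
  ox <- frame[frame$elem == "O", ]
  hy <- frame[frame$elem == "H", ]
  if (!nrow(hy))
    stop("no hydrogens in frame and no inference rule: cannot assign donors")
  if (!nrow(ox)) stop("no oxygens in frame")
  o_of_mol <- match(hy$mol, ox$mol)
  if (anyNA(o_of_mol))
    stop("hydrogen(s) belonging to molecules without an oxygen")
  O <- as.matrix(ox[, c("x", "y", "z")])
  H <- as.matrix(hy[, c("x", "y", "z")])
  res <- vector("list", 0L)
  cosmax <- cos(angle_max * pi / 180)
  for (h in seq_len(nrow(H))) {
    d_i <- o_of_mol[h]
    dO <- O - matrix(O[d_i, ], nrow(O), 3, byrow = TRUE)
    if (!is.null(box)) dO <- .min_image(dO, box, pbc)
    dist2 <- rowSums(dO * dO)
    cand <- which(dist2 <= d_max^2 & ox$mol != ox$mol[d_i])
    if (!length(cand)) next
    vh <- H[h, ] - O[d_i, ]
    if (!is.null(box)) vh <- drop(.min_image(matrix(vh, 1), box, pbc))
    nh <- sqrt(sum(vh^2))
    for (a in cand) {
      va <- dO[a, ]
      ca <- sum(vh * va) / (nh * sqrt(dist2[a]))
      if (ca >= cosmax)
        res[[length(res) + 1L]] <- data.frame(
          donor_mol = ox$mol[d_i], acceptor_mol = ox$mol[a],
          dist = sqrt(dist2[a]), angle = acos(pmin(1, ca)) * 180 / pi)
    }
  }
  if (!length(res))
    return(data.frame(donor_mol = integer(), acceptor_mol = integer(),
                      dist = numeric(), angle = numeric()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Detect ordered bridging waters at the AFP ice-binding surface
#'
#' Finds waters that bridge between the ice surface and the AFP: waters not
#' labelled ice that have at least one hydrogen bond (in either direction)
#' to an ice-labelled water and at least one to an ice-binding-surface
#' threonine hydroxyl. Members with at least two bonds of each class are
#' flagged fully coordinated (the fully satisfied tetrahedral arrangement:
#' two bonds to prism-face ice waters, two to adjacent threonine
#' hydroxyls). Nearest-neighbour spacing is reported along the a-axis (x),
#' and, when ideal lattice positions are supplied, the distance of each
#' member to the nearest ideal site (bridging waters sit at positions
#' distinct from bulk-ice sites).
#'
#' @param frame An [md_frame()] containing water and hydroxyl molecules.
#' @param ice_mols Molecule ids of ice-labelled waters.
#' @param ibs_mols Molecule ids of the IBS threonine hydroxyl groups.
#' @param d_max,angle_max,box,pbc Passed to [detect_hbonds()].
#' @param lattice_sites Optional matrix of ideal bulk-ice oxygen positions.
#' @return Object of class `ordered_waters`: data.frame `members` (mol,
#'   `x`, `n_hb_ice`, `n_hb_ibs`, `fully_coordinated`, `dist_to_lattice`),
#'   `mean_spacing` (A along x, `NA` with fewer than 2 members) and
#'   `n_members`.
#' @export
detect_ordered_waters <- function(frame, ice_mols, ibs_mols, d_max = 3.5,
                                  angle_max = 30, box = NULL,
                                  pbc = c(TRUE, TRUE, TRUE),
                                  lattice_sites = NULL) {
  if (!length(ibs_mols)) stop("empty ice-binding-surface set")
  hb <- detect_hbonds(frame, d_max, angle_max, box, pbc)
  ox <- frame[frame$elem == "O", ]
  waters <- ox$mol[ox$kind == "water"]
  cand <- setdiff(waters, ice_mols)
  count_to <- function(mol, set) {
    sum(hb$donor_mol == mol & hb$acceptor_mol %in% set) +
      sum(hb$acceptor_mol == mol & hb$donor_mol %in% set)
  }
  n_ice <- vapply(cand, count_to, numeric(1), set = ice_mols)
  n_ibs <- vapply(cand, count_to, numeric(1), set = ibs_mols)
  keep <- n_ice >= 1 & n_ibs >= 1
  members <- data.frame(mol = cand[keep],
                        x = ox$x[match(cand[keep], ox$mol)],
                        n_hb_ice = n_ice[keep], n_hb_ibs = n_ibs[keep],
                        fully_coordinated = n_ice[keep] >= 2 &
                          n_ibs[keep] >= 2)
  members <- members[order(members$x), ]
  rownames(members) <- NULL
  if (!is.null(lattice_sites) && nrow(members)) {
    P <- as.matrix(ox[match(members$mol, ox$mol), c("x", "y", "z")])
    L <- as.matrix(lattice_sites)
    members$dist_to_lattice <- vapply(seq_len(nrow(P)), function(k) {
      d <- L - matrix(P[k, ], nrow(L), 3, byrow = TRUE)
      if (!is.null(box)) d <- .min_image(d, box, pbc)
      sqrt(min(rowSums(d * d)))
    }, numeric(1))
  }
  mean_spacing <- if (nrow(members) >= 2) mean(diff(members$x)) else NA_real_
  structure(list(members = members, mean_spacing = mean_spacing,
                 n_members = nrow(members)),
            class = "ordered_waters")
}

#' @export
print.ordered_waters <- function(x, ...) {
  cat(sprintf("%d ordered bridging water(s)", x$n_members))
  if (x$n_members) {
    cat(sprintf(", %d fully coordinated", sum(x$members$fully_coordinated)))
    if (!is.na(x$mean_spacing))
      cat(sprintf(", mean a-axis spacing %.2f A", x$mean_spacing))
  }
  cat("\n")
  invisible(x)
}
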