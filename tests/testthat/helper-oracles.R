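# Independent oracles used by the tests. These deliberately re-derive
# results by brute force or closed form, separately from the package code
# paths they check.

N_AVOGADRO <- 6.02214076e23

# Brute-force enumeration of all Bernal-Fowler-valid proton configurations
# of a small periodic cell: every assignment of a direction to every bond,
# filtered by "each oxygen donates exactly two".
enumerate_ice_states <- function(bonds, n_oxygens) {
  nb <- nrow(bonds)
  stopifnot(nb <= 20)
  n_states <- 2^nb
  bits <- matrix(0L, n_states, nb)
  for (b in seq_len(nb))
    bits[, b] <- bitwAnd(seq_len(n_states) - 1L, bitwShiftL(1L, b - 1L)) > 0
  Ii <- matrix(0L, nb, n_oxygens)
  Ij <- matrix(0L, nb, n_oxygens)
  for (b in seq_len(nb)) {
    Ii[b, bonds$i[b]] <- Ii[b, bonds$i[b]] + 1L
    Ij[b, bonds$j[b]] <- Ij[b, bonds$j[b]] + 1L
  }
  outdeg <- bits %*% Ii + (1 - bits) %*% Ij
  valid <- rowSums(outdeg == 2L) == n_oxygens
  bits[valid, , drop = FALSE]
}

bond_dir_key <- function(dir) paste(as.integer(dir == 1L), collapse = "")

# All-pairs hydrogen-bond oracle: direct double loop over every hydrogen
# and every candidate acceptor oxygen.
oracle_hbonds <- function(frame, d_max = 3.5, angle_max = 30, box = NULL) {
  O <- frame[frame$elem == "O", ]
  H <- frame[frame$elem == "H", ]
  mi <- function(v) {
    if (!is.null(box)) v - box * round(v / box) else v
  }
  out <- NULL
  for (h in seq_len(nrow(H))) {
    d_i <- which(O$mol == H$mol[h])[1]
    for (a in seq_len(nrow(O))) {
      if (O$mol[a] == O$mol[d_i]) next
      dv <- mi(c(O$x[a] - O$x[d_i], O$y[a] - O$y[d_i], O$z[a] - O$z[d_i]))
      dd <- sqrt(sum(dv^2))
      if (dd > d_max) next
      hv <- mi(c(H$x[h] - O$x[d_i], H$y[h] - O$y[d_i], H$z[h] - O$z[d_i]))
      ang <- acos(min(1, sum(dv * hv) / (dd * sqrt(sum(hv^2))))) * 180 / pi
      if (ang <= angle_max)
        out <- rbind(out, data.frame(donor_mol = O$mol[d_i],
                                     acceptor_mol = O$mol[a]))
    }
  }
  out
}

# Random small water system for oracle comparisons.
random_water_frame <- function(n, box, seed) {
  set.seed(seed)
  rows <- NULL
  for (m in seq_len(n)) {
    o <- runif(3) * box
    for (rep in 1:2) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      h <- o + 0.9572 * u
      rows <- rbind(rows, data.frame(mol = m, elem = "H", kind = "water",
                                     x = h[1], y = h[2], z = h[3]))
    }
    rows <- rbind(rows, data.frame(mol = m, elem = "O", kind = "water",
                                   x = o[1], y = o[2], z = o[3]))
  }
  md_frame(rows$mol, rows$elem, rows$kind, rows$x, rows$y, rows$z)
}

# Hand-crafted fixed-column PDB text for reader tests (external format,
# written independently of the package writers).
pdb_atom_line <- function(ser, name, resn, chain, resno, x, y, z, b = 0) {
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          ser, name, resn, chain, resno, x, y, z, 1, b)
}
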