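#' Backbone-dihedral secondary-structure assignment
#'
#' Classifies each residue of each frame as helix (H), strand (E) or coil (C)
#' from its backbone (phi, psi) dihedrals, using broad Ramachandran regions:
#' helix for phi in (-100, -30) and psi in (-80, -5); strand for phi in
#' (-180, -40) and psi above 90 or below -170. Chain-terminal residues lack
#' one dihedral and are assigned coil.
#'
#' @param traj a `kin_trajectory` whose topology carries backbone N, CA, C
#'   atoms.
#' @return character matrix, frames by residues (columns named by residue
#'   number).
#' @export
assign_ss <- function(traj) {
  at <- traj$top$atoms
  resno <- unique(at$resno)
  n <- length(resno)
  idx_of <- function(res, name) {
    i <- which(at$resno == res & at$elety == name)
    if (length(i) != 1L) NA_integer_ else i
  }
  n_idx <- vapply(resno, idx_of, integer(1), name = "N")
  ca_idx <- vapply(resno, idx_of, integer(1), name = "CA")
  c_idx <- vapply(resno, idx_of, integer(1), name = "C")
  if (anyNA(n_idx) || anyNA(ca_idx) || anyNA(c_idx)) {
    stop("secondary-structure assignment needs backbone N, CA, C atoms for ",
         "every residue; keep the backbone when reducing the trajectory")
  }
  coords <- function(i) traj$xyz[, atoms2xyz(i), drop = FALSE]
  f <- nframes(traj)
  ss <- matrix("C", f, n, dimnames = list(NULL, resno))
  for (k in seq_len(n)) {
    prev_c <- if (k > 1L) c_idx[k - 1L] else NA
    next_n <- if (k < n) n_idx[k + 1L] else NA
    if (is.na(prev_c) || is.na(next_n)) next
    phi <- dihedral_frames(coords(prev_c), coords(n_idx[k]),
                           coords(ca_idx[k]), coords(c_idx[k]))
    psi <- dihedral_frames(coords(n_idx[k]), coords(ca_idx[k]),
                           coords(c_idx[k]), coords(next_n))
    helix <- phi > -100 & phi < -30 & psi > -80 & psi < -5
    strand <- phi > -180 & phi < -40 & (psi > 90 | psi < -170)
    ss[helix, k] <- "H"
    ss[strand & !helix, k] <- "E"
  }
  ss
}

# vectorised dihedral over frames; p* are F x 3 matrices
dihedral_frames <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  m1 <- cross(n1, b2)
  b2n <- sqrt(rowSums(b2^2))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2) / b2n
  atan2(y, x) * 180 / pi
}

#' Residues stably folded as secondary structure across several trajectories
#'
#' Returns the residues that are assigned helix or strand in at least
#' `stability_fraction` of the frames of every input trajectory. This is the
#' shared rigid frame used to align structurally distinct states (e.g. the
#' four catalytic states of a motor domain) before averaging.
#'
#' @param trajs a `kin_trajectory` or list of them.
#' @param stability_fraction fraction of frames (default 0.75) a residue must
#'   spend in helix/strand, in every trajectory, to qualify.
#' @return a `kin_selection` over the qualifying residues (backbone atoms).
#' @export
stable_ss_mask <- function(trajs, stability_fraction = 0.75) {
  if (inherits(trajs, "kin_trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1L,
            stability_fraction > 0, stability_fraction <= 1)
  stable <- NULL
  for (tr in trajs) {
    ss <- assign_ss(tr)
    frac <- colMeans(ss == "H" | ss == "E")
    keep <- as.integer(colnames(ss))[frac >= stability_fraction]
    stable <- if (is.null(stable)) keep else intersect(stable, keep)
  }
  if (!length(stable)) {
    stop("no residue is stably structured in every trajectory at fraction ",
         stability_fraction)
  }
  sel_spec(sort(stable), atoms = "backbone")
}
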