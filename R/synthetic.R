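#' Synthetic trajectories with known statistical ground truth
#'
#' Microsecond-scale MD of a motor domain is far beyond what a test suite can
#' run, so every analysis stage in this package is validated against
#' generated trajectories whose correlation structure, distance fluctuations
#' and state populations are known exactly. Two generators are provided:
#' stationary Gaussian fluctuation of alpha carbons around a reference with a
#' user-specified covariance ([make_harmonic_trajectory()]), and a two-state
#' flexible loop on a near-rigid scaffold emulating docked/undocked loop
#' alternation ([make_two_state_trajectory()]).
#'
#' @name synthetic
NULL

# -- topology builders --------------------------------------------------------

#' Build an alpha-carbon-only chain topology
#'
#' @param n number of residues.
#' @param shape `"helix"` places residues on a regular helical curve (3-D,
#'   generic globular-like spacing); `"line"` places them collinearly along x
#'   with a fixed gap (the geometry required by the collinear
#'   distance-fluctuation closed form).
#' @param spacing gap in Angstrom between consecutive residues for
#'   `shape = "line"`.
#' @return a `kin_structure` with one CA atom per residue.
#' @export
make_ca_topology <- function(n, shape = c("helix", "line"), spacing = 40) {
  shape <- match.arg(shape)
  if (shape == "line") {
    coords <- cbind(seq_len(n) * spacing, 0, 0)
  } else {
    t <- seq_len(n) * 100 * pi / 180
    coords <- cbind(2.3 * cos(t), 2.3 * sin(t), seq_len(n) * 1.5)
  }
  kin_structure(data.frame(
    elety = "CA", elesy = "C", resno = seq_len(n), resid = "ALA",
    chain = "A", x = coords[, 1], y = coords[, 2], z = coords[, 3],
    stringsAsFactors = FALSE), source = paste0("synthetic CA ", shape))
}

place_atom <- function(a, b, c, r, theta, chi) {
  # NeRF internal-to-Cartesian placement of atom D bonded to c,
  # with angle b-c-D = theta and dihedral a-b-c-D = chi (degrees)
  theta <- theta * pi / 180; chi <- -chi * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- r * c(-cos(theta), sin(theta) * cos(chi), sin(theta) * sin(chi))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build an ideal-geometry backbone chain at fixed dihedrals
#'
#' Generates N, CA, C, O atoms per residue with canonical bond lengths and
#' angles, placing every residue at the same (phi, psi). The default
#' (-57, -47) is an ideal alpha helix; (-120, 130) gives an extended strand.
#' Used to exercise backbone-dependent stages (secondary-structure masks,
#' the loop-clustering protocol) with geometry whose dihedrals are known.
#'
#' @param n residues.
#' @param phi,psi backbone dihedrals in degrees (recycled over residues, so a
#'   per-residue vector can mix helical and coil stretches).
#' @return a `kin_structure` with 4 backbone atoms per residue.
#' @export
make_backbone_topology <- function(n, phi = -57, psi = -47) {
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  coords <- matrix(NA_real_, 4L * n, 3L)
  rownames(coords) <- NULL
  idx <- function(i, a) (i - 1L) * 4L + match(a, c("N", "CA", "C", "O"))
  coords[idx(1, "N"), ] <- c(0, 0, 0)
  coords[idx(1, "CA"), ] <- c(1.458, 0, 0)
  th <- 111.2 * pi / 180
  coords[idx(1, "C"), ] <- coords[idx(1, "CA"), ] +
    1.525 * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)) {
    Ni <- coords[idx(i, "N"), ]; CAi <- coords[idx(i, "CA"), ]
    Ci <- coords[idx(i, "C"), ]
    coords[idx(i, "O"), ] <- place_atom(Ni, CAi, Ci, 1.231, 120.8,
                                        psi[i] - 180)
    if (i == n) break
    Nn <- place_atom(Ni, CAi, Ci, 1.329, 116.2, psi[i])
    coords[idx(i + 1, "N"), ] <- Nn
    CAn <- place_atom(CAi, Ci, Nn, 1.458, 121.7, 180)     # omega trans
    coords[idx(i + 1, "CA"), ] <- CAn
    coords[idx(i + 1, "C"), ] <- place_atom(Ci, Nn, CAn, 1.525, 111.2,
                                            phi[i + 1])
  }
  kin_structure(data.frame(
    elety = rep(c("N", "CA", "C", "O"), n),
    elesy = rep(c("N", "C", "C", "O"), n),
    resno = rep(seq_len(n), each = 4L), resid = "ALA", chain = "A",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    stringsAsFactors = FALSE), source = "synthetic backbone")
}

# -- harmonic (Gaussian) generator --------------------------------------------

#' Specify a Gaussian fluctuation model around a reference
#'
#' Frames drawn from this specification are independent Gaussian
#' displacements of the reference coordinates with the requested covariance,
#' so the dynamic cross-correlation matrix and (in the collinear limit) the
#' distance-fluctuation matrix are known in closed form.
#'
#' @param ref reference coordinates: a `kin_structure` (its atoms are taken
#'   as the fluctuating particles, typically one CA per residue) or an N x 3
#'   matrix.
#' @param cov displacement covariance in Angstrom^2, one of: a scalar
#'   (isotropic, identical residues), a length-N vector (isotropic,
#'   per-residue), an N x N matrix (applied independently to each active
#'   axis), or a full 3N x 3N matrix (xyz-interleaved atom blocks).
#' @param seed integer seed governing all draws.
#' @param axes axes the N x N covariance acts on (default all three);
#'   inactive axes are rigid. Ignored for 3N x 3N input.
#' @return object of class `harmonic_spec`.
#' @export
harmonic_spec <- function(ref, cov, seed = 1L, axes = c("x", "y", "z")) {
  if (inherits(ref, "kin_structure")) {
    top <- ref
    refmat <- as.matrix(ref$atoms[, c("x", "y", "z")])
  } else {
    refmat <- as.matrix(ref)
    stopifnot(ncol(refmat) == 3L)
    top <- kin_structure(data.frame(
      elety = "CA", elesy = "C", resno = seq_len(nrow(refmat)),
      resid = "ALA", chain = "A",
      x = refmat[, 1], y = refmat[, 2], z = refmat[, 3],
      stringsAsFactors = FALSE), source = "synthetic CA")
  }
  n <- nrow(refmat)
  stopifnot(all(is.finite(refmat)))
  axes <- match.arg(axes, c("x", "y", "z"), several.ok = TRUE)

  if (is.matrix(cov) && nrow(cov) == 3L * n && n > 1L) {
    mode <- "full"
    sigma <- cov
  } else if (is.matrix(cov)) {
    stopifnot(nrow(cov) == n, ncol(cov) == n)
    mode <- "per_axis"
    sigma <- cov
  } else if (length(cov) == 1L) {
    mode <- "per_axis"
    sigma <- diag(rep(as.numeric(cov), n), n)
  } else {
    stopifnot(length(cov) == n)
    mode <- "per_axis"
    sigma <- diag(as.numeric(cov), n)
  }
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma)))) {
    stop("covariance must be symmetric")
  }
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(1, max(abs(ev$values)))) {
    stop("covariance is not positive semi-definite (min eigenvalue ",
         signif(min(ev$values), 3), ")")
  }
  vals <- pmax(ev$values, 0)
  factor <- ev$vectors %*% diag(sqrt(vals), length(vals))
  structure(list(top = top, ref = refmat, sigma = sigma, mode = mode,
                 axes = axes, factor = factor, seed = as.integer(seed)),
            class = "harmonic_spec")
}

draw_gaussian <- function(spec, n_frames) {
  n <- nrow(spec$ref)
  disp <- matrix(0, n_frames, 3L * n)
  if (spec$mode == "full") {
    z <- matrix(stats::rnorm(n_frames * 3L * n), n_frames)
    disp <- z %*% t(spec$factor)
  } else {
    for (ax in spec$axes) {
      k <- match(ax, c("x", "y", "z"))
      z <- matrix(stats::rnorm(n_frames * n), n_frames)
      disp[, seq(k, 3L * n, by = 3L)] <- z %*% t(spec$factor)
    }
  }
  disp
}

#' Sample a trajectory from a Gaussian fluctuation model
#'
#' Frames are independent draws by default: the distance-fluctuation,
#' correlation and shortest-path statistics this package computes are
#' functionals of the marginal displacement distribution only, so temporal
#' correlation would change convergence rates but not expectations. An
#' optional AR(1) mixing coefficient is available for realism; it preserves
#' the stationary covariance.
#'
#' @param spec a [harmonic_spec()].
#' @param n_frames frames per replica.
#' @param n_replicas independent replicas to concatenate; each replica uses
#'   seed `spec$seed + replica - 1`, mirroring independently seeded MD runs.
#' @param ar1 lag-1 autocorrelation coefficient in [0, 1).
#' @return a `kin_trajectory` with replica bounds at replica starts.
#' @export
make_harmonic_trajectory <- function(spec, n_frames, n_replicas = 1L,
                                     ar1 = 0) {
  stopifnot(inherits(spec, "harmonic_spec"), n_frames >= 1L,
            ar1 >= 0, ar1 < 1)
  refvec <- mat2xyz(spec$ref)
  blocks <- vector("list", n_replicas)
  for (r in seq_len(n_replicas)) {
    disp <- with_seed(spec$seed + r - 1L, draw_gaussian(spec, n_frames))
    if (ar1 > 0 && n_frames > 1L) {
      w <- sqrt(1 - ar1^2)
      for (t in 2:n_frames) {
        disp[t, ] <- ar1 * disp[t - 1L, ] + w * disp[t, ]
      }
    }
    blocks[[r]] <- sweep(disp, 2L, refvec, "+")
  }
  bounds <- 1L + (seq_len(n_replicas) - 1L) * n_frames
  kin_trajectory(spec$top, do.call(rbind, blocks), replica_bounds = bounds)
}

#' Exact dynamic cross-correlation of a Gaussian fluctuation model
#'
#' Evaluates the expectation form of the normalised displacement correlation
#' \eqn{C_{ij} = \langle \Delta r_i \cdot \Delta r_j \rangle /
#' \sqrt{\langle \Delta r_i^2 \rangle \langle \Delta r_j^2 \rangle}}
#' directly from the specified covariance (no sampling): the numerator is the
#' trace of the 3 x 3 cross-covariance block of atoms i and j.
#'
#' @param spec a [harmonic_spec()].
#' @return a `kin_cormat` (see [correlation_matrix()]); residues with zero
#'   total displacement get zero off-diagonal entries and are flagged.
#' @export
ground_truth_correlation <- function(spec) {
  stopifnot(inherits(spec, "harmonic_spec"))
  n <- nrow(spec$ref)
  if (spec$mode == "full") {
    m <- matrix(0, n, n)
    for (k in 1:3) {
      idx <- seq(k, 3L * n, by = 3L)
      m <- m + spec$sigma[idx, idx]
    }
  } else {
    m <- length(spec$axes) * spec$sigma
  }
  v <- diag(m)
  rigid <- v <= 0
  denom <- sqrt(outer(pmax(v, 1e-300), pmax(v, 1e-300)))
  cc <- m / denom
  cc[rigid, ] <- 0; cc[, rigid] <- 0
  diag(cc) <- 1
  new_cormat(cc, spec$top$atoms$resno, reference = "analytic",
             rigid = which(rigid))
}

# -- two-state loop generator -------------------------------------------------

#' Specify a two-state flexible loop on a near-rigid scaffold
#'
#' Emulates a loop alternating between discrete conformational states (the
#' docked/undocked regimes of kinesin-5 loop 5) while the rest of the domain
#' fluctuates weakly: each frame picks loop conformation A or B with fixed
#' probabilities and adds isotropic Gaussian noise per coordinate.
#'
#' @param top topology (`kin_structure`); scaffold coordinates are taken from
#'   it.
#' @param loop_sel selection defining the mobile loop atoms.
#' @param conf_a,conf_b loop coordinates (n_loop_atoms x 3) for the two
#'   states; `conf_a` defaults to the topology coordinates of the loop.
#' @param p_a probability of state A (strictly between 0 and 1 unless exactly
#'   0 or 1 for degenerate single-state tests).
#' @param sigma within-state isotropic noise s.d. per coordinate on the loop,
#'   Angstrom.
#' @param scaffold_sigma noise s.d. on non-loop atoms (near-rigid scaffold).
#' @param seed integer seed.
#' @return object of class `two_state_spec`; `$overlap` flags specifications
#'   whose noise exceeds half the A-B RMSD (states not cleanly separable).
#' @export
two_state_spec <- function(top, loop_sel, conf_a = NULL, conf_b,
                           p_a = 0.5, sigma = 0.5, scaffold_sigma = 0.05,
                           seed = 1L) {
  stopifnot(inherits(top, "kin_structure"), p_a >= 0, p_a <= 1, sigma >= 0)
  inds <- resolve_selection(top, loop_sel)
  if (is.null(conf_a)) {
    conf_a <- as.matrix(top$atoms[inds, c("x", "y", "z")])
  }
  conf_a <- as.matrix(conf_a); conf_b <- as.matrix(conf_b)
  if (!all(dim(conf_a) == c(length(inds), 3L)) ||
      !all(dim(conf_b) == c(length(inds), 3L))) {
    stop("loop conformations must be n_loop_atoms x 3 matrices (",
         length(inds), " loop atoms selected)")
  }
  ab_rmsd <- sqrt(mean(rowSums((conf_a - conf_b)^2)))
  structure(list(top = top, loop_inds = inds, conf_a = conf_a,
                 conf_b = conf_b, p_a = p_a, sigma = sigma,
                 scaffold_sigma = scaffold_sigma, seed = as.integer(seed),
                 ab_rmsd = ab_rmsd, overlap = sigma > ab_rmsd / 2),
            class = "two_state_spec")
}

#' Sample a two-state loop trajectory with known frame labels
#'
#' @param spec a [two_state_spec()].
#' @param n_frames number of frames (>= 2).
#' @return list with elements `traj` (`kin_trajectory`), `labels` (character
#'   "A"/"B" per frame, the ground truth for clustering-recovery tests) and
#'   `spec`.
#' @export
make_two_state_trajectory <- function(spec, n_frames) {
  stopifnot(inherits(spec, "two_state_spec"), n_frames >= 2L)
  n_at <- natoms(spec$top)
  refvec <- mat2xyz(as.matrix(spec$top$atoms[, c("x", "y", "z")]))
  loop_cols <- atoms2xyz(spec$loop_inds)
  a_vec <- mat2xyz(spec$conf_a); b_vec <- mat2xyz(spec$conf_b)
  out <- with_seed(spec$seed, {
    labels <- ifelse(stats::runif(n_frames) < spec$p_a, "A", "B")
    xyz <- matrix(refvec, n_frames, 3L * n_at, byrow = TRUE)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = spec$scaffold_sigma),
                        n_frames)
    base <- matrix(0, n_frames, length(loop_cols))
    if (any(labels == "A")) {
      base[labels == "A", ] <- matrix(a_vec, sum(labels == "A"),
                                      length(loop_cols), byrow = TRUE)
    }
    if (any(labels == "B")) {
      base[labels == "B", ] <- matrix(b_vec, sum(labels == "B"),
                                      length(loop_cols), byrow = TRUE)
    }
    xyz[, loop_cols] <- base +
      matrix(stats::rnorm(length(base), sd = spec$sigma), n_frames)
    list(xyz = xyz, labels = labels)
  })
  list(traj = kin_trajectory(spec$top, out$xyz), labels = out$labels,
       spec = spec)
}

# -- collinear closed form ----------------------------------------------------

#' Closed-form distance-fluctuation matrix for collinear Gaussians
#'
#' For particles constrained to a line whose separations are large compared
#' with their fluctuations (ordering preserved), the inter-particle distance
#' is simply \eqn{x_j - x_i}, so the distance fluctuation has the exact form
#' \eqn{DF_{ij} = Var(x_j - x_i) = \sigma_i^2 + \sigma_j^2 - 2 cov_{ij}}.
#' This is the independent oracle the sampled estimator is validated against.
#'
#' @param positions per-residue mean positions on the line (Angstrom).
#' @param variances per-residue displacement variances (Angstrom^2).
#' @param covariances N x N covariance matrix (its diagonal must equal
#'   `variances`), or `NULL` for independent residues.
#' @return a `kin_df` matrix object (see [compute_df()]).
#' @export
collinear_df_closed_form <- function(positions, variances,
                                     covariances = NULL) {
  n <- length(positions)
  stopifnot(length(variances) == n, all(variances >= 0))
  if (is.null(covariances)) covariances <- diag(variances, n)
  stopifnot(all(dim(covariances) == n))
  if (max(abs(diag(covariances) - variances)) > 1e-8) {
    stop("diagonal of covariance matrix must equal the variances")
  }
  gap <- min(diff(sort(positions)))
  if (gap <= 6 * sqrt(max(variances))) {
    stop("separations too small relative to fluctuations (min gap ",
         signif(gap, 3), " A <= 6 max sd): particle ordering is not ",
         "preserved and the collinear closed form does not apply")
  }
  df <- outer(variances, variances, "+") - 2 * covariances
  df[df < 0] <- 0
  diag(df) <- 0
  new_df(df, seq_len(n), state = "collinear closed form", n_frames = NA_integer_,
         mode = "analytic")
}
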