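#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generators do not
#' perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Convert atom indices to xyz vector indices
#' @param inds atom indices (1-based).
#' @return indices into a flat (x1,y1,z1,x2,...) coordinate vector.
#' @keywords internal
atoms2xyz <- function(inds) {
  as.vector(rbind(3L * inds - 2L, 3L * inds - 1L, 3L * inds))
}

#' Reshape a flat coordinate vector to an N x 3 matrix
#' @keywords internal
xyz2mat <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

#' Flatten an N x 3 coordinate matrix to bio3d xyz order
#' @keywords internal
mat2xyz <- function(m) as.vector(t(m))

#' Fast all-pairs RMSD between trajectory frames
#'
#' Computes the F x F matrix of root-mean-square deviations between frames of
#' a coordinate matrix (rows = frames, columns = flat xyz), without any
#' per-pair refitting. Uses the Gram-matrix identity
#' \eqn{\|x_i-x_j\|^2 = \|x_i\|^2 + \|x_j\|^2 - 2 x_i \cdot x_j}, which is
#' considerably faster than looping over pairs for thousands of frames.
#'
#' @param X numeric matrix, frames by 3*atoms.
#' @return symmetric F x F matrix of RMSD values in Angstrom.
#' @keywords internal
pairwise_rmsd <- function(X) {
  stopifnot(is.matrix(X), ncol(X) %% 3 == 0)
  natoms <- ncol(X) / 3L
  g <- tcrossprod(X)
  sq <- diag(g)
  d2 <- outer(sq, sq, "+") - 2 * g
  d2[d2 < 0] <- 0          # numerical negatives from cancellation
  diag(d2) <- 0
  sqrt(d2 / natoms)
}

#' Dihedral angle of four points
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors.
#' @return angle in degrees in (-180, 180].
#' @keywords internal
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  b2n <- sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / b2n
  atan2(y, x) * 180 / pi
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Closed-form least-squares superposition of frames onto a reference
#'
#' For every row (frame) of `X`, finds the proper rotation and translation
#' minimising the RMSD of the fit atoms to the reference (Kabsch SVD
#' solution, reflection-corrected) and applies it to the whole frame.
#'
#' @param X frames-by-3N coordinate matrix.
#' @param ref flat reference coordinates, length 3N.
#' @param fit_cols coordinate-column indices used for the fit.
#' @return transformed coordinate matrix, same shape as `X`.
#' @keywords internal
kabsch_fit <- function(X, ref, fit_cols) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  b <- xyz2mat(ref[fit_cols])
  bc <- colMeans(b)
  b0 <- sweep(b, 2L, bc)
  m <- nrow(b0)
  out <- X
  n_all <- ncol(X) / 3L
  for (f in seq_len(nrow(X))) {
    a <- matrix(X[f, fit_cols], ncol = 3L, byrow = TRUE)
    ac <- colMeans(a)
    h <- crossprod(sweep(a, 2L, ac), b0)
    sv <- svd(h)
    d <- sign(det(tcrossprod(sv$v, sv$u)))
    rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    frame <- matrix(X[f, ], ncol = 3L, byrow = TRUE)
    moved <- sweep(frame, 2L, ac) %*% t(rot)
    out[f, ] <- as.vector(t(sweep(moved, 2L, bc, "+")))
  }
  out
}
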