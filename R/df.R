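#' Distance-fluctuation matrices
#'
#' The distance fluctuation of a residue pair is the variance of their
#' alpha-carbon distance over a trajectory,
#' \eqn{DF_{ij} = \langle (d_{ij} - \langle d_{ij} \rangle)^2 \rangle}.
#' Because inter-atomic distances are invariant to rigid-body motion, no
#' fitting or realignment is required; the trajectory is only stripped to one
#' atom per residue. Low values flag pairs that move in a coordinated,
#' allosterically coupled way.
#'
#' @name distance-fluctuation
NULL

new_df <- function(scores, resno, state, n_frames, mode,
                   estimator = "population") {
  dimnames(scores) <- list(resno, resno)
  structure(list(scores = scores, resno = as.integer(resno), state = state,
                 n_frames = n_frames, mode = mode, estimator = estimator),
            class = "kin_df")
}

#' @export
print.kin_df <- function(x, ...) {
  cat("<kin_df> ", length(x$resno), " residues, state '", x$state,
      "', ", x$mode, " over ", x$n_frames, " frames\n", sep = "")
  invisible(x)
}

# mean and variance of all pairwise distances, vectorised over frames
pair_distance_moments <- function(xyz, n) {
  f <- nrow(xyz)
  xs <- xyz[, seq(1L, 3L * n, 3L), drop = FALSE]
  ys <- xyz[, seq(2L, 3L * n, 3L), drop = FALSE]
  zs <- xyz[, seq(3L, 3L * n, 3L), drop = FALSE]
  m1 <- matrix(0, n, n); m2 <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    d <- sqrt((xs[, j, drop = FALSE] - xs[, i])^2 +
              (ys[, j, drop = FALSE] - ys[, i])^2 +
              (zs[, j, drop = FALSE] - zs[, i])^2)
    m1[i, j] <- colMeans(d)
    m2[i, j] <- colMeans(d * d)
  }
  m1 <- m1 + t(m1); m2 <- m2 + t(m2)
  list(mean = m1, meansq = m2)
}

#' Compute the distance-fluctuation matrix of a trajectory
#'
#' @param traj a `kin_trajectory`.
#' @param sel selection yielding exactly one atom per residue (default all
#'   alpha carbons).
#' @param replica_mode `"pooled"` computes the variance over the concatenated
#'   metatrajectory; `"per_replica_mean"` averages the per-replica variance
#'   matrices. Pooled additionally captures between-replica differences in
#'   mean distance (law of total variance), so pooled >= per-replica mean
#'   entrywise.
#' @param estimator `"population"` divides by F, matching the expectation
#'   form of the definition; `"sample"` divides by F - 1.
#' @param state label stored in the result (e.g. `"ATP"`, `"ADP"`).
#' @return a `kin_df` with `$scores` in Angstrom^2.
#' @examples
#' top <- make_ca_topology(4)
#' spec <- harmonic_spec(top, cov = 0.01, seed = 7)
#' df <- compute_df(make_harmonic_trajectory(spec, 200))
#' @export
compute_df <- function(traj, sel = sel_spec(atoms = "CA"),
                       replica_mode = c("pooled", "per_replica_mean"),
                       estimator = c("population", "sample"),
                       state = "unnamed") {
  replica_mode <- match.arg(replica_mode)
  estimator <- match.arg(estimator)
  red <- reduce_trajectory(traj, sel)
  resno <- red$top$atoms$resno
  if (anyDuplicated(resno)) {
    stop("selection yields more than one atom for residue(s) ",
         paste(unique(resno[duplicated(resno)]), collapse = ", "),
         "; distance fluctuations need exactly one atom per residue")
  }
  f <- nframes(red)
  if (f < 2L) stop("at least 2 frames are required to compute a variance")
  n <- length(resno)
  bessel <- function(v, nf) if (estimator == "sample") v * nf / (nf - 1L) else v

  if (replica_mode == "pooled") {
    mom <- pair_distance_moments(red$xyz, n)
    scores <- bessel(pmax(mom$meansq - mom$mean^2, 0), f)
  } else {
    rep_id <- replica_of(red)
    mats <- lapply(split(seq_len(f), rep_id), function(rows) {
      if (length(rows) < 2L) {
        stop("replica with fewer than 2 frames: per-replica variance undefined")
      }
      mom <- pair_distance_moments(red$xyz[rows, , drop = FALSE], n)
      bessel(pmax(mom$meansq - mom$mean^2, 0), length(rows))
    })
    scores <- Reduce(`+`, mats) / length(mats)
  }
  new_df(scores, resno, state = state, n_frames = f, mode = replica_mode,
         estimator = estimator)
}

#' Difference of two distance-fluctuation matrices across a transition
#'
#' Computes end-point minus starting-point scores, following the order of the
#' catalytic cycle: positive values mean the residue pair lost coordination
#' during the transition, negative values mean it gained coordination.
#'
#' @param final `kin_df` of the transition end point.
#' @param initial `kin_df` of the starting point.
#' @return a `kin_ddf` with `$deltas` in Angstrom^2.
#' @export
delta_df <- function(final, initial) {
  stopifnot(inherits(final, "kin_df"), inherits(initial, "kin_df"))
  if (!identical(final$resno, initial$resno)) {
    stop("residue maps differ between the two matrices")
  }
  structure(list(deltas = final$scores - initial$scores,
                 resno = final$resno,
                 final = final$state, initial = initial$state),
            class = "kin_ddf")
}

#' @export
print.kin_ddf <- function(x, ...) {
  cat("<kin_ddf> ", length(x$resno), " residues: '", x$final, "' - '",
      x$initial, "'\n", sep = "")
  invisible(x)
}

#' Per-residue profile of a difference matrix
#'
#' Extracts the row of a `kin_ddf` for one residue, the form used to paint a
#' single residue's coordination change onto a structure (e.g. the profile of
#' the conserved pocket tryptophan across a transition).
#'
#' @param delta a `kin_ddf`.
#' @param residue residue sequence number.
#' @return named numeric vector of length N (names are residue numbers).
#' @export
residue_profile <- function(delta, residue) {
  stopifnot(inherits(delta, "kin_ddf"))
  i <- match(residue, delta$resno)
  if (is.na(i)) stop("residue ", residue, " not present in the matrix")
  stats::setNames(delta$deltas[i, ], delta$resno)
}

#' Aggregate a score matrix over a pair of regions
#'
#' Summarises the block of entries between two residue regions, e.g. the mean
#' distance fluctuation between a loop and the nucleotide pocket. When the
#' two regions are identical the diagonal is excluded.
#'
#' @param mat a `kin_df` or `kin_ddf`.
#' @param region_a,region_b residue numbers (integer vectors, range strings,
#'   or `kin_selection` objects).
#' @param statistic `"mean"` or `"median"`.
#' @return scalar, Angstrom^2.
#' @export
region_summary <- function(mat, region_a, region_b,
                           statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  scores <- if (inherits(mat, "kin_df")) mat$scores
            else if (inherits(mat, "kin_ddf")) mat$deltas
            else stop("mat must be a kin_df or kin_ddf")
  resno <- if (inherits(mat, "kin_df")) mat$resno else mat$resno
  as_res <- function(r) {
    if (inherits(r, "kin_selection")) r <- r$residues
    if (is.character(r)) r <- parse_ranges(r)
    r
  }
  ia <- which(resno %in% as_res(region_a))
  ib <- which(resno %in% as_res(region_b))
  if (!length(ia) || !length(ib)) stop("region resolves to no residues")
  block <- scores[ia, ib, drop = FALSE]
  if (identical(sort(ia), sort(ib))) {
    block <- block[row(block) != col(block)]
    if (!length(block)) stop("region block is empty after removing diagonal")
  }
  if (statistic == "mean") mean(block) else stats::median(block)
}

#' Write a square score matrix to a plain-text file
#'
#' Format: one header line `# residues: <id> <id> ...`, then the matrix,
#' whitespace-delimited, full double precision (round-trips bit-identically
#' through [read_score_matrix()]).
#'
#' @param mat a `kin_df`, `kin_ddf` or `kin_cormat`.
#' @param path output file.
#' @export
write_score_matrix <- function(mat, path) {
  m <- if (inherits(mat, "kin_df")) mat$scores
       else if (inherits(mat, "kin_ddf")) mat$deltas
       else if (inherits(mat, "kin_cormat")) mat$values
       else if (inherits(mat, "kin_avgdist")) mat$values
       else if (is.matrix(mat)) mat
       else stop("unsupported matrix object")
  resno <- if (is.matrix(mat)) seq_len(nrow(mat)) else mat$resno
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# residues:", paste(resno, collapse = " ")), con)
  utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                     con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a square score matrix written by [write_score_matrix()]
#'
#' @param path file path.
#' @return list with `values` (matrix) and `resno` (integer vector).
#' @export
read_score_matrix <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("^# residues:", header)) {
    stop("not a score-matrix file (missing '# residues:' header): ", path)
  }
  resno <- as.integer(strsplit(sub("^# residues:\\s*", "", header),
                               "\\s+")[[1]])
  m <- as.matrix(utils::read.table(path, skip = 1L))
  dimnames(m) <- list(resno, resno)
  if (nrow(m) != length(resno) || ncol(m) != length(resno)) {
    stop("matrix dimensions do not match the residue header in ", path)
  }
  list(values = m, resno = resno)
}
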