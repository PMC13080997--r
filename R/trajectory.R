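#' Construct a trajectory
#'
#' @param top topology, a `kin_structure`.
#' @param xyz coordinate matrix, one row per frame, columns in
#'   (x1, y1, z1, x2, ...) order, Angstrom.
#' @param replica_bounds 1-based frame indices at which independent replicas
#'   start; first element must be 1. Defaults to a single replica.
#' @return object of class `kin_trajectory`.
#' @export
kin_trajectory <- function(top, xyz, replica_bounds = 1L) {
  stopifnot(inherits(top, "kin_structure"))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (ncol(xyz) != 3L * natoms(top)) {
    stop("coordinate width ", ncol(xyz), " does not match topology (",
         3L * natoms(top), " expected)")
  }
  if (!all(is.finite(xyz))) stop("non-finite coordinates in trajectory")
  replica_bounds <- as.integer(replica_bounds)
  if (replica_bounds[1] != 1L || is.unsorted(replica_bounds, strictly = TRUE) ||
      any(replica_bounds > nrow(xyz))) {
    stop("replica_bounds must be strictly increasing 1-based frame indices ",
         "starting at 1 and not exceeding the frame count")
  }
  structure(list(top = top, xyz = xyz, replica_bounds = replica_bounds),
            class = "kin_trajectory")
}

#' @export
print.kin_trajectory <- function(x, ...) {
  cat("<kin_trajectory> ", nframes(x), " frames, ", natoms(x), " atoms, ",
      length(x$replica_bounds), " replica(s)\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `kin_trajectory`.
#' @export
nframes <- function(traj) nrow(traj$xyz)

#' Extract one frame as a flat coordinate vector
#' @param traj a `kin_trajectory`.
#' @param i frame index.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1L, i <= nframes(traj))
  traj$xyz[i, ]
}

#' Replica id of every frame
#' @param traj a `kin_trajectory`.
#' @return integer vector of length `nframes(traj)`.
#' @export
replica_of <- function(traj) {
  bounds <- c(traj$replica_bounds, nframes(traj) + 1L)
  rep(seq_along(traj$replica_bounds), diff(bounds))
}

trajectory_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pdb = "pdb", dcd = "dcd", nc = "ncdf", ncdf = "ncdf", netcdf = "ncdf",
         stop("unsupported trajectory format '", ext, "' for ", path,
              " (supported: multi-model PDB, DCD, Amber NetCDF)"))
}

read_traj_xyz <- function(path) {
  switch(trajectory_format(path),
    pdb = bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)$xyz,
    dcd = bio3d::read.dcd(path, verbose = FALSE),
    ncdf = {
      if (!requireNamespace("ncdf4", quietly = TRUE)) {
        stop("reading Amber NetCDF requires the ncdf4 package")
      }
      bio3d::read.ncdf(path)
    })
}

#' Load and concatenate trajectory files into a metatrajectory
#'
#' Frames are concatenated in the order the paths are given; each file is
#' recorded as one replica, so pooling several independent runs yields a
#' metatrajectory whose replica boundaries remain available to downstream
#' statistics (e.g. per-replica distance-fluctuation averaging).
#'
#' @param top topology (`kin_structure`) the frames must match.
#' @param paths character vector of trajectory files (multi-model PDB, DCD,
#'   or Amber NetCDF, chosen by extension).
#' @param check_jumps validate that consecutive frames within a replica show
#'   no alpha-carbon displacement above `max_jump` (a symptom of periodic
#'   imaging artifacts); trajectories are assumed pre-imaged.
#' @param max_jump threshold in Angstrom for the jump check.
#' @return a `kin_trajectory` with `replica_bounds` set at file boundaries.
#' @export
load_trajectory <- function(top, paths, check_jumps = TRUE, max_jump = 20) {
  stopifnot(inherits(top, "kin_structure"), length(paths) >= 1L)
  blocks <- vector("list", length(paths))
  for (k in seq_along(paths)) {
    x <- read_traj_xyz(paths[k])
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
    if (ncol(x) != 3L * natoms(top)) {
      stop("atom count mismatch in ", paths[k], ": file has ", ncol(x) / 3,
           " atoms, topology has ", natoms(top))
    }
    blocks[[k]] <- x
  }
  nf <- vapply(blocks, nrow, integer(1))
  bounds <- cumsum(c(1L, nf[-length(nf)]))
  traj <- kin_trajectory(top, do.call(rbind, blocks), replica_bounds = bounds)
  if (check_jumps) validate_imaging(traj, max_jump = max_jump)
  traj
}

#' Check a trajectory for periodic-imaging artifacts
#'
#' Errors when any alpha-carbon moves more than `max_jump` Angstrom between
#' consecutive frames of the same replica. Such jumps almost always mean the
#' molecule was wrapped across a periodic boundary; re-imaging is
#' engine-specific and must be done upstream.
#'
#' @param traj a `kin_trajectory`.
#' @param max_jump threshold in Angstrom.
#' @return invisibly `TRUE` when clean.
#' @export
validate_imaging <- function(traj, max_jump = 20) {
  ca <- tryCatch(resolve_selection(traj$top, sel_spec(atoms = "CA")),
                 error = function(e) integer(0))
  if (length(ca) == 0L || nframes(traj) < 2L) return(invisible(TRUE))
  cols <- atoms2xyz(ca)
  rep_id <- replica_of(traj)
  d <- traj$xyz[-1L, cols, drop = FALSE] -
       traj$xyz[-nframes(traj), cols, drop = FALSE]
  same <- rep_id[-1L] == rep_id[-nframes(traj)]
  if (!any(same)) return(invisible(TRUE))
  d2 <- d[same, , drop = FALSE]^2
  k <- seq(1L, ncol(d2), by = 3L)
  jump2 <- d2[, k, drop = FALSE] + d2[, k + 1L, drop = FALSE] +
           d2[, k + 2L, drop = FALSE]
  worst <- sqrt(max(jump2))
  if (worst > max_jump) {
    stop("frame-to-frame alpha-carbon jump of ", round(worst, 1),
         " A exceeds ", max_jump,
         " A; trajectory looks periodically wrapped - re-image it upstream")
  }
  invisible(TRUE)
}

#' Write a trajectory to file
#'
#' @param traj a `kin_trajectory`.
#' @param path output file; format chosen by extension (`.pdb` multi-model
#'   PDB, `.nc` Amber NetCDF).
#' @export
write_trajectory <- function(traj, path) {
  fmt <- trajectory_format(path)
  at <- traj$top$atoms
  if (fmt == "pdb") {
    bio3d::write.pdb(file = path, xyz = traj$xyz,
                     type = ifelse(at$het, "HETATM", "ATOM"),
                     resno = at$resno, resid = at$resid, eleno = at$eleno,
                     elety = at$elety, chain = at$chain, o = at$o,
                     elesy = at$elesy)
  } else if (fmt == "ncdf") {
    if (!requireNamespace("ncdf4", quietly = TRUE)) {
      stop("writing Amber NetCDF requires the ncdf4 package")
    }
    bio3d::write.ncdf(traj$xyz, trjfile = path)
  } else {
    stop("writing format '", fmt, "' is not supported")
  }
  invisible(path)
}

#' Restrict a trajectory to a selection
#'
#' Returns a new trajectory containing only the selected atoms in every
#' frame; the residue mapping is retained in the reduced topology.
#'
#' @param traj a `kin_trajectory`.
#' @param sel a `kin_selection`.
#' @return reduced `kin_trajectory`.
#' @export
reduce_trajectory <- function(traj, sel) {
  inds <- resolve_selection(traj$top, sel)
  at <- traj$top$atoms[inds, , drop = FALSE]
  top <- kin_structure(at, source = paste0(traj$top$source, " (reduced)"))
  kin_trajectory(top, traj$xyz[, atoms2xyz(inds), drop = FALSE],
                 replica_bounds = traj$replica_bounds)
}

#' Least-squares superposition of all frames onto a reference
#'
#' Each frame is rigid-body transformed (closed-form least-squares rotation
#' plus translation) to minimise the RMSD of the fit selection to the
#' reference; the transform is applied to all atoms of the frame.
#'
#' @param traj a `kin_trajectory`.
#' @param reference frame index into `traj`, or a flat coordinate vector of
#'   the same width as a frame.
#' @param fit_sel selection used for the fit (default: all alpha carbons).
#' @return superposed `kin_trajectory`.
#' @export
superpose_trajectory <- function(traj, reference = 1L,
                                 fit_sel = sel_spec(atoms = "CA")) {
  if (length(reference) == 1L) reference <- get_frame(traj, reference)
  stopifnot(length(reference) == ncol(traj$xyz))
  inds <- resolve_selection(traj$top, fit_sel)
  if (length(inds) < 3L) stop("superposition needs at least 3 fit atoms")
  cols <- atoms2xyz(inds)
  fitted <- kabsch_fit(traj$xyz, reference, cols)
  kin_trajectory(traj$top, fitted, replica_bounds = traj$replica_bounds)
}

#' RMSD between two structures or coordinate sets
#'
#' Atoms are paired by residue sequence number plus atom name over the
#' residues resolved in both inputs (chain-agnostic), so structures with
#' different gaps or chains can be compared directly.
#'
#' @param a,b `kin_structure` objects.
#' @param sel selection applied to both sides (default alpha carbons).
#' @param fit superpose `b` onto `a` (least squares) before measuring.
#' @return RMSD in Angstrom.
#' @examples
#' # identical structures have zero RMSD irrespective of fitting
#' @export
rmsd_structures <- function(a, b, sel = sel_spec(atoms = "CA"), fit = TRUE) {
  stopifnot(inherits(a, "kin_structure"), inherits(b, "kin_structure"))
  ia <- resolve_selection(a, sel)
  ib <- resolve_selection(b, sel)
  key_a <- paste(a$atoms$resno[ia], a$atoms$elety[ia])
  key_b <- paste(b$atoms$resno[ib], b$atoms$elety[ib])
  common <- intersect(key_a, key_b)
  if (length(common) == 0L) stop("no common atoms under the given selection")
  ia <- ia[match(common, key_a)]
  ib <- ib[match(common, key_b)]
  va <- mat2xyz(as.matrix(a$atoms[ia, c("x", "y", "z")]))
  vb <- mat2xyz(as.matrix(b$atoms[ib, c("x", "y", "z")]))
  rmsd_xyz(va, vb, fit = fit)
}

#' RMSD between two flat coordinate vectors
#'
#' @param va,vb flat xyz vectors of equal length.
#' @param fit least-squares superpose `vb` onto `va` first.
#' @return RMSD in Angstrom.
#' @export
rmsd_xyz <- function(va, vb, fit = FALSE) {
  stopifnot(length(va) == length(vb), length(va) %% 3 == 0)
  if (fit) {
    as.numeric(bio3d::rmsd(va, vb, fit = TRUE))
  } else {
    sqrt(mean(rowSums((xyz2mat(va) - xyz2mat(vb))^2)))
  }
}

#' Mean structure of a trajectory
#'
#' Per-atom arithmetic mean of coordinates over frames, optionally after
#' superposing frames on a fit selection (recommended unless the trajectory
#' is already aligned).
#'
#' @param traj a `kin_trajectory`.
#' @param fit_sel selection for prior superposition, or `NULL` to average the
#'   frames as they are.
#' @return flat coordinate vector of the average structure.
#' @export
average_structure <- function(traj, fit_sel = NULL) {
  if (nframes(traj) < 1L) stop("empty trajectory")
  if (!is.null(fit_sel)) traj <- superpose_trajectory(traj, 1L, fit_sel)
  colMeans(traj$xyz)
}
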