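#' Geometric noncovalent-interaction metrics
#'
#' Per-frame time series of simple geometric criteria — aromatic stacking,
#' salt bridges, hydrogen bonds — summarised as occupancies (the fraction of
#' frames satisfying the criterion), plus radial distribution functions and
#' 3-D occupancy densities for ligand-pocket analyses. All thresholds are
#' explicit parameters and are recorded in the returned objects.
#'
#' @name interactions
NULL

new_series <- function(values, criterion, satisfied, flagged = NULL) {
  if (is.null(flagged)) flagged <- rep(FALSE, length(satisfied))
  denom <- sum(!flagged)
  occupancy <- if (denom > 0) sum(satisfied & !flagged) / denom else NA_real_
  structure(list(values = values, criterion = criterion,
                 satisfied = satisfied, flagged = flagged,
                 occupancy = occupancy),
            class = "kin_series")
}

#' @export
print.kin_series <- function(x, ...) {
  cat("<kin_series> ", length(x$satisfied), " frames, occupancy ",
      sprintf("%.3f", x$occupancy), " (", x$criterion$label, ")\n", sep = "")
  invisible(x)
}

frame_coords <- function(traj, inds) {
  cols <- atoms2xyz(inds)
  function(f) xyz2mat(traj$xyz[f, cols])
}

#' Aromatic ring stacking time series
#'
#' Per frame, the centroid-centroid distance of two rings and the angle
#' between their best-fit plane normals; the pair counts as stacked when the
#' distance is at most `d_max` and the acute inter-plane angle at most
#' `theta_max` (defaults 5.5 Angstrom, 30 degrees: face-to-face geometry;
#' T-shaped contacts are excluded by design).
#'
#' @param traj a `kin_trajectory`.
#' @param ring_a,ring_b selections of the ring heavy atoms (at least 5 atoms
#'   each).
#' @param d_max,theta_max stacking criterion parameters.
#' @return a `kin_series` with per-frame columns `distance` and `angle`.
#'   Frames with degenerate (collinear) ring geometry are flagged and
#'   excluded from the occupancy denominator.
#' @export
pi_stack_series <- function(traj, ring_a, ring_b, d_max = 5.5,
                            theta_max = 30) {
  ia <- resolve_selection(traj$top, ring_a)
  ib <- resolve_selection(traj$top, ring_b)
  if (length(ia) < 5L || length(ib) < 5L) {
    stop("each ring selection needs at least 5 atoms")
  }
  ca <- frame_coords(traj, ia); cb <- frame_coords(traj, ib)
  f <- nframes(traj)
  dist <- angle <- numeric(f)
  flagged <- logical(f)
  plane_normal <- function(m) {
    centred <- sweep(m, 2L, colMeans(m))
    sv <- svd(centred, nu = 0, nv = 3)
    if (sv$d[2] < 1e-6 * max(sv$d[1], 1e-12)) return(NULL)  # collinear ring
    sv$v[, 3]
  }
  for (k in seq_len(f)) {
    ma <- ca(k); mb <- cb(k)
    dist[k] <- sqrt(sum((colMeans(ma) - colMeans(mb))^2))
    na <- plane_normal(ma); nb <- plane_normal(mb)
    if (is.null(na) || is.null(nb)) {
      flagged[k] <- TRUE
      angle[k] <- NA_real_
      next
    }
    ang <- acos(pmin(1, abs(sum(na * nb)))) * 180 / pi
    angle[k] <- ang
  }
  satisfied <- !flagged & dist <= d_max & angle <= theta_max
  satisfied[is.na(satisfied)] <- FALSE
  new_series(data.frame(distance = dist, angle = angle),
             criterion = list(label = sprintf(
               "pi-stack: d <= %.2f A, angle <= %.0f deg", d_max, theta_max),
               d_max = d_max, theta_max = theta_max),
             satisfied = satisfied, flagged = flagged)
}

#' Salt-bridge time series
#'
#' Per frame, the minimum heavy-atom distance between a set of anionic-group
#' atoms (e.g. carboxylate oxygens) and a set of cationic-group atoms (e.g.
#' an ammonium nitrogen); bridged when at most `d_max` (default 4 Angstrom).
#'
#' @param traj a `kin_trajectory`.
#' @param anionic,cationic selections of the charged-group heavy atoms.
#' @param d_max distance criterion in Angstrom.
#' @return a `kin_series` with per-frame column `distance`.
#' @export
salt_bridge_series <- function(traj, anionic, cationic, d_max = 4.0) {
  ia <- resolve_selection(traj$top, anionic)
  ib <- resolve_selection(traj$top, cationic)
  ca <- frame_coords(traj, ia); cb <- frame_coords(traj, ib)
  f <- nframes(traj)
  dmin <- vapply(seq_len(f), function(k) {
    ma <- ca(k); mb <- cb(k)
    min(sqrt(outer(rowSums(ma^2), rowSums(mb^2), "+") -
             2 * tcrossprod(ma, mb)))
  }, numeric(1))
  new_series(data.frame(distance = dmin),
             criterion = list(label = sprintf("salt bridge: d <= %.2f A",
                                              d_max), d_max = d_max),
             satisfied = dmin <= d_max)
}

#' Hydrogen-bond time series
#'
#' Donor-acceptor criterion: bonded when the donor heavy atom is within
#' `d_max` of the acceptor and the D-H...A angle is at least `angle_min`
#' (defaults 3.5 Angstrom, 135 degrees). One donor/hydrogen pair against one
#' acceptor atom per call.
#'
#' @param traj a `kin_trajectory`.
#' @param donor selection of the donor heavy atom (one atom).
#' @param hydrogen selection of the donor hydrogen (one atom); if the
#'   topology carries no hydrogens, set `heavy_only = TRUE` to fall back to
#'   the distance-only criterion.
#' @param acceptor selection of the acceptor heavy atom (one atom).
#' @param d_max,angle_min criterion parameters.
#' @param heavy_only drop the angle condition (no-hydrogen topologies).
#' @return a `kin_series` with per-frame columns `distance` and `angle`.
#' @export
hbond_series <- function(traj, donor, hydrogen = NULL, acceptor,
                         d_max = 3.5, angle_min = 135, heavy_only = FALSE) {
  one <- function(sel, what) {
    i <- resolve_selection(traj$top, sel)
    if (length(i) != 1L) stop(what, " selection must resolve to one atom")
    i
  }
  id <- one(donor, "donor")
  ia <- one(acceptor, "acceptor")
  if (!heavy_only && is.null(hydrogen)) {
    stop("no hydrogen supplied; pass the donor hydrogen or set ",
         "heavy_only = TRUE for a distance-only criterion")
  }
  cd <- traj$xyz[, atoms2xyz(id), drop = FALSE]
  cc <- traj$xyz[, atoms2xyz(ia), drop = FALSE]
  dist <- sqrt(rowSums((cd - cc)^2))
  if (heavy_only) {
    return(new_series(data.frame(distance = dist),
                      criterion = list(label = sprintf(
                        "h-bond (heavy only): d <= %.2f A", d_max),
                        d_max = d_max, angle_min = NA),
                      satisfied = dist <= d_max))
  }
  ih <- one(hydrogen, "hydrogen")
  ch <- traj$xyz[, atoms2xyz(ih), drop = FALSE]
  v1 <- cd - ch; v2 <- cc - ch
  cosang <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  new_series(data.frame(distance = dist, angle = ang),
             criterion = list(label = sprintf(
               "h-bond: d <= %.2f A, angle >= %.0f deg", d_max, angle_min),
               d_max = d_max, angle_min = angle_min),
             satisfied = dist <= d_max & ang >= angle_min)
}

#' Radial distribution function between two selections
#'
#' Histogram of reference-target distances over all frames, normalised by
#' shell volume and by the mean target density inside the analysis sphere of
#' radius `r_max` around each reference atom, so a uniformly distributed
#' target gives g(r) = 1.
#'
#' @param traj a `kin_trajectory`.
#' @param reference,target disjoint selections.
#' @param r_max largest distance analysed (Angstrom).
#' @param bin_width histogram bin width (Angstrom), < `r_max`.
#' @return object of class `kin_rdf`: `$r` (bin centres), `$g`, `$counts`,
#'   `$bin_width`.
#' @export
rdf <- function(traj, reference, target, r_max = 10, bin_width = 0.1) {
  if (!(r_max > bin_width && bin_width > 0)) {
    stop("need r_max > bin_width > 0")
  }
  ir <- resolve_selection(traj$top, reference)
  it <- resolve_selection(traj$top, target)
  if (length(intersect(ir, it))) {
    stop("reference and target selections overlap")
  }
  cr <- frame_coords(traj, ir); ct <- frame_coords(traj, it)
  breaks <- seq(0, r_max, by = bin_width)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, r_max)
  counts <- numeric(length(breaks) - 1L)
  f <- nframes(traj)
  for (k in seq_len(f)) {
    mr <- cr(k); mt <- ct(k)
    d2 <- outer(rowSums(mr^2), rowSums(mt^2), "+") - 2 * tcrossprod(mr, mt)
    d <- sqrt(pmax(d2, 0))
    d <- d[d < r_max]
    counts <- counts + tabulate(findInterval(d, breaks,
                                             rightmost.closed = TRUE),
                                nbins = length(counts))
  }
  shell_vol <- 4 / 3 * pi * diff(breaks^3)
  total_vol <- 4 / 3 * pi * r_max^3
  n_in <- sum(counts) / (f * length(ir))   # mean targets within r_max per ref
  dens <- n_in / total_vol
  g <- if (dens > 0) counts / (f * length(ir)) / (shell_vol * dens)
       else counts * 0
  structure(list(r = (breaks[-1] + breaks[-length(breaks)]) / 2, g = g,
                 counts = counts, bin_width = bin_width, r_max = r_max,
                 mean_density = dens, n_frames = f),
            class = "kin_rdf")
}

#' @export
print.kin_rdf <- function(x, ...) {
  cat("<kin_rdf> ", length(x$r), " bins to ", x$r_max, " A over ",
      x$n_frames, " frames\n", sep = "")
  invisible(x)
}

#' Regular 3-D grid specification
#'
#' @param origin length-3 lower corner (Angstrom).
#' @param spacing voxel edge (Angstrom).
#' @param dims length-3 voxel counts.
#' @export
grid_spec <- function(origin, spacing, dims) {
  stopifnot(length(origin) == 3L, spacing > 0, length(dims) == 3L,
            all(dims >= 1L))
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = as.integer(dims)), class = "kin_gridspec")
}

#' Voxel occupancy density of a selection over a trajectory
#'
#' Per voxel, the fraction of frames in which at least one selected atom
#' falls inside the voxel — the occupancy density used to compare where a
#' nucleotide or ligand sits in a pocket across states. Superpose the
#' trajectory on the pocket first; atoms outside the grid are ignored but an
#' error is raised if the grid misses the selection entirely in any frame.
#'
#' @param traj a `kin_trajectory` (already superposed on the region of
#'   interest).
#' @param sel selection of the density-carrying atoms.
#' @param grid a [grid_spec()].
#' @return object of class `kin_density`: `$values` (3-D array of per-voxel
#'   fractions) and `$grid`.
#' @export
occupancy_density <- function(traj, sel, grid) {
  stopifnot(inherits(grid, "kin_gridspec"))
  inds <- resolve_selection(traj$top, sel)
  cf <- frame_coords(traj, inds)
  f <- nframes(traj)
  acc <- array(0, grid$dims)
  for (k in seq_len(f)) {
    m <- cf(k)
    v <- floor(sweep(m, 2L, grid$origin) / grid$spacing) + 1
    inside <- v[, 1] >= 1 & v[, 1] <= grid$dims[1] &
              v[, 2] >= 1 & v[, 2] <= grid$dims[2] &
              v[, 3] >= 1 & v[, 3] <= grid$dims[3]
    if (!any(inside)) {
      stop("grid does not cover the selection in frame ", k,
           "; enlarge the grid")
    }
    vox <- unique(v[inside, , drop = FALSE])
    acc[vox] <- acc[vox] + 1
  }
  structure(list(values = acc / f, grid = grid), class = "kin_density")
}

#' @export
print.kin_density <- function(x, ...) {
  cat("<kin_density> ", paste(x$grid$dims, collapse = " x "),
      " voxels, spacing ", x$grid$spacing, " A, ",
      sum(x$values > 0), " occupied\n", sep = "")
  invisible(x)
}

#' Overlap between two occupancy densities
#'
#' Jaccard-like score on voxel occupancies:
#' \eqn{\sum_v \min(a_v, b_v) / \sum_v \max(a_v, b_v)}; 1 for identical
#' densities, 0 for disjoint ones.
#'
#' @param a,b `kin_density` objects on congruent grids.
#' @return scalar in [0, 1].
#' @export
density_overlap <- function(a, b) {
  stopifnot(inherits(a, "kin_density"), inherits(b, "kin_density"))
  ga <- a$grid; gb <- b$grid
  if (!isTRUE(all.equal(ga$origin, gb$origin)) ||
      ga$spacing != gb$spacing || !all(ga$dims == gb$dims)) {
    stop("grids are not congruent")
  }
  denom <- sum(pmax(a$values, b$values))
  if (denom == 0) return(NA_real_)
  sum(pmin(a$values, b$values)) / denom
}

#' Write an occupancy density as an OpenDX volumetric grid
#'
#' Plain-text DX format readable by common molecular viewers.
#'
#' @param dens a `kin_density`.
#' @param path output file.
#' @export
write_density_dx <- function(dens, path) {
  g <- dens$grid
  n <- prod(g$dims)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d",
            g$dims[1], g$dims[2], g$dims[3]),
    sprintf("origin %.4f %.4f %.4f", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %.4f 0 0", g$spacing),
    sprintf("delta 0 %.4f 0", g$spacing),
    sprintf("delta 0 0 %.4f", g$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            g$dims[1], g$dims[2], g$dims[3]),
    sprintf(paste0("object 3 class array type double rank 0 items %d ",
                   "data follows"), n)), con)
  vals <- as.vector(aperm(dens$values, c(3, 2, 1)))  # DX is z-fastest
  full <- c(vals, rep(NA_real_, (3 - length(vals) %% 3) %% 3))
  m <- matrix(full, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(r) {
    paste(sprintf("%.6g", r[!is.na(r)]), collapse = " ")
  })
  writeLines(lines, con)
  invisible(path)
}
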