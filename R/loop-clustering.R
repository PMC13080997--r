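#' Loop-conformation clustering protocol
#'
#' A four-step protocol to separate the conformational regimes of a flexible
#' loop carried by a helix (developed for loop 5 of the kinesin-5 motor
#' domain, which interrupts helix alpha-2):
#' \enumerate{
#'   \item strip the trajectory to its backbone and align it to the backbone
#'     of the first frame;
#'   \item align on the stably structured residues (helix/strand in every
#'     analysed state) and compute an average structure;
#'   \item fit every frame to the helix anchor flanking the loop (default
#'     residues 111-116 and 135-140) of that average structure and retain
#'     only the loop backbone (default residues 111-140);
#'   \item hierarchical agglomerative clustering on the pairwise frame RMSD,
#'     cutting the dendrogram at epsilon (default 5 Angstrom).
#' }
#' Crucially, the pairwise RMSD in step 4 is computed without per-pair
#' re-superposition: frames share the anchor frame of reference, so a docked
#' and an undocked loop position differ even when their internal shapes are
#' similar.
#'
#' @name loop-clustering
NULL

#' Configuration of the loop-clustering protocol
#'
#' @param loop residues whose backbone is clustered (range string or integer
#'   vector); default `"111-140"`, the helix-plus-loop segment.
#' @param anchor helix residues used for the step-3 fit; default
#'   `"111-116,135-140"`, the helix turns flanking the loop.
#' @param atoms `"backbone"` (default) or `"CA"` (for alpha-carbon-only
#'   inputs such as coarse synthetic trajectories).
#' @param stable_ss optional `kin_selection` of stably structured residues
#'   for step 2; when `NULL` it is computed from the trajectory itself via
#'   [stable_ss_mask()] (backbone inputs only).
#' @param stability_fraction threshold for the computed stable mask.
#' @param epsilon dendrogram cut height in Angstrom (> 0).
#' @param linkage `"average"` (default), `"single"` or `"complete"`.
#' @return object of class `cluster_config`.
#' @export
cluster_config <- function(loop = "111-140", anchor = "111-116,135-140",
                           atoms = c("backbone", "CA"), stable_ss = NULL,
                           stability_fraction = 0.75, epsilon = 5,
                           linkage = c("average", "single", "complete")) {
  atoms <- match.arg(atoms)
  linkage <- match.arg(linkage)
  if (epsilon <= 0) stop("epsilon must be positive")
  as_res <- function(r) if (is.character(r)) parse_ranges(r) else as.integer(r)
  structure(list(loop = as_res(loop), anchor = as_res(anchor), atoms = atoms,
                 stable_ss = stable_ss,
                 stability_fraction = stability_fraction,
                 epsilon = epsilon, linkage = linkage),
            class = "cluster_config")
}

#' Steps 1-3 of the loop-clustering protocol
#'
#' Executes stripping, alignment, averaging and the anchor fit, returning the
#' backbone-only loop trajectory expressed in the anchor frame of reference.
#' The average structure from step 2 is attached as attribute
#' `"average_structure"`.
#'
#' @param traj a `kin_trajectory` (backbone atoms required unless
#'   `config$atoms == "CA"`).
#' @param config a [cluster_config()].
#' @return reduced `kin_trajectory` of the loop backbone.
#' @export
protocol_transform <- function(traj, config = cluster_config()) {
  stopifnot(inherits(config, "cluster_config"))
  if (nframes(traj) < 2L) stop("protocol needs at least 2 frames")
  all_sel <- sel_spec(NULL, atoms = config$atoms)

  # step 1: strip side chains, align to the first frame's backbone
  red <- reduce_trajectory(traj, all_sel)
  red <- superpose_trajectory(red, 1L, all_sel)

  # step 2: align on stable secondary structure, average
  ss_sel <- config$stable_ss
  if (is.null(ss_sel)) {
    if (config$atoms == "CA") {
      stop("stable_ss must be supplied for alpha-carbon-only inputs ",
           "(dihedral assignment needs the backbone)")
    }
    ss_sel <- stable_ss_mask(red, config$stability_fraction)
  }
  ss_sel <- sel_spec(ss_sel$residues, atoms = config$atoms)
  red <- superpose_trajectory(red, 1L, ss_sel)
  avg <- colMeans(red$xyz)

  # step 3: fit to the helix anchor of the average, keep the loop backbone
  anchor_sel <- sel_spec(config$anchor, atoms = config$atoms)
  red <- superpose_trajectory(red, avg, anchor_sel)
  out <- reduce_trajectory(red, sel_spec(config$loop, atoms = config$atoms))
  attr(out, "average_structure") <- avg
  out
}

#' Step 4: hierarchical clustering of loop conformations
#'
#' Agglomerates frames on their pairwise RMSD (no per-pair refitting; the
#' frames are already in the anchor frame of reference) and cuts the
#' dendrogram where the linkage distance exceeds `epsilon`. Clusters are
#' numbered by decreasing population.
#'
#' @param reduced loop trajectory from [protocol_transform()] (any
#'   `kin_trajectory` works).
#' @param epsilon cut height in Angstrom.
#' @param linkage agglomeration rule.
#' @return object of class `kin_clusters`: `$labels` (integer per frame),
#'   `$populations` (fractions, sorted decreasing), `$centroid_frames`
#'   (member frame minimising summed within-cluster RMSD), `$rmsd_summary`
#'   (mean within- and between-cluster RMSD).
#' @export
hier_cluster <- function(reduced, epsilon = 5,
                         linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  if (epsilon <= 0) stop("epsilon must be positive")
  f <- nframes(reduced)
  if (f < 2L) stop("clustering needs at least 2 frames")
  rm <- pairwise_rmsd(reduced$xyz)
  hc <- stats::hclust(stats::as.dist(rm), method = linkage)
  raw <- stats::cutree(hc, h = epsilon)
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  labels <- as.integer(relabel[as.character(raw)])
  k <- length(sizes)
  centroids <- integer(k)
  within <- numeric(k)
  for (c in seq_len(k)) {
    members <- which(labels == c)
    sub <- rm[members, members, drop = FALSE]
    centroids[c] <- members[which.min(rowSums(sub))]
    within[c] <- if (length(members) > 1L) {
      mean(sub[upper.tri(sub)])
    } else 0
  }
  between <- if (k > 1L) mean(rm[outer(labels, labels, "!=")]) else NA_real_
  structure(list(labels = labels,
                 populations = as.numeric(sizes) / f,
                 centroid_frames = centroids,
                 n_clusters = k, epsilon = epsilon, linkage = linkage,
                 rmsd_summary = list(within = within, between = between)),
            class = "kin_clusters")
}

#' @export
print.kin_clusters <- function(x, ...) {
  cat("<kin_clusters> ", x$n_clusters, " cluster(s) at epsilon ",
      x$epsilon, " A (", x$linkage, " linkage): populations ",
      paste(sprintf("%.1f%%", 100 * x$populations), collapse = "/"),
      "\n", sep = "")
  invisible(x)
}

#' Fitted RMSD between two representative conformations
#'
#' Quantifies how similar two cluster centroids (or any two frames) are,
#' optionally over a sub-selection — the numeric counterpart of visually
#' superposing representative loop conformations from different catalytic
#' states.
#'
#' @param a,b flat coordinate vectors of equal length.
#' @param top optional `kin_structure` the vectors are congruent with, needed
#'   when `sel` is given.
#' @param sel optional `kin_selection` restricting the comparison.
#' @param fit least-squares superpose before measuring (default `TRUE`).
#' @return RMSD in Angstrom.
#' @export
compare_representatives <- function(a, b, top = NULL, sel = NULL,
                                    fit = TRUE) {
  stopifnot(length(a) == length(b))
  if (!is.null(sel)) {
    if (is.null(top)) stop("a topology is required to resolve 'sel'")
    cols <- atoms2xyz(resolve_selection(top, sel))
    a <- a[cols]; b <- b[cols]
  }
  rmsd_xyz(a, b, fit = fit)
}

#' Best-matching agreement between two labelings
#'
#' Fraction of frames on which two cluster labelings agree under the best
#' one-to-one matching of cluster ids (exhaustive over permutations up to 7
#' clusters, greedy beyond). Used to score recovery of generator ground-truth
#' states.
#'
#' @param labels,truth vectors of equal length (any label type).
#' @return agreement fraction in [0, 1].
#' @export
cluster_agreement <- function(labels, truth) {
  stopifnot(length(labels) == length(truth))
  la <- as.integer(factor(labels)); tr <- as.integer(factor(truth))
  ka <- max(la); kt <- max(tr)
  tab <- table(factor(la, 1:ka), factor(tr, 1:kt))
  k <- max(ka, kt)
  m <- matrix(0, k, k)
  m[1:ka, 1:kt] <- tab
  if (k <= 7L) {
    perms <- permutations_of(k)
    best <- 0
    for (p in perms) best <- max(best, sum(m[cbind(1:k, p)]))
  } else {
    best <- 0
    mm <- m
    for (i in seq_len(k)) {
      w <- which(mm == max(mm), arr.ind = TRUE)[1, ]
      best <- best + mm[w[1], w[2]]
      mm[w[1], ] <- -1; mm[, w[2]] <- -1
    }
  }
  best / length(labels)
}

permutations_of <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in permutations_of(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}
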