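#' Shortest Path Maps
#'
#' A Shortest Path Map (SPM) condenses a trajectory's dynamic
#' cross-correlation into a sparse residue network: residues are nodes,
#' spatially proximal pairs (mean alpha-carbon distance below a cutoff,
#' default 6 Angstrom) are joined by edges of length \eqn{-\log |C_{ij}|},
#' and the edges most frequently traversed by all-pairs shortest paths form
#' the final map. Strongly (anti)correlated neighbours give short edges, so
#' the map traces the routes along which allosteric communication is
#' cheapest.
#'
#' @name spm
NULL

new_cormat <- function(values, resno, reference = "unspecified",
                       rigid = integer(0)) {
  dimnames(values) <- list(resno, resno)
  structure(list(values = values, resno = as.integer(resno),
                 reference = reference, rigid = rigid),
            class = "kin_cormat")
}

#' @export
print.kin_cormat <- function(x, ...) {
  cat("<kin_cormat> ", length(x$resno), " residues (reference: ",
      x$reference, ")", if (length(x$rigid)) paste0("; ", length(x$rigid),
      " zero-displacement residue(s) flagged"), "\n", sep = "")
  invisible(x)
}

#' Most representative frame of a trajectory
#'
#' Superposes all frames on alpha carbons, clusters them hierarchically on
#' pairwise RMSD, and returns the centroid of the most populated cluster:
#' the member frame minimising summed RMSD to the other members. This is the
#' reference structure used for displacement correlations.
#'
#' @param traj a `kin_trajectory`.
#' @param epsilon height (Angstrom) at which the dendrogram is cut.
#' @param linkage agglomeration rule passed to [stats::hclust()].
#' @param max_frames frames above this count are strided down for the
#'   clustering step (the full frame set is still eligible as centroid
#'   members via the strided subset); keeps the F x F RMSD matrix tractable.
#' @return list with `frame_index` (into `traj`) and `frame` (flat
#'   coordinates of the superposed trajectory at that index).
#' @export
reference_structure <- function(traj, epsilon = 2, linkage = "average",
                                max_frames = 2000L) {
  if (nframes(traj) < 1L) stop("empty trajectory")
  sup <- superpose_trajectory(traj, 1L, sel_spec(atoms = "CA"))
  if (nframes(sup) == 1L) {
    return(list(frame_index = 1L, frame = get_frame(sup, 1L)))
  }
  red <- reduce_trajectory(sup, sel_spec(atoms = "CA"))
  frames <- seq_len(nframes(red))
  if (length(frames) > max_frames) {
    frames <- frames[seq(1L, length(frames),
                         by = ceiling(length(frames) / max_frames))]
  }
  rm <- pairwise_rmsd(red$xyz[frames, , drop = FALSE])
  cl <- stats::cutree(stats::hclust(stats::as.dist(rm), method = linkage),
                      h = epsilon)
  sizes <- table(cl)
  top_cl <- as.integer(names(sizes)[which.max(sizes)])
  members <- which(cl == top_cl)
  centroid_local <- members[which.min(rowSums(rm[members, members,
                                                 drop = FALSE]))]
  idx <- frames[centroid_local]
  list(frame_index = idx, frame = get_frame(sup, idx))
}

#' Dynamic cross-correlation relative to a reference structure
#'
#' Computes \eqn{C_{ij} = \langle \Delta r_i \cdot \Delta r_j \rangle /
#' \sqrt{\langle \Delta r_i^2 \rangle \langle \Delta r_j^2 \rangle}} where
#' \eqn{\Delta r_i} is the displacement of residue i's alpha carbon from its
#' position in the reference structure, after superposing every frame on the
#' reference (alpha carbons) to remove rigid-body motion.
#'
#' @param traj a `kin_trajectory`.
#' @param reference flat coordinate vector congruent with `traj` frames, a
#'   frame index, or `NULL` to derive the most representative frame via
#'   [reference_structure()].
#' @param superpose set `FALSE` only when frames are already aligned to the
#'   reference (e.g. generated displacement data).
#' @return a `kin_cormat`. Residues with zero mean-square displacement have
#'   undefined correlations; their off-diagonal entries are set to 0 and
#'   their indices flagged in `$rigid`.
#' @export
correlation_matrix <- function(traj, reference = NULL, superpose = TRUE) {
  if (nframes(traj) < 2L) stop("at least 2 frames required")
  ref_label <- "supplied frame"
  if (is.null(reference)) {
    reference <- reference_structure(traj)$frame
    ref_label <- "most representative frame"
  } else if (length(reference) == 1L) {
    reference <- get_frame(traj, reference)
    ref_label <- paste0("frame ", reference)
  }
  stopifnot(length(reference) == ncol(traj$xyz))
  if (superpose) traj <- superpose_trajectory(traj, reference,
                                              sel_spec(atoms = "CA"))
  red <- reduce_trajectory(traj, sel_spec(atoms = "CA"))
  ref_top <- kin_trajectory(traj$top, matrix(reference, nrow = 1L))
  ref_red <- reduce_trajectory(ref_top, sel_spec(atoms = "CA"))
  n <- natoms(red)
  d <- sweep(red$xyz, 2L, ref_red$xyz[1L, ], "-")
  f <- nrow(d)
  raw <- matrix(0, n, n)
  for (k in 1:3) {
    idx <- seq(k, 3L * n, by = 3L)
    raw <- raw + crossprod(d[, idx, drop = FALSE])
  }
  raw <- raw / f
  v <- diag(raw)
  rigid <- which(v <= .Machine$double.eps)
  cc <- raw / sqrt(outer(pmax(v, .Machine$double.xmin),
                         pmax(v, .Machine$double.xmin)))
  cc[cc > 1] <- 1; cc[cc < -1] <- -1
  if (length(rigid)) { cc[rigid, ] <- 0; cc[, rigid] <- 0 }
  diag(cc) <- 1
  new_cormat(cc, red$top$atoms$resno, reference = ref_label, rigid = rigid)
}

#' Mean alpha-carbon distance matrix of a trajectory
#'
#' \eqn{\langle d_{ij} \rangle} over frames; rotation-invariant, so no
#' fitting is performed.
#'
#' @param traj a `kin_trajectory`.
#' @param sel one-atom-per-residue selection (default alpha carbons).
#' @return object of class `kin_avgdist` with `$values` in Angstrom.
#' @export
average_distance_matrix <- function(traj, sel = sel_spec(atoms = "CA")) {
  red <- reduce_trajectory(traj, sel)
  resno <- red$top$atoms$resno
  if (anyDuplicated(resno)) stop("selection must yield one atom per residue")
  m <- pair_distance_moments(red$xyz, length(resno))$mean
  dimnames(m) <- list(resno, resno)
  structure(list(values = m, resno = as.integer(resno)),
            class = "kin_avgdist")
}

#' @export
print.kin_avgdist <- function(x, ...) {
  cat("<kin_avgdist> ", length(x$resno), " residues\n", sep = "")
  invisible(x)
}

#' Build the allosteric residue graph
#'
#' Residues i and j are connected only when their alpha carbons stay, on
#' average, closer than `cutoff`; each retained edge gets length
#' \eqn{l_{ij} = -\log |C_{ij}|} (natural log; shortest-path ranking is
#' invariant to the log base, which only rescales all lengths uniformly).
#' Pairs with exactly zero correlation carry no information and are omitted
#' (their length would be infinite).
#'
#' @param cormat a `kin_cormat`.
#' @param avgdist a `kin_avgdist` on the same residues.
#' @param cutoff contact cutoff in Angstrom (> 0), default 6.
#' @return object of class `kin_graph` wrapping an igraph graph plus the
#'   edge-length matrix.
#' @export
build_graph <- function(cormat, avgdist, cutoff = 6) {
  stopifnot(inherits(cormat, "kin_cormat"), inherits(avgdist, "kin_avgdist"))
  if (cutoff <= 0) stop("cutoff must be positive")
  if (!identical(cormat$resno, avgdist$resno)) {
    stop("correlation and distance matrices cover different residues")
  }
  n <- length(cormat$resno)
  absc <- abs(cormat$values)
  keep <- avgdist$values < cutoff & absc > 0 & upper.tri(absc)
  idx <- which(keep, arr.ind = TRUE)
  w <- -log(absc[keep])
  w[w < 0] <- 0              # numerical guard for |C| rounding above 1
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- as.character(cormat$resno)
  if (nrow(idx)) {
    g <- igraph::add_edges(g, as.vector(t(idx)), weight = w)
  }
  structure(list(graph = g, resno = cormat$resno, cutoff = cutoff,
                 n = n, edges = data.frame(i = idx[, 1], j = idx[, 2],
                                           length = w)),
            class = "kin_graph")
}

#' @export
print.kin_graph <- function(x, ...) {
  cat("<kin_graph> ", x$n, " residues, ", nrow(x$edges),
      " edges (cutoff ", x$cutoff, " A)\n", sep = "")
  invisible(x)
}

# dense weight matrix (Inf = no edge) and neighbour lists
graph_weights <- function(kg) {
  w <- matrix(Inf, kg$n, kg$n)
  if (nrow(kg$edges)) {
    w[cbind(kg$edges$i, kg$edges$j)] <- kg$edges$length
    w[cbind(kg$edges$j, kg$edges$i)] <- kg$edges$length
  }
  w
}

graph_neighbours <- function(kg) {
  nb <- vector("list", kg$n)
  for (r in seq_len(nrow(kg$edges))) {
    i <- kg$edges$i[r]; j <- kg$edges$j[r]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  lapply(nb, function(v) if (is.null(v)) integer(0) else sort(v))
}

# lexicographically smallest simple shortest path from s to t, given the
# all-pairs distance matrix; greedy forward walk on the shortest-path DAG
reconstruct_path <- function(s, t, w, dm, nbrs) {
  tol <- 1e-9 * (1 + abs(dm[s, t]))
  n <- nrow(w)
  visited <- rep(FALSE, n)
  path <- integer(0)
  v <- s
  repeat {
    path <- c(path, v)
    if (v == t) return(path)
    visited[v] <- TRUE
    cand <- nbrs[[v]]
    cand <- cand[!visited[cand]]
    ok <- cand[abs(dm[s, v] + w[v, cand] - dm[s, cand]) <= tol &
               abs(dm[s, cand] + dm[cand, t] - dm[s, t]) <= tol]
    if (!length(ok)) {
      stop("internal error: shortest-path reconstruction stalled")
    }
    v <- min(ok)
  }
}

#' Compute the shortest-path map of an allosteric graph
#'
#' Traces one shortest path for every unordered residue pair in the same
#' connected component (ties broken deterministically in favour of the
#' lexicographically smallest node sequence), accumulates how often each edge
#' and node is traversed, and retains the edges whose usage reaches
#' `keep_frac` of the maximum edge usage. Pairs in different components
#' contribute nothing.
#'
#' @param kg a `kin_graph`.
#' @param keep_frac retention threshold as a fraction of the maximum edge
#'   usage count (the map threshold is a free choice; 0.2 gives a sparse
#'   backbone-like map on typical inputs).
#' @return object of class `kin_spm`: `$edges` (usage-annotated edge table
#'   with `retained` flag), `$node_usage` (paths through each residue,
#'   endpoints included), `$n_pairs` (connected pairs traced), `$path_lengths`
#'   (matrix of shortest-path lengths).
#' @export
shortest_path_map <- function(kg, keep_frac = 0.2) {
  stopifnot(inherits(kg, "kin_graph"))
  if (kg$n < 2L) stop("graph needs at least 2 nodes")
  stopifnot(keep_frac >= 0, keep_frac <= 1)
  w <- graph_weights(kg)
  nbrs <- graph_neighbours(kg)
  dm <- igraph::distances(kg$graph, weights = igraph::E(kg$graph)$weight)
  dimnames(dm) <- NULL
  edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  usage <- stats::setNames(rep(0L, nrow(kg$edges)),
                           edge_key(kg$edges$i, kg$edges$j))
  node_usage <- rep(0L, kg$n)
  n_pairs <- 0L
  for (s in seq_len(kg$n - 1L)) {
    for (t in (s + 1L):kg$n) {
      if (!is.finite(dm[s, t])) next
      p <- reconstruct_path(s, t, w, dm, nbrs)
      n_pairs <- n_pairs + 1L
      node_usage[p] <- node_usage[p] + 1L
      if (length(p) > 1L) {
        k <- edge_key(p[-length(p)], p[-1L])
        usage[k] <- usage[k] + 1L
      }
    }
  }
  edges <- kg$edges
  edges$usage <- as.integer(usage[edge_key(edges$i, edges$j)])
  max_use <- if (nrow(edges)) max(edges$usage) else 0L
  edges$retained <- max_use > 0 & edges$usage >= keep_frac * max_use
  edges$resno_i <- kg$resno[edges$i]
  edges$resno_j <- kg$resno[edges$j]
  structure(list(edges = edges,
                 node_usage = stats::setNames(node_usage, kg$resno),
                 n_pairs = n_pairs, keep_frac = keep_frac,
                 path_lengths = dm, resno = kg$resno),
            class = "kin_spm")
}

#' @export
print.kin_spm <- function(x, ...) {
  cat("<kin_spm> ", sum(x$edges$retained), "/", nrow(x$edges),
      " edges retained (keep_frac ", x$keep_frac, "), ", x$n_pairs,
      " residue pairs traced\n", sep = "")
  invisible(x)
}

#' Shortest paths between two residue regions
#'
#' For every source-target residue pair within one connected component,
#' returns the shortest path and its total length, plus the single best
#' (minimum-length) path over all pairs — e.g. the cheapest communication
#' route between a regulatory loop and the nucleotide-binding P-loop.
#'
#' @param kg a `kin_graph`.
#' @param source,target residue numbers (vectors, range strings, or
#'   `kin_selection` objects).
#' @return list with `paths` (data-frame-free list of per-pair results, each
#'   holding `source`, `target`, `length`, `path` as residue numbers) and
#'   `best` (the minimum-length entry, or `NULL` with a warning when no pair
#'   is connected).
#' @export
path_between <- function(kg, source, target) {
  stopifnot(inherits(kg, "kin_graph"))
  as_res <- function(r) {
    if (inherits(r, "kin_selection")) r <- r$residues
    if (is.character(r)) r <- parse_ranges(r)
    r
  }
  src <- which(kg$resno %in% as_res(source))
  tgt <- which(kg$resno %in% as_res(target))
  if (!length(src) || !length(tgt)) stop("empty source or target selection")
  w <- graph_weights(kg)
  nbrs <- graph_neighbours(kg)
  dm <- igraph::distances(kg$graph, weights = igraph::E(kg$graph)$weight)
  dimnames(dm) <- NULL
  out <- list()
  for (s in src) {
    for (t in tgt) {
      if (s == t) {
        out[[length(out) + 1L]] <- list(source = kg$resno[s],
                                        target = kg$resno[t],
                                        length = 0, path = kg$resno[s])
        next
      }
      if (!is.finite(dm[s, t])) next
      p <- reconstruct_path(s, t, w, dm, nbrs)
      out[[length(out) + 1L]] <- list(source = kg$resno[s],
                                      target = kg$resno[t],
                                      length = dm[s, t],
                                      path = kg$resno[p])
    }
  }
  if (!length(out)) {
    warning("no connected source-target pair")
    return(list(paths = list(), best = NULL))
  }
  best <- out[[which.min(vapply(out, `[[`, numeric(1), "length"))]]
  list(paths = out, best = best)
}

#' Export a shortest-path map to plain-text files
#'
#' Writes `<prefix>edges.tsv` (edge usage table), `<prefix>nodes.tsv`
#' (per-node usage), and `<prefix>spm_draw.py`, a PyMOL script drawing dark
#' spheres at alpha-carbon positions of retained nodes and cylinders along
#' retained edges with radius proportional to usage.
#'
#' @param spm a `kin_spm`.
#' @param top a `kin_structure` providing alpha-carbon coordinates.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
export_spm <- function(spm, top, prefix) {
  stopifnot(inherits(spm, "kin_spm"), inherits(top, "kin_structure"))
  ca <- top$atoms[top$atoms$elety == "CA", , drop = FALSE]
  if (!all(spm$resno %in% ca$resno)) {
    stop("structure lacks alpha carbons for some map residues")
  }
  edge_path <- paste0(prefix, "edges.tsv")
  node_path <- paste0(prefix, "nodes.tsv")
  pml_path <- paste0(prefix, "spm_draw.py")
  ed <- spm$edges[, c("resno_i", "resno_j", "length", "usage", "retained")]
  utils::write.table(format(ed, digits = 17, trim = TRUE), edge_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  nd <- data.frame(resno = as.integer(names(spm$node_usage)),
                   usage = as.integer(spm$node_usage))
  utils::write.table(nd, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  kept <- spm$edges[spm$edges$retained, , drop = FALSE]
  coord_of <- function(res) {
    r <- ca[match(res, ca$resno), c("x", "y", "z")]
    as.numeric(r)
  }
  lines <- c("from pymol import cmd", "from pymol.cgo import *",
             "obj = []")
  if (nrow(kept)) {
    max_use <- max(kept$usage)
    kept_nodes <- unique(c(kept$resno_i, kept$resno_j))
    for (res in kept_nodes) {
      p <- coord_of(res)
      lines <- c(lines, sprintf(
        "obj += [COLOR, 0.1, 0.1, 0.6, SPHERE, %.3f, %.3f, %.3f, 0.8]",
        p[1], p[2], p[3]))
    }
    for (r in seq_len(nrow(kept))) {
      a <- coord_of(kept$resno_i[r]); b <- coord_of(kept$resno_j[r])
      rad <- 0.1 + 0.5 * kept$usage[r] / max_use
      lines <- c(lines, sprintf(
        paste0("obj += [CYLINDER, %.3f, %.3f, %.3f, %.3f, %.3f, %.3f, ",
               "%.3f, 0.5, 0.7, 1.0, 0.5, 0.7, 1.0]"),
        a[1], a[2], a[3], b[1], b[2], b[3], rad))
    }
  }
  lines <- c(lines, "cmd.load_cgo(obj, 'spm')")
  writeLines(lines, pml_path)
  invisible(c(edge_path, node_path, pml_path))
}

#' Read back an edge table written by [export_spm()]
#'
#' @param path the `...edges.tsv` file.
#' @return data frame with `resno_i`, `resno_j`, `length`, `usage`,
#'   `retained`.
#' @export
read_spm_edges <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
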