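# Independent oracles, implemented without touching the package internals.

# Floyd-Warshall all-pairs shortest path lengths from a dense weight matrix
# (Inf = no edge).
fw_distances <- function(w) {
  n <- nrow(w)
  d <- w
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      alt <- d[i, k] + d[k, ]
      upd <- alt < d[i, ]
      d[i, upd] <- alt[upd]
    }
  }
  d
}

# lexicographically smallest simple shortest path from s to t, using only the
# Floyd-Warshall distance matrix: greedy forward walk choosing at every step
# the smallest-index unvisited neighbour that still lies on some shortest
# path (same tie-break rule the package documents).
fw_path <- function(s, t, w, d) {
  tol <- 1e-9 * (1 + abs(d[s, t]))
  path <- s
  v <- s
  visited <- rep(FALSE, nrow(w))
  while (v != t) {
    visited[v] <- TRUE
    cand <- which(is.finite(w[v, ]) & !visited)
    ok <- cand[abs(d[s, v] + w[v, cand] - d[s, cand]) <= tol &
               abs(d[s, cand] + d[cand, t] - d[s, t]) <= tol]
    stopifnot(length(ok) > 0)
    v <- min(ok)
    path <- c(path, v)
  }
  path
}

# full oracle: per-pair lengths plus edge and node usage counts
spm_oracle <- function(w) {
  n <- nrow(w)
  d <- fw_distances(w)
  edge_usage <- matrix(0L, n, n)
  node_usage <- integer(n)
  n_pairs <- 0L
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(d[s, t])) next
      p <- fw_path(s, t, w, d)
      n_pairs <- n_pairs + 1L
      node_usage[p] <- node_usage[p] + 1L
      for (e in seq_len(length(p) - 1)) {
        i <- min(p[e], p[e + 1]); j <- max(p[e], p[e + 1])
        edge_usage[i, j] <- edge_usage[i, j] + 1L
      }
    }
  }
  list(dist = d, edge_usage = edge_usage, node_usage = node_usage,
       n_pairs = n_pairs)
}

# build a kin_graph with prescribed edge lengths: edges get |C| = exp(-len)
# and mean distance 3 A; non-edges get mean distance 10 A (beyond cutoff)
graph_from_lengths <- function(len) {
  n <- nrow(len)
  cvals <- exp(-len)
  cvals[!is.finite(len)] <- 0.5       # value irrelevant: distance blocks edge
  diag(cvals) <- 1
  dvals <- matrix(10, n, n)
  dvals[is.finite(len)] <- 3
  diag(dvals) <- 0
  cm <- structure(list(values = cvals, resno = seq_len(n),
                       reference = "constructed", rigid = integer(0)),
                  class = "kin_cormat")
  dm <- structure(list(values = dvals, resno = seq_len(n)),
                  class = "kin_avgdist")
  build_graph(cm, dm, cutoff = 6)
}

# random symmetric length matrix for an Erdos-Renyi-like graph
random_length_matrix <- function(n, p_edge = 0.4) {
  len <- matrix(Inf, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p_edge) {
        len[i, j] <- len[j, i] <- stats::runif(1, 0.05, 2)
      }
    }
  }
  diag(len) <- Inf
  len
}
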