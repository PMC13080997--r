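test_that("the reference structure is the centroid of the main cluster", {
  top <- make_ca_topology(8)
  same <- static_traj(top, 5)
  expect_equal(reference_structure(same)$frame_index, 1L)

  single <- static_traj(top, 1)
  expect_equal(reference_structure(single)$frame_index, 1L)

  # dominant-state centroid belongs to the dominant state
  fix <- two_state_fixture(p_a = 0.8, seed = 6)
  ts <- make_two_state_trajectory(fix$spec, 200)
  ref <- reference_structure(ts$traj, epsilon = 2)
  expect_equal(ts$labels[ref$frame_index], "A")
})

test_that("correlations reproduce hand-built displacement patterns", {
  top <- make_ca_topology(2, shape = "line", spacing = 50)
  ref <- ref_xyz(top)
  # both residues translate identically along x each frame
  shifts <- c(1, -2, 0.5, 1.5)
  xyz <- t(vapply(shifts, function(s) ref + rep(c(s, 0, 0), 2),
                  numeric(6)))
  cm <- correlation_matrix(kin_trajectory(top, xyz), reference = ref,
                           superpose = FALSE)
  expect_equal(cm$values[1, 2], 1)

  # equal and opposite displacements: perfect anticorrelation
  xyz2 <- t(vapply(shifts, function(s) ref + c(s, 0, 0, -s, 0, 0),
                   numeric(6)))
  cm2 <- correlation_matrix(kin_trajectory(top, xyz2), reference = ref,
                            superpose = FALSE)
  expect_equal(cm2$values[1, 2], -1)

  # orthogonal +-1 patterns over four frames: zero correlation
  di <- c(1, -1, 1, -1); dj <- c(1, 1, -1, -1)
  xyz3 <- t(vapply(1:4, function(f) ref + c(di[f], 0, 0, dj[f], 0, 0),
                   numeric(6)))
  cm3 <- correlation_matrix(kin_trajectory(top, xyz3), reference = ref,
                            superpose = FALSE)
  expect_equal(cm3$values[1, 2], 0)
  expect_equal(diag(cm3$values), c(1, 1), ignore_attr = TRUE)
})

test_that("zero-displacement residues are flagged and isolated", {
  top <- make_ca_topology(3, shape = "line", spacing = 50)
  ref <- ref_xyz(top)
  xyz <- t(vapply(c(1, -1, 2, -2), function(s) {
    v <- ref
    v[1] <- v[1] + s       # residue 1 moves
    v[4] <- v[4] - s       # residue 2 moves
    v                      # residue 3 rigid
  }, numeric(9)))
  cm <- correlation_matrix(kin_trajectory(top, xyz), reference = ref,
                           superpose = FALSE)
  expect_equal(cm$rigid, 3L)
  expect_equal(cm$values[3, 1], 0)
  expect_equal(cm$values[3, 3], 1)
})

test_that("mean distances average the per-frame geometry", {
  top <- make_ca_topology(2, shape = "line", spacing = 1)
  xyz <- rbind(c(0, 0, 0, 1, 0, 0), c(0, 0, 0, 3, 0, 0))
  dm <- average_distance_matrix(kin_trajectory(top, xyz))
  expect_equal(dm$values[1, 2], 2)
  expect_equal(diag(dm$values), c(0, 0), ignore_attr = TRUE)

  static <- static_traj(make_ca_topology(5), 3)
  dm2 <- average_distance_matrix(static)
  ref <- matrix(ref_xyz(static$top), ncol = 3, byrow = TRUE)
  expect_equal(dm2$values, as.matrix(dist(ref)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("graph edges follow the distance cutoff and the log-length rule", {
  cvals <- matrix(c(1, 1, 0.5, 0,
                    1, 1, 0.8, 0.9,
                    0.5, 0.8, 1, 0.7,
                    0, 0.9, 0.7, 1), 4)
  dvals <- matrix(3, 4, 4); diag(dvals) <- 0
  dvals[1, 2] <- dvals[2, 1] <- 6.5   # beyond cutoff despite |C| = 1
  cm <- structure(list(values = cvals, resno = 1:4, reference = "toy",
                       rigid = integer(0)), class = "kin_cormat")
  dm <- structure(list(values = dvals, resno = 1:4), class = "kin_avgdist")
  kg <- build_graph(cm, dm, cutoff = 6)

  has_edge <- function(i, j) {
    any(kg$edges$i == i & kg$edges$j == j)
  }
  expect_false(has_edge(1, 2))        # blocked by the 6 A rule
  expect_false(has_edge(1, 4))        # |C| = 0 carries no information
  expect_true(has_edge(1, 3))
  expect_equal(kg$edges$length[kg$edges$i == 1 & kg$edges$j == 3], log(2))
  expect_equal(kg$edges$length[kg$edges$i == 2 & kg$edges$j == 4],
               -log(0.9))
  expect_error(build_graph(cm, dm, cutoff = 0), "positive")

  # widening the cutoff can only add edges
  kg7 <- build_graph(cm, dm, cutoff = 7)
  key <- function(g) paste(g$edges$i, g$edges$j)
  expect_true(all(key(kg) %in% key(kg7)))
})

test_that("path-graph usage counts match brute-force enumeration", {
  # a - b - c - d with equal lengths
  len <- matrix(Inf, 4, 4)
  len[1, 2] <- len[2, 1] <- 1
  len[2, 3] <- len[3, 2] <- 1
  len[3, 4] <- len[4, 3] <- 1
  kg <- graph_from_lengths(len)
  spm <- shortest_path_map(kg, keep_frac = 0)
  oracle <- spm_oracle(len)
  expect_equal(spm$n_pairs, 6L)
  got <- matrix(0L, 4, 4)
  got[cbind(spm$edges$i, spm$edges$j)] <- spm$edges$usage
  expect_equal(got, oracle$edge_usage)
  # middle edge carries a-c, a-d, b-c ... : verify against the oracle count
  expect_equal(spm$edges$usage[spm$edges$i == 2 & spm$edges$j == 3],
               oracle$edge_usage[2, 3])
  expect_equal(unname(spm$node_usage), oracle$node_usage)
})

test_that("disconnected graphs trace no paths", {
  len <- matrix(Inf, 4, 4)
  kg <- graph_from_lengths(len)
  spm <- shortest_path_map(kg)
  expect_equal(spm$n_pairs, 0L)
  expect_equal(nrow(spm$edges), 0L)
  expect_true(all(spm$node_usage == 0))
})

test_that("random graphs agree exactly with the Floyd-Warshall oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:12, 1)
    len <- random_length_matrix(n)
    kg <- graph_from_lengths(len)
    spm <- shortest_path_map(kg, keep_frac = 0)
    oracle <- spm_oracle(len)
    expect_equal(spm$path_lengths, oracle$dist, tolerance = 1e-9)
    got <- matrix(0L, n, n)
    if (nrow(spm$edges)) {
      got[cbind(spm$edges$i, spm$edges$j)] <- spm$edges$usage
    }
    expect_identical(got, oracle$edge_usage)
    expect_identical(unname(spm$node_usage), oracle$node_usage)
    expect_equal(spm$n_pairs, oracle$n_pairs)
    # node/edge count conservation: every traced path of k edges touches k+1
    # nodes, so summed node usage = summed edge usage + number of paths
    expect_equal(sum(spm$node_usage), sum(spm$edges$usage) + spm$n_pairs)
  }
})

test_that("the retained map is invariant to the logarithm base", {
  set.seed(77)
  len <- random_length_matrix(10)
  kg <- graph_from_lengths(len)
  kg10 <- kg
  kg10$edges$length <- kg10$edges$length / log(10)  # base-10 edge lengths
  kg10$graph <- igraph::set_edge_attr(kg10$graph, "weight",
                                      value = kg10$edges$length)
  a <- shortest_path_map(kg, keep_frac = 0.2)
  b <- shortest_path_map(kg10, keep_frac = 0.2)
  expect_identical(a$edges$usage, b$edges$usage)
  expect_identical(a$edges$retained, b$edges$retained)
  expect_identical(a$node_usage, b$node_usage)
})

test_that("region-to-region paths report the best connection", {
  #   1 - 2 (0.1) , 2 - 3 (0.1), 1 - 3 (1.0), 3 - 4 (0.2)
  len <- matrix(Inf, 4, 4)
  len[1, 2] <- len[2, 1] <- 0.1
  len[2, 3] <- len[3, 2] <- 0.1
  len[1, 3] <- len[3, 1] <- 1.0
  len[3, 4] <- len[4, 3] <- 0.2
  kg <- graph_from_lengths(len)

  pb <- path_between(kg, 1, 4)
  expect_equal(pb$best$path, c(1, 2, 3, 4))   # 0.4 beats 1.2 via direct edge
  expect_equal(pb$best$length, 0.4)

  # singleton source = target: trivial zero-length path
  pb0 <- path_between(kg, 2, 2)
  expect_equal(pb0$best$length, 0)
  expect_equal(pb0$best$path, 2)

  # removing the best path's edges must worsen or disconnect the route
  len2 <- len
  len2[1, 2] <- len2[2, 1] <- Inf
  len2[2, 3] <- len2[3, 2] <- Inf
  len2[3, 4] <- len2[4, 3] <- Inf
  pb2 <- suppressWarnings(path_between(graph_from_lengths(len2), 1, 4))
  expect_true(is.null(pb2$best) || pb2$best$length > pb$best$length)

  empty <- matrix(Inf, 4, 4)
  expect_warning(path_between(graph_from_lengths(empty), 1, 4),
                 "no connected")
})

test_that("exported edge tables round-trip exactly", {
  set.seed(5)
  len <- random_length_matrix(8)
  kg <- graph_from_lengths(len)
  spm <- shortest_path_map(kg)
  top <- make_ca_topology(8)
  prefix <- file.path(withr::local_tempdir(), "spm_")
  files <- export_spm(spm, top, prefix)
  expect_true(all(file.exists(files)))
  back <- read_spm_edges(paste0(prefix, "edges.tsv"))
  expect_equal(back$usage, spm$edges$usage)
  expect_equal(back$resno_i, spm$edges$resno_i)
  expect_equal(back$length, spm$edges$length, tolerance = 1e-12)

  # empty map: header-only edge list, script draws nothing
  kg0 <- graph_from_lengths(matrix(Inf, 3, 3))
  spm0 <- shortest_path_map(kg0)
  prefix0 <- file.path(withr::local_tempdir(), "empty_")
  export_spm(spm0, make_ca_topology(3), prefix0)
  expect_equal(nrow(read_spm_edges(paste0(prefix0, "edges.tsv"))), 0L)
})

test_that("sampled correlations feed a graph that recovers planted structure", {
  # strongly coupled consecutive residues give a chain-like retained map
  n <- 10
  top <- make_ca_topology(n)
  K <- 0.3 * (0.85 ^ abs(outer(1:n, 1:n, "-")))
  tr <- make_harmonic_trajectory(harmonic_spec(top, K, seed = 23), 3000)
  cm <- correlation_matrix(tr, reference = ref_xyz(top), superpose = FALSE)
  dm <- average_distance_matrix(tr)
  kg <- build_graph(cm, dm, cutoff = 6)
  spm <- shortest_path_map(kg)
  expect_gt(sum(spm$edges$retained), 0)
  expect_true(all(spm$edges$usage >= 0))
})
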