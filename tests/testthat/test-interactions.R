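test_that("ring stacking criterion follows constructed geometry", {
  # parallel coplanar hexagons 3.5 A apart: stacked
  r1 <- hexagon(c(0, 0, 0), c(0, 0, 1))
  r2 <- hexagon(c(0, 0, 3.5), c(0, 0, 1))
  top <- two_ring_top(r1, r2)
  tr <- static_traj(top, 3)
  sa <- sel_spec(1, atoms = paste0("C", 1:6))
  sb <- sel_spec(2, atoms = paste0("C", 1:6))
  s <- pi_stack_series(tr, sa, sb)
  expect_equal(s$values$distance, rep(3.5, 3), tolerance = 1e-9)
  expect_equal(s$values$angle, rep(0, 3), tolerance = 1e-6)
  expect_equal(s$occupancy, 1)

  # far apart: not stacked
  far <- two_ring_top(r1, hexagon(c(0, 0, 10), c(0, 0, 1)))
  s2 <- pi_stack_series(static_traj(far, 2), sa, sb)
  expect_equal(s2$occupancy, 0)

  # T-shaped (perpendicular) at 4 A: excluded by the default 30 degree cap
  tshape <- two_ring_top(r1, hexagon(c(0, 0, 4), c(1, 0, 0)))
  s3 <- pi_stack_series(static_traj(tshape, 2), sa, sb)
  expect_equal(s3$values$angle[1], 90, tolerance = 1e-6)
  expect_equal(s3$occupancy, 0)

  expect_error(pi_stack_series(tr, sel_spec(1, atoms = c("C1", "C2")), sb),
               "at least 5")
})

test_that("degenerate ring frames are excluded from the denominator", {
  r1 <- hexagon(c(0, 0, 0), c(0, 0, 1))
  r2 <- hexagon(c(0, 0, 3.5), c(0, 0, 1))
  top <- two_ring_top(r1, r2)
  # second frame collapses ring B onto a line
  bad <- ref_xyz(top)
  line <- cbind(seq(0, 5, length.out = 6), 0, 3.5)
  bad[allokin:::atoms2xyz(7:12)] <- as.vector(t(line))
  tr <- kin_trajectory(top, rbind(ref_xyz(top), bad))
  s <- pi_stack_series(tr, sel_spec(1, atoms = paste0("C", 1:6)),
                       sel_spec(2, atoms = paste0("C", 1:6)))
  expect_equal(s$flagged, c(FALSE, TRUE))
  expect_equal(s$occupancy, 1)  # 1 valid frame, stacked
})

test_that("salt-bridge occupancy counts frames under the cutoff", {
  top <- point_top(c("OE1", "NZ"), rbind(c(0, 0, 0), c(3, 0, 0)))
  an <- sel_spec(1, atoms = "OE1")
  cat_ <- sel_spec(2, atoms = "NZ")
  expect_equal(salt_bridge_series(static_traj(top, 4), an, cat_)$occupancy, 1)

  top8 <- point_top(c("OE1", "NZ"), rbind(c(0, 0, 0), c(8, 0, 0)))
  expect_equal(salt_bridge_series(static_traj(top8, 4), an, cat_)$occupancy, 0)

  # alternating 3 A / 8 A: occupancy one half
  xyz <- rbind(c(0, 0, 0, 3, 0, 0), c(0, 0, 0, 8, 0, 0),
               c(0, 0, 0, 3, 0, 0), c(0, 0, 0, 8, 0, 0))
  s <- salt_bridge_series(kin_trajectory(top, xyz), an, cat_)
  expect_equal(s$occupancy, 0.5)
  expect_equal(s$values$distance, c(3, 8, 3, 8))
})

test_that("hydrogen bonds need both distance and angle", {
  mk <- function(acceptor_pos, h_pos = c(1, 0, 0)) {
    point_top(c("N", "H", "O"),
              rbind(c(0, 0, 0), h_pos, acceptor_pos), resno = c(1, 1, 2))
  }
  don <- sel_spec(1, atoms = "N"); hyd <- sel_spec(1, atoms = "H")
  acc <- sel_spec(2, atoms = "O")

  # near-linear 2.8 A bond
  close_lin <- mk(c(2.8, 0.15, 0))
  s <- hbond_series(static_traj(close_lin, 2), don, hyd, acc)
  expect_equal(s$occupancy, 1)
  expect_gt(s$values$angle[1], 135)

  # too far
  s2 <- hbond_series(static_traj(mk(c(5, 0, 0)), 2), don, hyd, acc)
  expect_equal(s2$occupancy, 0)

  # close but bent to ~90 degrees at the hydrogen
  bent <- mk(c(1, 2.6, 0))
  s3 <- hbond_series(static_traj(bent, 2), don, hyd, acc)
  expect_lt(s3$values$angle[1], 135)
  expect_equal(s3$occupancy, 0)

  expect_error(hbond_series(static_traj(close_lin, 2), don, NULL, acc),
               "heavy_only")
  s4 <- hbond_series(static_traj(close_lin, 2), don, NULL, acc,
                     heavy_only = TRUE)
  expect_equal(s4$occupancy, 1)
})

test_that("occupancies respond monotonically to their thresholds", {
  set.seed(30)
  top <- point_top(c("OE1", "NZ"), rbind(c(0, 0, 0), c(4, 0, 0)))
  xyz <- cbind(0, 0, 0, runif(60, 2, 9), 0, 0)
  tr <- kin_trajectory(top, xyz)
  an <- sel_spec(1, atoms = "OE1"); ct <- sel_spec(2, atoms = "NZ")
  occ <- vapply(c(2.5, 3.5, 4.5, 6, 9.5), function(d) {
    salt_bridge_series(tr, an, ct, d_max = d)$occupancy
  }, numeric(1))
  expect_true(all(diff(occ) >= 0))

  # hydrogen bonds: occupancy non-increasing in the angle threshold
  toph <- point_top(c("N", "H", "O"),
                    rbind(c(0, 0, 0), c(1, 0, 0), c(2.8, 0, 0)),
                    resno = c(1, 1, 2))
  xyzh <- t(vapply(runif(60, 0, 2.5), function(dy) {
    c(0, 0, 0, 1, 0, 0, 2.8, dy, 0)
  }, numeric(9)))
  trh <- kin_trajectory(toph, xyzh)
  occh <- vapply(c(90, 120, 150, 170), function(a) {
    hbond_series(trh, sel_spec(1, atoms = "N"), sel_spec(1, atoms = "H"),
                 sel_spec(2, atoms = "O"), angle_min = a)$occupancy
  }, numeric(1))
  expect_true(all(diff(occh) <= 0))
})

test_that("a rigid pair concentrates all RDF mass in its distance bin", {
  top <- point_top(c("P", "Q"), rbind(c(0, 0, 0), c(3.0, 0, 0)))
  tr <- static_traj(top, 5)
  prof <- rdf(tr, sel_spec(1, atoms = "P"), sel_spec(2, atoms = "Q"),
              r_max = 6, bin_width = 0.5)
  expect_equal(sum(prof$counts), 5)
  expect_equal(prof$counts[prof$r == 3.25 | prof$r == 2.75][1] +
                 prof$counts[prof$r == 3.25 | prof$r == 2.75][2],
               5)
  expect_error(rdf(tr, sel_spec(1, atoms = "P"), sel_spec(1, atoms = "P"),
                   6, 0.5), "overlap")
  expect_error(rdf(tr, sel_spec(1, atoms = "P"), sel_spec(2, atoms = "Q"),
                   1, 2), "r_max > bin_width")
})

test_that("RDF normalisation conserves the pair count", {
  set.seed(31)
  m <- 200
  top <- make_ca_topology(m + 1)
  xyz <- t(vapply(1:50, function(f) {
    c(c(0, 0, 0), runif(3 * m, -15, 15))
  }, numeric(3 * (m + 1))))
  tr <- kin_trajectory(top, xyz)
  prof <- rdf(tr, sel_spec(1), sel_spec(2:(m + 1)), r_max = 10,
              bin_width = 1)
  shell_vol <- 4 / 3 * pi * diff(seq(0, 10, 1)^3)
  lhs <- sum(prof$g * shell_vol * prof$mean_density)
  rhs <- sum(prof$counts) / (prof$n_frames * 1)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("occupancy densities obey the min/max overlap arithmetic", {
  g <- grid_spec(c(0, 0, 0), 1, c(4, 1, 1))
  mk_traj <- function(xs) {
    top <- point_top(paste0("A", seq_along(xs)),
                     cbind(xs, 0.5, 0.5), resno = seq_along(xs))
    static_traj(top, 3)
  }
  sel_all <- function(n) sel_spec(1:n, atoms = "all")
  a <- occupancy_density(mk_traj(c(0.5, 1.5)), sel_all(2), g)  # voxels 1,2
  b <- occupancy_density(mk_traj(c(1.5, 2.5)), sel_all(2), g)  # voxels 2,3
  c_ <- occupancy_density(mk_traj(c(3.5)), sel_all(1), g)      # voxel 4

  expect_equal(density_overlap(a, a), 1)
  expect_equal(density_overlap(a, c_), 0)
  expect_equal(density_overlap(a, b), 1 / 3)   # share one of three voxels
  expect_equal(density_overlap(a, b), density_overlap(b, a))

  g2 <- grid_spec(c(0, 0, 0), 0.5, c(8, 2, 2))
  expect_error(density_overlap(a, occupancy_density(mk_traj(0.5),
                                                    sel_all(1), g2)),
               "congruent")
  # grid must cover the selection
  expect_error(occupancy_density(mk_traj(9), sel_all(1), g), "cover")
})

test_that("density files are written as parseable OpenDX text", {
  g <- grid_spec(c(0, 0, 0), 1, c(2, 2, 2))
  top <- point_top("A1", matrix(c(0.5, 0.5, 0.5), 1), resno = 1)
  d <- occupancy_density(static_traj(top, 2), sel_spec(1, atoms = "all"), g)
  f <- withr::local_tempfile(fileext = ".dx")
  write_density_dx(d, f)
  txt <- readLines(f)
  expect_match(txt[1], "gridpositions counts 2 2 2")
  vals <- as.numeric(unlist(strsplit(txt[-(1:7)], " ")))
  expect_equal(sum(vals), sum(d$values))
})
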