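test_that("PDB structure round-trip preserves atoms and coordinates", {
  top <- make_backbone_topology(5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(top, f)
  back <- load_structure(f)
  expect_equal(natoms(back), natoms(top))
  expect_equal(back$atoms$elety, top$atoms$elety)
  expect_equal(back$atoms$resno, top$atoms$resno)
  # PDB stores 3 decimals
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(top$atoms[, c("x", "y", "z")]),
               tolerance = 2e-3, ignore_attr = TRUE)
})

test_that("missing chains and models are reported with what is available", {
  top <- make_ca_topology(4)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(top, f)
  expect_error(load_structure(f, chain = "Z"), "available chains: A")
  expect_error(load_structure(f, model = 3), "model")
})

test_that("multi-file loading concatenates frames with replica bounds", {
  top <- make_ca_topology(6)
  tr10 <- make_harmonic_trajectory(harmonic_spec(top, 0.01, seed = 1), 10)
  f1 <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tr10, f1)
  got <- load_trajectory(top, f1)
  expect_equal(nframes(got), 10)
  expect_equal(got$replica_bounds, 1L)

  # six independent 5-frame replicas pooled into one metatrajectory
  files <- vapply(1:6, function(k) tempfile(fileext = ".pdb"), character(1))
  withr::defer(unlink(files))
  for (k in 1:6) {
    trk <- make_harmonic_trajectory(harmonic_spec(top, 0.01, seed = k), 5)
    write_trajectory(trk, files[k])
  }
  meta <- load_trajectory(top, files)
  expect_equal(nframes(meta), 30)
  expect_equal(meta$replica_bounds, c(1L, 6L, 11L, 16L, 21L, 26L))
  expect_equal(replica_of(meta), rep(1:6, each = 5))
})

test_that("atom-count mismatches name the offending file", {
  top6 <- make_ca_topology(6)
  top4 <- make_ca_topology(4)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(static_traj(top4, 3), f)
  expect_error(load_trajectory(top6, f), "atom count mismatch")
  expect_error(load_trajectory(top6, f), basename(f))
})

test_that("reduction keeps the requested atoms and the residue mapping", {
  top <- make_backbone_topology(150)
  top$atoms$resno <- top$atoms$resno + 100L  # number residues 101-250
  tr <- static_traj(top, 3)
  red <- reduce_trajectory(tr, sel_spec("111-140", atoms = "backbone"))
  expect_equal(natoms(red), 30 * 4)
  expect_equal(sort(unique(red$top$atoms$resno)), 111:140)
  expect_equal(nframes(red), 3)

  ca <- reduce_trajectory(tr, sel_spec(atoms = "CA"))
  expect_equal(natoms(ca), 150)
  expect_error(reduce_trajectory(tr, sel_spec("900-950")), "zero atoms")
})

test_that("superposition undoes rigid-body motion exactly", {
  top <- make_ca_topology(12)
  tr <- rigid_body_traj(top, 20, seed = 4)
  sup <- superpose_trajectory(tr, ref_xyz(top), sel_spec(atoms = "CA"))
  for (f in seq_len(nframes(sup))) {
    expect_lt(rmsd_xyz(get_frame(sup, f), ref_xyz(top)), 1e-6)
  }
})

test_that("the fit transform is rigid: non-fit atoms move consistently", {
  top <- make_backbone_topology(10)
  set.seed(5)
  noisy <- kin_trajectory(top, t(vapply(1:5, function(f) {
    apply_rigid(ref_xyz(top) + rnorm(natoms(top) * 3, sd = 0.2),
                random_rotation(), rnorm(3, sd = 4))
  }, numeric(3 * natoms(top)))))
  sup <- superpose_trajectory(noisy, 1L, sel_spec("1-4", atoms = "backbone"))
  # intra-frame distances are invariant under the applied transform
  for (f in 1:5) {
    before <- dist(matrix(get_frame(noisy, f), ncol = 3, byrow = TRUE))
    after <- dist(matrix(get_frame(sup, f), ncol = 3, byrow = TRUE))
    expect_equal(as.vector(after), as.vector(before), tolerance = 1e-6)
  }
})

test_that("least-squares fitting never increases the RMSD", {
  top <- make_ca_topology(15)
  set.seed(6)
  for (k in 1:5) {
    frame <- ref_xyz(top) + rnorm(3 * natoms(top), sd = 3)
    tr <- kin_trajectory(top, matrix(frame, nrow = 1))
    pre <- rmsd_xyz(frame, ref_xyz(top))
    sup <- superpose_trajectory(tr, ref_xyz(top), sel_spec(atoms = "CA"))
    expect_lte(rmsd_xyz(get_frame(sup, 1), ref_xyz(top)), pre + 1e-12)
  }
})

test_that("superposition agrees with the reference implementation", {
  top <- make_ca_topology(20)
  tr <- rigid_body_traj(top, 10, seed = 7)
  ref <- ref_xyz(top)
  ours <- superpose_trajectory(tr, ref, sel_spec(atoms = "CA"))
  theirs <- bio3d::fit.xyz(fixed = ref, mobile = tr$xyz,
                           fixed.inds = 1:(3 * natoms(top)),
                           mobile.inds = 1:(3 * natoms(top)))
  expect_equal(ours$xyz, theirs, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("superposition is idempotent", {
  top <- make_ca_topology(10)
  tr <- make_harmonic_trajectory(harmonic_spec(top, 0.5, seed = 3), 8)
  once <- superpose_trajectory(tr, 1L, sel_spec(atoms = "CA"))
  twice <- superpose_trajectory(once, 1L, sel_spec(atoms = "CA"))
  expect_equal(twice$xyz, once$xyz, tolerance = 1e-6)
})

test_that("reduce and superpose commute on a shared selection", {
  top <- make_backbone_topology(12)
  tr <- rigid_body_traj(top, 6, seed = 8)
  sel <- sel_spec(NULL, atoms = "CA")
  a <- reduce_trajectory(superpose_trajectory(tr, 1L, sel), sel)
  b <- superpose_trajectory(reduce_trajectory(tr, sel), 1L, sel)
  expect_equal(a$xyz, b$xyz, tolerance = 1e-6)
})

test_that("cross-structure RMSD pairs atoms by residue number and name", {
  top <- make_backbone_topology(8)
  expect_equal(rmsd_structures(top, top), 0)

  shifted <- top
  shifted$atoms$x <- shifted$atoms$x + 5  # pure translation
  expect_equal(rmsd_structures(top, shifted, fit = TRUE), 0, tolerance = 1e-9)
  expect_equal(rmsd_structures(top, shifted, fit = FALSE), 5, tolerance = 1e-9)

  # partial residue overlap: only shared residues are compared
  part <- top
  part$atoms <- part$atoms[part$atoms$resno %in% 3:8, ]
  expect_equal(rmsd_structures(top, part), 0, tolerance = 1e-9)

  expect_equal(rmsd_structures(top, shifted, fit = FALSE),
               rmsd_structures(shifted, top, fit = FALSE), tolerance = 1e-12)
  other <- make_ca_topology(5)
  other$atoms$resno <- other$atoms$resno + 100L
  expect_error(rmsd_structures(top, other), "no common atoms")
})

test_that("average structure is the per-atom mean", {
  top <- make_ca_topology(7)
  same <- static_traj(top, 4)
  expect_equal(average_structure(same), ref_xyz(top), ignore_attr = TRUE)

  # two frames symmetric about the reference average to the reference
  offs <- rnorm(3 * natoms(top), sd = 1)
  two <- kin_trajectory(top, rbind(ref_xyz(top) + offs, ref_xyz(top) - offs))
  expect_equal(average_structure(two), ref_xyz(top), ignore_attr = TRUE)
})

test_that("periodic-imaging jumps are caught at load time", {
  top <- make_ca_topology(5)
  xyz <- rbind(ref_xyz(top), ref_xyz(top))
  xyz[2, 1] <- xyz[2, 1] + 50  # one atom jumps 50 A between frames
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(kin_trajectory(top, xyz), f)
  expect_error(load_trajectory(top, f), "wrapped")
  expect_silent(load_trajectory(top, f, check_jumps = FALSE))
})

test_that("trajectory coordinates survive a PDB round-trip", {
  top <- make_ca_topology(6)
  tr <- make_harmonic_trajectory(harmonic_spec(top, 0.2, seed = 5), 7)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tr, f)
  back <- load_trajectory(top, f)
  expect_equal(back$xyz, tr$xyz, tolerance = 2e-3, ignore_attr = TRUE)
})

test_that("the Gram-matrix pairwise RMSD equals the direct computation", {
  set.seed(33)
  X <- matrix(rnorm(20 * 18), 20, 18)  # 20 frames, 6 atoms
  fast <- allokin:::pairwise_rmsd(X)
  direct <- as.matrix(dist(X)) / sqrt(6)
  expect_equal(fast, direct, tolerance = 1e-10, ignore_attr = TRUE)
})
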