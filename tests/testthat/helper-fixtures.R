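# Shared fixtures: deterministic geometry builders and rigid-motion helpers.

# uniform random rotation matrix (quaternion method)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

apply_rigid <- function(frame_vec, rot, shift) {
  m <- matrix(frame_vec, ncol = 3, byrow = TRUE) %*% t(rot)
  as.vector(t(sweep(m, 2, shift, "+")))
}

# trajectory whose frames are random rigid transforms of the topology coords
rigid_body_traj <- function(top, n_frames, seed = 1) {
  ref <- as.vector(t(as.matrix(top$atoms[, c("x", "y", "z")])))
  set.seed(seed)
  xyz <- t(vapply(seq_len(n_frames), function(f) {
    apply_rigid(ref, random_rotation(), stats::rnorm(3, sd = 10))
  }, numeric(length(ref))))
  kin_trajectory(top, xyz)
}

ref_xyz <- function(top) as.vector(t(as.matrix(top$atoms[, c("x", "y", "z")])))

# standard two-state loop fixture: 24-residue backbone helix, 8-residue loop
# displaced rigidly by `shift` Angstrom between states
two_state_fixture <- function(p_a = 0.6, sigma = 0.5, shift = 8, seed = 1) {
  top <- make_backbone_topology(24)
  loop <- sel_spec("9-16", atoms = "backbone")
  conf_a <- as.matrix(top$atoms[resolve_selection(top, loop),
                                c("x", "y", "z")])
  spec <- two_state_spec(top, loop, conf_a = conf_a,
                         conf_b = sweep(conf_a, 2, c(shift, 0, 0), "+"),
                         p_a = p_a, sigma = sigma, seed = seed)
  config <- cluster_config(loop = "9-16", anchor = "5-8,17-20",
                           atoms = "backbone",
                           stable_ss = sel_spec(c(2:8, 17:23),
                                                atoms = "backbone"),
                           epsilon = 5)
  list(spec = spec, config = config)
}

# planar hexagonal ring centred at `centre`, normal along `normal`
hexagon <- function(centre, normal, radius = 1.4) {
  normal <- normal / sqrt(sum(normal^2))
  seed_v <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- seed_v - sum(seed_v * normal) * normal
  u <- u / sqrt(sum(u^2))
  v <- c(normal[2] * u[3] - normal[3] * u[2],
         normal[3] * u[1] - normal[1] * u[3],
         normal[1] * u[2] - normal[2] * u[1])
  ang <- (0:5) * pi / 3
  t(vapply(ang, function(a) {
    centre + radius * (cos(a) * u + sin(a) * v)
  }, numeric(3)))
}

# topology holding two 6-atom rings as residues 1 and 2
two_ring_top <- function(ring1, ring2) {
  kin_structure(data.frame(
    elety = rep(paste0("C", 1:6), 2), elesy = "C",
    resno = rep(1:2, each = 6), resid = "RNG", chain = "A",
    x = c(ring1[, 1], ring2[, 1]),
    y = c(ring1[, 2], ring2[, 2]),
    z = c(ring1[, 3], ring2[, 3]),
    stringsAsFactors = FALSE))
}

# small structure with named atoms at explicit coordinates (one chain)
point_top <- function(names, coords, resno = seq_along(names)) {
  kin_structure(data.frame(
    elety = names, elesy = substr(names, 1, 1), resno = resno,
    resid = "PNT", chain = "A",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    stringsAsFactors = FALSE))
}

static_traj <- function(top, n_frames = 2) {
  kin_trajectory(top, matrix(rep(ref_xyz(top), n_frames),
                             nrow = n_frames, byrow = TRUE))
}
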