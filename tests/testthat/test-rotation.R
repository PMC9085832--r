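test_that("pore superposition removes rigid motion and matches a quaternion oracle", {
  start <- toy_start()
  X0 <- get_frame(start, 1)
  pore <- resolve_selection(start$topology, selection_spec(428:444, 0:3, "CA"))
  # identity
  s0 <- superimpose_pore(X0, X0, pore)
  expect_equal(s0$rmsd, 0, tolerance = 1e-10)
  expect_equal(s0$coords, X0, tolerance = 1e-10)
  # pure translation is removed exactly
  Xt <- X0 + matrix(c(10, 0, 0), nrow(X0), 3, byrow = TRUE)
  st <- superimpose_pore(Xt, X0, pore)
  expect_equal(st$rmsd, 0, tolerance = 1e-10)
  # random deformation: RMSD equals the quaternion-based oracle
  set.seed(31)
  for (k in 1:10) {
    X <- X0 + matrix(rnorm(length(X0), 0, 0.5), nrow(X0), 3)
    R <- random_rotation_matrix()
    X <- X %*% R + matrix(rnorm(3, 0, 10), nrow(X0), 3, byrow = TRUE)
    s <- superimpose_pore(X, X0, pore)
    expect_equal(s$rmsd,
                 quaternion_superpose_rmsd(X[pore, ], X0[pore, ]),
                 tolerance = 1e-8)
    # the fit never increases the RMSD over the unfitted coordinates
    raw <- sqrt(mean(rowSums((X[pore, ] - X0[pore, ])^2)))
    expect_lte(s$rmsd, raw + 1e-12)
  }
  # collinear selections are rejected
  line <- cbind(1:5, 0, 0)
  expect_error(channelrot:::kabsch_fit(line, line + 1), "collinear")
})

test_that("the rotation reference puts the pore points on the symmetry axis and the elbow centroids per subunit", {
  start <- toy_start()
  X0 <- get_frame(start, 1)
  topo <- start$topology
  ref <- build_rotation_reference(X0, topo)
  # C4 symmetry forces II and III onto the z axis
  expect_lt(max(abs(ref$point_II[1:2])), 1e-10)
  expect_lt(max(abs(ref$point_III[1:2])), 1e-10)
  # point I is the centroid of exactly 4 C-alphas of residues 460-463
  for (s in 0:3) {
    idx <- resolve_selection(topo, selection_spec(460:463, s, "CA"))
    expect_length(idx, 4)
    expect_equal(ref$point_I[[s + 1]], colMeans(X0[idx, ]))
  }
  expect_error(
    build_rotation_reference(X0, topo, elbow_res = 900:903),
    "elbow")
})

test_that("the dihedral metric reports azimuthal displacement with the documented sign convention", {
  # no azimuthal displacement: 0 degrees
  expect_equal(dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1),
                              c(1, 0, 1)), 0)
  # quarter turn: |angle| = 90, sign checked against the oracle
  a <- dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(0, 1, 1))
  expect_equal(abs(a), 90)
  expect_equal(a, dihedral_oracle(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1),
                                  c(0, 1, 1)))
  # degenerate: IV on the axis
  expect_error(dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1),
                              c(0, 0, 2)), "degenerate")
  # exact block rotations are recovered angle-for-angle over a sweep
  start <- toy_start()
  ref <- build_rotation_reference(get_frame(start, 1), start$topology)
  for (theta in c(-30, -5, -0.5, 0.5, 5, 30)) {
    e <- generate_rotated_ensemble(start, 1, 1, rotation_mean = theta,
                                   rotation_sd = 0, seed = 1)
    rs <- rotation_summary(e, ref)
    expect_equal(rs$per_run$angle, rep(theta, 4), tolerance = 1e-9)
  }
  # the starting structure itself measures 0 on every subunit
  rs0 <- rotation_summary(start, ref)
  expect_equal(rs0$per_run$angle, rep(0, 4), tolerance = 1e-10)
  expect_equal(rs0$sem, 0)
})

test_that("rotation angles are invariant under global rigid-body transforms of the frames", {
  start <- toy_start()
  e <- generate_rotated_ensemble(start, 2, 4, rotation_mean = 4,
                                 rotation_sd = 2, noise_amplitude = 0.05,
                                 seed = 41)
  ref <- build_rotation_reference(get_frame(start, 1), start$topology)
  base <- rotation_summary(e, ref)
  set.seed(43)
  for (k in 1:3) {
    e_t <- apply_rigid(e, random_rotation_matrix(), rnorm(3, 0, 25))
    expect_equal(rotation_summary(e_t, ref)$per_run$angle,
                 base$per_run$angle, tolerance = 1e-7)
  }
})

test_that("per-run averaging and the grand mean follow the subunit x replica bookkeeping", {
  start <- toy_start()
  e <- generate_rotated_ensemble(start, n_replicas = 5, n_frames = 20,
                                 rotation_mean = 2, rotation_sd = 1,
                                 seed = 47)
  ref <- build_rotation_reference(get_frame(start, 1), start$topology)
  rs <- rotation_summary(e, ref)
  expect_equal(rs$n, 20)  # 4 subunits x 5 replicas
  # per-run means equal the generator's drawn-angle means
  tru <- aggregate(theta ~ subunit + replica, e$truth, mean)
  got <- rs$per_run[order(rs$per_run$replica, rs$per_run$subunit), ]
  tru <- tru[order(tru$replica, tru$subunit), ]
  expect_equal(got$angle, tru$theta, tolerance = 1e-9)
})

test_that("the ensemble-average structure is the coordinate-wise mean in the aligned frame", {
  start <- toy_start()
  X0 <- get_frame(start, 1)
  expect_equal(average_structure(start), X0)
  # two frames mirrored about X0: average is X0
  topo <- start$topology
  delta <- matrix(rnorm(length(X0), 0, 0.1), nrow(X0), 3)
  coords <- array(c(X0 + delta, X0 - delta), c(nrow(X0), 3, 2))
  e2 <- channel_ensemble(topo, coords)
  expect_equal(average_structure(e2), X0, tolerance = 1e-10)
  # noisy ensemble: average approaches the base structure as 1/sqrt(n)
  e <- generate_rotated_ensemble(start, 1, 400, noise_amplitude = 0.2,
                                 seed = 53)
  avg <- average_structure(e)
  expect_lt(max(abs(avg - X0)), 0.2 / sqrt(400) * 6)
})
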