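test_that("the hydrogen-bond criterion combines distance and donor-H-acceptor angle", {
  # collinear D-H-A at 2.0 A: both criteria met
  f <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_true(detect_hbond(f, 1, 3, 2))
  # distance 3.6 A exceeds the 3.5 A cutoff regardless of angle
  f2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 3.6))
  expect_false(detect_hbond(f2, 1, 3, 2))
  # acceptor constructed by explicit rotation to a 110 degree
  # donor-H-acceptor angle at d = 2.8 A: angle criterion fails
  D <- c(0, 0, 0); H <- c(1, 0, 0)
  ang <- 110 * pi / 180
  # acceptor on the cone around H: direction at (180 - 110) from -DH
  w <- c(cos(pi - ang), sin(pi - ang), 0)
  L <- uniroot(function(L) sqrt(sum((H + L * w - D)^2)) - 2.8, c(0.1, 5))$root
  A <- H + L * w
  check <- acos(sum((D - H) * (A - H)) /
                  (sqrt(sum((D - H)^2)) * sqrt(sum((A - H)^2)))) * 180 / pi
  expect_equal(check, 110, tolerance = 1e-6)
  f3 <- rbind(D, H, A)
  expect_false(detect_hbond(f3, 1, 3, 2))
  # the same geometry passes once the angle cutoff is relaxed below 110
  expect_true(detect_hbond(f3, 1, 3, 2, angle_cutoff = 100))
  # distance-only mode when no hydrogens are present
  expect_true(detect_hbond(f3, 1, 3, integer(0)))
  # hydrogen coincident with the donor: degenerate angle, criterion fails
  f4 <- rbind(D, D, c(2, 0, 0))
  expect_false(detect_hbond(f4, 1, 3, 2))
})

test_that("contact frequencies count frames with any passing donor/acceptor combination", {
  start <- toy_start()
  def <- contact_definition(464, "sidechain-N", 155, "backbone-O",
                            "opposite")
  # scripted 7-of-10 occupancy on every subunit pair
  X0 <- get_frame(start, 1)
  topo <- start$topology
  coords <- array(rep(X0, 10), c(nrow(X0), 3, 10))
  o_idx <- resolve_selection(topo, selection_spec(155, 0:3, "backbone-O"))
  for (fi in 1:3) coords[o_idx, 3, fi] <- coords[o_idx, 3, fi] + 10
  e <- channel_ensemble(topo, coords)
  cf <- contact_frequency(e, def)
  expect_equal(unique(cf$per_pair_per_replica$frequency), 0.7)
  expect_equal(cf$mean, 0.7)
  expect_equal(cf$n, 4)
  # bounds: all frames bonded / none bonded
  e1 <- generate_contact_trajectory(start, p = 1, n_frames = 20, seed = 1)
  e0 <- generate_contact_trajectory(start, p = 0, n_frames = 20, seed = 1)
  expect_equal(contact_frequency(e1, def)$mean, 1)
  expect_equal(contact_frequency(e0, def)$mean, 0)
})

test_that("contact frequency is monotone in the cutoffs", {
  start <- toy_start()
  e <- generate_contact_trajectory(start, p = 0.5, n_frames = 50,
                                   d_on = 3.3, d_off = 3.8, seed = 3)
  freqs_d <- vapply(c(3.0, 3.5, 4.0), function(dc)
    contact_frequency(e, contact_definition(
      464, "sidechain-N", 155, "backbone-O", "opposite",
      distance_cutoff = dc))$mean, numeric(1))
  expect_false(is.unsorted(freqs_d))
  freqs_a <- vapply(c(100, 140, 175), function(ac)
    contact_frequency(e, contact_definition(
      464, "sidechain-N", 155, "backbone-O", "opposite",
      angle_cutoff = ac))$mean, numeric(1))
  expect_false(is.unsorted(rev(freqs_a)))
})

test_that("minimum selection distance matches the exhaustive pairwise search", {
  f <- rbind(c(0, 0, 0), c(0, 0, 5.2))
  expect_equal(min_distance(f, 1, 1), 0)
  expect_equal(min_distance(f, 1, 2), 5.2)
  set.seed(11)
  for (k in 1:20) {
    X <- matrix(rnorm(30 * 3, 0, 5), 30, 3)
    ia <- sample(30, 6); ib <- sample(30, 8)
    brute <- min(vapply(ia, function(i) min(vapply(ib, function(j)
      sqrt(sum((X[i, ] - X[j, ])^2)), numeric(1))), numeric(1)))
    expect_equal(min_distance(X, ia, ib), brute, tolerance = 1e-12)
  }
  expect_error(min_distance(f, integer(0), 1), "non-empty")
})

test_that("salt bridges reuse the donor/acceptor machinery on charged groups and check residue chemistry", {
  start <- toy_start()
  expect_error(salt_bridge_frequency(start, 155, 243), "not basic")
  expect_error(salt_bridge_frequency(start, 464, 155), "not acidic")
  # scripted occupancy p = 0.25 between K464 and E247 side-chain oxygens
  e <- generate_contact_trajectory(start, 464, "sidechain-N",
                                   247, "sidechain-O", p = 0.25,
                                   n_frames = 200, seed = 13)
  sb <- salt_bridge_frequency(e, 464, 247)
  expect_equal(sb$mean, mean(e$truth$bonded))
  n_draw <- nrow(e$truth)
  expect_lt(abs(sb$mean - 0.25), 2.576 * sqrt(0.25 * 0.75 / n_draw))
  # distance-only mode is flagged
  sb2 <- salt_bridge_frequency(e, 464, 247, angle = FALSE)
  expect_true(sb2$distance_only)
  expect_gte(sb2$mean, sb$mean)
})

test_that("occurrence frequencies are invariant under a global rigid-body transform", {
  start <- toy_start()
  e <- generate_contact_trajectory(start, p = 0.4, n_frames = 40, seed = 17)
  set.seed(23)
  e_t <- apply_rigid(e, random_rotation_matrix(), rnorm(3, 0, 30))
  def <- contact_definition(464, "sidechain-N", 155, "backbone-O",
                            "opposite")
  expect_equal(contact_frequency(e_t, def)$per_pair_per_replica$frequency,
               contact_frequency(e, def)$per_pair_per_replica$frequency)
})
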