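# Independent oracles used to cross-check the package's geometry engines.
# These deliberately use different formulations than the implementation.

# Horn's quaternion-based absolute orientation: least-squares rigid fit
# of P onto Q via the largest eigenvector of the 4x4 quaternion matrix.
quaternion_superpose_rmsd <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  S <- crossprod(Pc, Qc)
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  fitted <- Pc %*% t(R)
  sqrt(mean(rowSums((fitted - Qc)^2)))
}

# Dihedral via normalized plane normals, acos magnitude and the sign of
# the triple product (no atan2).
dihedral_oracle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  crs <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                          a[3] * b[1] - a[1] * b[3],
                          a[1] * b[2] - a[2] * b[1])
  n1 <- crs(b1, b2); n2 <- crs(b2, b3)
  n1 <- n1 / sqrt(sum(n1^2)); n2 <- n2 / sqrt(sum(n2^2))
  ang <- acos(max(-1, min(1, sum(n1 * n2)))) * 180 / pi
  s <- sign(sum(crs(n1, n2) * b2))
  if (s < 0) -ang else ang
}

# Plain-loop hydrogen-bond detector (the O(N^2) brute force).
brute_hbond <- function(frame, donor, acceptor, hydrogens, dist_cut,
                        ang_cut) {
  d <- sqrt(sum((frame[donor, ] - frame[acceptor, ])^2))
  if (d > dist_cut) return(FALSE)
  if (length(hydrogens) == 0) return(TRUE)
  for (h in hydrogens) {
    u <- frame[donor, ] - frame[h, ]
    v <- frame[acceptor, ] - frame[h, ]
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu < 1e-12 || nv < 1e-12) next
    ang <- acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
    if (ang >= ang_cut) return(TRUE)
  }
  FALSE
}

random_rotation_matrix <- function() {
  # QR of a Gaussian matrix, determinant forced positive
  M <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

apply_rigid <- function(ensemble, R, t) {
  for (k in seq_len(dim(ensemble$coords)[3]))
    ensemble$coords[, , k] <- ensemble$coords[, , k] %*% R +
      matrix(t, dim(ensemble$coords)[1], 3, byrow = TRUE)
  ensemble
}

toy_start <- function() build_toy_tetramer()
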