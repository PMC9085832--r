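#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation + translation minimising the RMSD of `P`
#' onto `Q` (no scaling, no reflection), via SVD of the covariance
#' matrix with the usual determinant sign correction.
#'
#' @param P,Q n x 3 matrices of matched coordinates (n >= 3, not
#'   collinear)
#' @return list with `R` (3x3 rotation), `t` (translation, so that the
#'   fitted P is `P %*% R + t`), `rmsd`
#' @keywords internal
kabsch_fit <- function(P, Q) {
  if (nrow(P) < 3) stop("superposition needs at least 3 atoms")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  if (min(s$d) < 1e-10 && sum(s$d > 1e-10) < 2)
    stop("degenerate (collinear) selection: superposition undefined")
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  tvec <- cq - cp %*% R
  fitted <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  list(R = R, t = as.numeric(tvec), rmsd = rmsd)
}

#' Superimpose a frame's pore onto a reference frame
#'
#' The optimal rigid-body fit is computed over the pore selection and
#' then applied to the whole frame; the returned RMSD is over the pore
#' atoms only.
#'
#' @param frame,reference_frame n_atoms x 3 coordinate matrices sharing
#'   one topology
#' @param pore_idx atom indices (>= 3, non-collinear) used for the fit
#' @return list with `coords` (transformed frame) and `rmsd` (Angstrom)
#' @export
superimpose_pore <- function(frame, reference_frame, pore_idx) {
  fit <- kabsch_fit(frame[pore_idx, , drop = FALSE],
                    reference_frame[pore_idx, , drop = FALSE])
  coords <- frame %*% fit$R + matrix(fit$t, nrow(frame), 3, byrow = TRUE)
  list(coords = coords, rmsd = fit$rmsd)
}

#' Signed four-point dihedral angle, degrees
#'
#' atan2 formulation (stable near 0 and 180 degrees); result in
#' (-180, 180].
#'
#' @param p1,p2,p3,p4 3-vectors
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  nb2 <- vnorm(b2)
  if (nb2 < 1e-12 || vnorm(n1) < 1e-12 || vnorm(n2) < 1e-12)
    stop("degenerate dihedral geometry")
  x <- sum(n1 * n2)
  y <- sum(pracma_cross(n1, n2) * b2) / nb2
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build the static rotation reference from a starting structure
#'
#' Reference points for the C-linker/CNBD rotation dihedral, defined on
#' the starting structure after the convention of COM-based domain
#' rotation analysis:
#' \describe{
#'   \item{point I (per subunit)}{centroid of the C-alpha atoms of the
#'     elbow terminal residues (default 460-463, the A'-helix tip)}
#'   \item{point II}{centroid of the C-alpha atoms of the upper pore
#'     residue (default T436) over all four subunits}
#'   \item{point III}{same for the lower pore residue (default I432)}
#' }
#' Point IV is dynamic: the per-frame elbow centroid of each subunit.
#' Points II and III lie on the pore axis for a symmetric channel, so
#' the dihedral I-II-III-IV measures the azimuthal displacement of the
#' elbow around that axis.
#'
#' @param start_frame n_atoms x 3 coordinates of the starting structure
#' @param topology a [channel_topology()]
#' @param elbow_res residue numbers of the elbow terminus (default
#'   460:463)
#' @param pore_res_upper,pore_res_lower single residues defining the
#'   axis (defaults 436 and 432)
#' @param pore_selection [selection_spec()] used for pore superposition
#'   (default C-alpha of residues 428-444, all subunits)
#' @param clockwise_positive sign convention: TRUE (default) reports
#'   rotations that appear clockwise viewed from the intracellular side
#'   as positive (the negated raw dihedral); FALSE reports the raw
#'   I-II-III-IV dihedral
#' @return object of class `rotation_reference`
#' @export
build_rotation_reference <- function(start_frame, topology,
                                     elbow_res = 460:463,
                                     pore_res_upper = 436,
                                     pore_res_lower = 432,
                                     pore_selection = selection_spec(
                                       428:444, 0:3, "CA"),
                                     clockwise_positive = TRUE) {
  elbow_idx <- lapply(0:3, function(s) {
    idx <- resolve_selection(topology, selection_spec(elbow_res, s, "CA"),
                             allow_empty = TRUE)
    if (length(idx) == 0)
      stop("no C-alpha atoms for elbow residues ",
           paste(range(elbow_res), collapse = "-"), " on subunit ", s)
    idx
  })
  up_idx <- resolve_selection(topology, selection_spec(pore_res_upper, 0:3, "CA"))
  lo_idx <- resolve_selection(topology, selection_spec(pore_res_lower, 0:3, "CA"))
  point_I <- lapply(elbow_idx, function(idx)
    colMeans(start_frame[idx, , drop = FALSE]))
  point_II <- colMeans(start_frame[up_idx, , drop = FALSE])
  point_III <- colMeans(start_frame[lo_idx, , drop = FALSE])
  if (vnorm(point_II - point_III) < 1e-9)
    stop("upper and lower pore points coincide: rotation axis undefined")
  pore_idx <- resolve_selection(topology, pore_selection)
  structure(list(point_I = point_I, point_II = point_II,
                 point_III = point_III, elbow_idx = elbow_idx,
                 pore_idx = pore_idx, start_frame = start_frame,
                 clockwise_positive = clockwise_positive),
            class = "rotation_reference")
}

#' Rotation angle of one subunit's elbow in one frame
#'
#' The frame must already be pore-superimposed onto the starting
#' structure (as [rotation_summary()] does). Computes the signed
#' dihedral between the static half-plane through point I and the
#' dynamic half-plane through point IV, both hinged on the II-III axis.
#'
#' @param frame pore-superimposed n_atoms x 3 coordinates
#' @param reference a [build_rotation_reference()]
#' @param subunit subunit index 0..3
#' @return degrees, in (-180, 180]
#' @export
rotation_angle <- function(frame, reference, subunit) {
  point_IV <- colMeans(frame[reference$elbow_idx[[subunit + 1L]], ,
                             drop = FALSE])
  ang <- dihedral_angle(reference$point_I[[subunit + 1L]],
                        reference$point_II, reference$point_III, point_IV)
  if (reference$clockwise_positive) ang <- -ang
  if (ang <= -180) ang <- ang + 360
  if (ang > 180) ang <- ang - 360
  ang
}

#' Rotation summary over an ensemble
#'
#' Every frame is pore-superimposed onto the starting structure held in
#' the reference, per-frame angles are computed for all four subunits,
#' averaged within each (subunit, replica), and summarised as grand mean
#' +/- SEM over those n = 4 x replicas values.
#'
#' @param ensemble a [channel_ensemble()]
#' @param reference a [build_rotation_reference()] built on the same
#'   topology
#' @return object of class `rotation_series`: `angles` (long data.frame:
#'   subunit, replica, frame, angle), `per_run` (subunit, replica, mean
#'   angle), `mean`, `sem`, `n`
#' @export
rotation_summary <- function(ensemble, reference) {
  nf <- n_frames(ensemble)
  rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    sup <- superimpose_pore(get_frame(ensemble, f), reference$start_frame,
                            reference$pore_idx)
    ang <- vapply(0:3, function(s) rotation_angle(sup$coords, reference, s),
                  numeric(1))
    rows[[f]] <- data.frame(subunit = 0:3, replica = ensemble$replica[f],
                            frame = f, angle = ang)
  }
  angles <- do.call(rbind, rows)
  per_run <- aggregate(angle ~ subunit + replica, angles, mean)
  structure(list(angles = angles, per_run = per_run,
                 mean = mean(per_run$angle), sem = sem(per_run$angle),
                 n = nrow(per_run)),
            class = "rotation_series")
}

#' @export
print.rotation_series <- function(x, ...) {
  cat(sprintf("rotation: %.3f deg +/- %.3f (SEM, n = %d)\n",
              x$mean, x$sem, x$n))
  invisible(x)
}

#' Ensemble-average structure
#'
#' Coordinate-wise mean over all frames after superimposing each frame
#' onto the first frame over `align_idx` (pore C-alpha by convention).
#' With `align_idx = NULL` no alignment is performed.
#'
#' @param ensemble a [channel_ensemble()]
#' @param align_idx atom indices used for the superposition, or NULL
#' @return n_atoms x 3 matrix
#' @export
average_structure <- function(ensemble, align_idx = NULL) {
  nf <- n_frames(ensemble)
  if (nf < 1) stop("ensemble has no frames")
  ref <- get_frame(ensemble, 1)
  acc <- matrix(0, n_atoms(ensemble), 3)
  for (f in seq_len(nf)) {
    X <- get_frame(ensemble, f)
    if (!is.null(align_idx) && f > 1)
      X <- superimpose_pore(X, ref, align_idx)$coords
    acc <- acc + X
  }
  acc / nf
}
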