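#' Define an inter-subunit contact
#'
#' A contact couples a donor residue on subunit role "i" with an acceptor
#' residue on the adjacent ("i+1") or opposite ("i+2") subunit, together
#' with the geometric criteria. Defaults follow the common MD convention:
#' donor-acceptor heavy-atom distance below 3.5 Angstrom and a
#' donor-H-acceptor angle of at least 120 degrees.
#'
#' @param donor_res residue number carrying the donor atoms
#' @param donor_atoms atom filter for the donor heavy atoms (see
#'   [selection_spec()]), e.g. `"sidechain-N"`
#' @param acceptor_res residue number carrying the acceptor atoms
#' @param acceptor_atoms atom filter for acceptors, e.g. `"backbone-O"`
#' @param role `"opposite"` (i to i+2) or `"adjacent"` (i to i+1)
#' @param distance_cutoff Angstrom, > 0
#' @param angle_cutoff degrees in (0, 180]
#' @param kind `"hbond"` or `"saltbridge"` (label only; criteria are as
#'   given)
#' @export
contact_definition <- function(donor_res, donor_atoms, acceptor_res,
                               acceptor_atoms, role = c("opposite", "adjacent"),
                               distance_cutoff = 3.5, angle_cutoff = 120,
                               kind = c("hbond", "saltbridge")) {
  role <- match.arg(role)
  kind <- match.arg(kind)
  stopifnot(distance_cutoff > 0, angle_cutoff > 0, angle_cutoff <= 180)
  structure(list(donor_res = donor_res, donor_atoms = donor_atoms,
                 acceptor_res = acceptor_res, acceptor_atoms = acceptor_atoms,
                 role = role, distance_cutoff = distance_cutoff,
                 angle_cutoff = angle_cutoff, kind = kind),
            class = "contact_definition")
}

vnorm <- function(v) sqrt(sum(v * v))

angle_deg <- function(a, b, c) {
  # angle at vertex b, degrees; NA when degenerate
  u <- a - b; v <- c - b
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu < 1e-12 || nv < 1e-12) return(NA_real_)
  cosang <- sum(u * v) / (nu * nv)
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Per-frame hydrogen-bond test for one donor/acceptor pair
#'
#' True iff the donor-acceptor distance is within `distance_cutoff` and at
#' least one attached hydrogen gives a donor-H-acceptor angle of at least
#' `angle_cutoff`. When `hydrogen_idx` is empty the angle criterion is
#' waived (distance-only mode for hydrogen-free models); a degenerate
#' hydrogen coincident with the donor fails the criterion.
#'
#' @param frame n_atoms x 3 coordinate matrix
#' @param donor_idx,acceptor_idx single atom indices
#' @param hydrogen_idx indices of hydrogens bonded to the donor
#' @param distance_cutoff,angle_cutoff criteria (Angstrom / degrees)
#' @return logical
#' @export
detect_hbond <- function(frame, donor_idx, acceptor_idx, hydrogen_idx,
                         distance_cutoff = 3.5, angle_cutoff = 120) {
  d <- frame[donor_idx, ]; a <- frame[acceptor_idx, ]
  if (vnorm(a - d) > distance_cutoff) return(FALSE)
  if (length(hydrogen_idx) == 0) return(TRUE)
  for (h in hydrogen_idx) {
    ang <- angle_deg(d, frame[h, ], a)
    if (!is.na(ang) && ang >= angle_cutoff) return(TRUE)
  }
  FALSE
}

#' Hydrogens attached to a donor atom
#'
#' Attachment is resolved by the PDB naming convention first (donor `NZ`
#' owns `HZ1..HZ3`, backbone `N` owns `H`/`H1..H3`), with a geometric
#' fallback accepting any hydrogen of the same residue within 1.2
#' Angstrom of the donor.
#'
#' @param topology a [channel_topology()]
#' @param donor_idx donor atom index
#' @param frame optional coordinate matrix enabling the geometric fallback
#' @return integer vector of hydrogen atom indices (possibly empty)
#' @export
attached_hydrogens <- function(topology, donor_idx, frame = NULL) {
  a <- topology$atoms
  don <- a[donor_idx, ]
  same_res <- which(a$res_id == don$res_id & a$subunit == don$subunit &
                      a$is_hydrogen)
  if (length(same_res) == 0) return(integer(0))
  suffix <- substring(don$name, 2)
  pat <- if (nzchar(suffix)) paste0("^H", suffix, "[0-9]*$") else "^H[0-9]*$"
  by_name <- same_res[grepl(pat, a$name[same_res])]
  if (length(by_name) > 0) return(by_name)
  if (!is.null(frame)) {
    d2 <- colSums((t(frame[same_res, , drop = FALSE]) - frame[donor_idx, ])^2)
    return(same_res[d2 < 1.2^2])
  }
  integer(0)
}

#' Minimum pairwise distance between two selections
#'
#' @param frame n_atoms x 3 coordinate matrix
#' @param idx_a,idx_b non-empty atom index vectors
#' @return Angstrom
#' @export
min_distance <- function(frame, idx_a, idx_b) {
  if (length(idx_a) == 0 || length(idx_b) == 0)
    stop("min_distance requires two non-empty selections")
  A <- frame[idx_a, , drop = FALSE]
  B <- frame[idx_b, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(max(0, min(d2)))
}

role_pairs <- function(role) {
  offset <- if (role == "opposite") 2L else 1L
  data.frame(donor_subunit = 0:3, acceptor_subunit = (0:3 + offset) %% 4L)
}

#' Contact occurrence frequency across an ensemble
#'
#' For every donor subunit i (all four symmetric placements of the
#' contact are scored) and every replica, the fraction of frames in which
#' any (donor atom, hydrogen, acceptor atom) combination satisfies
#' [detect_hbond()]. The summary mean and SEM are taken over all
#' subunit-pair x replica values (n = 4 x replicas).
#'
#' @param ensemble a [channel_ensemble()]
#' @param definition a [contact_definition()]
#' @return object of class `contact_frequency` with elements
#'   `per_pair_per_replica` (data.frame: donor_subunit, acceptor_subunit,
#'   replica, frequency), `mean`, `sem`, `n`, `distance_only` (TRUE when
#'   no donor hydrogens were found and the angle criterion was waived)
#' @export
contact_frequency <- function(ensemble, definition) {
  topo <- ensemble$topology
  pairs <- role_pairs(definition$role)
  # resolve atoms once per subunit
  setup <- lapply(seq_len(nrow(pairs)), function(k) {
    don <- resolve_selection(topo, selection_spec(
      definition$donor_res, pairs$donor_subunit[k], definition$donor_atoms))
    acc <- resolve_selection(topo, selection_spec(
      definition$acceptor_res, pairs$acceptor_subunit[k],
      definition$acceptor_atoms))
    hyd <- lapply(don, function(d)
      attached_hydrogens(topo, d, get_frame(ensemble, 1)))
    list(don = don, acc = acc, hyd = hyd)
  })
  distance_only <- all(vapply(setup, function(s)
    all(lengths(s$hyd) == 0), logical(1)))
  reps <- unique(ensemble$replica)
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    s <- setup[[k]]
    for (r in reps) {
      fr_idx <- which(ensemble$replica == r)
      hit <- vapply(fr_idx, function(f) {
        X <- get_frame(ensemble, f)
        for (di in seq_along(s$don)) for (ai in s$acc) {
          if (detect_hbond(X, s$don[di], ai, s$hyd[[di]],
                           definition$distance_cutoff,
                           definition$angle_cutoff)) return(TRUE)
        }
        FALSE
      }, logical(1))
      rows[[length(rows) + 1]] <- data.frame(
        donor_subunit = pairs$donor_subunit[k],
        acceptor_subunit = pairs$acceptor_subunit[k],
        replica = r, frequency = mean(hit))
    }
  }
  tab <- do.call(rbind, rows)
  structure(list(definition = definition, per_pair_per_replica = tab,
                 mean = mean(tab$frequency),
                 sem = sem(tab$frequency), n = nrow(tab),
                 distance_only = distance_only),
            class = "contact_frequency")
}

#' @export
print.contact_frequency <- function(x, ...) {
  cat(sprintf(
    "contact %d:%s -> %d:%s (%s, %s): %.1f%% +/- %.1f%% (n = %d)%s\n",
    x$definition$donor_res, paste(x$definition$donor_atoms, collapse = ","),
    x$definition$acceptor_res,
    paste(x$definition$acceptor_atoms, collapse = ","),
    x$definition$role, x$definition$kind,
    100 * x$mean, 100 * x$sem, x$n,
    if (x$distance_only) " [distance-only]" else ""))
  invisible(x)
}

#' Salt-bridge occurrence frequency
#'
#' Applies the hydrogen-bond machinery to the charged groups: side-chain
#' nitrogens of a basic residue as donors, side-chain (carboxylate)
#' oxygens of an acidic residue as acceptors, under the same distance and
#' angle criteria. With `angle = FALSE` the angle term is dropped
#' (distance-only salt-bridge criterion); the mode is recorded in the
#' result's definition.
#'
#' @param ensemble a [channel_ensemble()]
#' @param basic_res residue number; must be LYS, ARG or HIS
#' @param acidic_res residue number; must be ASP or GLU
#' @param role `"opposite"` or `"adjacent"`
#' @param distance_cutoff,angle_cutoff criteria
#' @param angle include the donor-H-acceptor angle criterion
#' @return a `contact_frequency` object
#' @export
salt_bridge_frequency <- function(ensemble, basic_res, acidic_res,
                                  role = "opposite", distance_cutoff = 3.5,
                                  angle_cutoff = 120, angle = TRUE) {
  a <- ensemble$topology$atoms
  bname <- unique(a$res_name[a$res_id == basic_res])
  aname <- unique(a$res_name[a$res_id == acidic_res])
  if (!any(bname %in% c("LYS", "ARG", "HIS")))
    stop("residue ", basic_res, " is not basic (LYS/ARG/HIS): ",
         paste(bname, collapse = ","))
  if (!any(aname %in% c("ASP", "GLU")))
    stop("residue ", acidic_res, " is not acidic (ASP/GLU): ",
         paste(aname, collapse = ","))
  def <- contact_definition(basic_res, "sidechain-N", acidic_res,
                            "sidechain-O", role,
                            distance_cutoff, angle_cutoff,
                            kind = "saltbridge")
  if (!angle) def$angle_cutoff <- 0  # any geometry passes the angle term
  res <- contact_frequency(ensemble, def)
  if (!angle) res$distance_only <- TRUE
  res
}
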