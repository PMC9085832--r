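cyl_point <- function(r, az_deg, z) {
  a <- az_deg * pi / 180
  c(r * cos(a), r * sin(a), z)
}

rotate_about_axis <- function(X, theta_deg, axis_point = c(0, 0, 0),
                              axis_dir = c(0, 0, 1)) {
  # Rodrigues rotation of an n x 3 matrix about an arbitrary axis
  u <- axis_dir / vnorm(axis_dir)
  th <- theta_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  Xc <- sweep(X, 2, axis_point)
  sweep(Xc %*% t(R), 2, axis_point, "+")
}

#' Build a miniature C4-symmetric tetramer
#'
#' A toy homotetramer carrying the residues that the structural analyses
#' address, at their canonical mHCN2 residue numbers inside a sparse
#' chain:
#' an HCN-domain stretch (150-157, with M155 whose backbone oxygen is
#' the opposite-subunit acceptor), the S2/S3 linker acidics (242-248
#' with E243, D244, E247), the pore/S6 helix (428-444 with gate residues
#' I432, T436, Q440, C-beta ring at `pore_radius`), and the C-linker
#' elbow (458-464, terminal residues 460-463 plus K464 whose side-chain
#' nitrogen NZ, with hydrogen HZ1, is the donor). The pore axis is z;
#' K464(i) and the backbone O of M155(i+2) are placed at
#' `contact_distance` with a collinear donor hydrogen, so the starting
#' structure is in contact geometry on all four symmetric placements.
#'
#' @param pore_radius radius of the gate C-beta ring, Angstrom
#' @param elbow_radius radius of the elbow C-alpha arc, Angstrom
#' @param contact_distance donor-acceptor distance of the built-in
#'   K464-M155 contact, Angstrom
#' @param state_label ensemble tag
#' @return one-frame [channel_ensemble()] (the starting structure)
#' @export
build_toy_tetramer <- function(pore_radius = 5, elbow_radius = 16,
                               contact_distance = 2.9,
                               state_label = "start") {
  if (elbow_radius <= pore_radius + 3)
    stop("elbow_radius too small: arms would overlap the pore")
  res_name_of <- function(res) switch(as.character(res),
    "155" = "MET", "243" = "GLU", "244" = "ASP", "247" = "GLU",
    "432" = "ILE", "436" = "THR", "440" = "GLN",
    "460" = "MET", "461" = "ILE", "462" = "ARG", "463" = "HIS",
    "464" = "LYS", "ALA")
  rows <- list(); coords <- list()
  add_atom <- function(name, element, res_name, res_id, subunit, xyz) {
    rows[[length(rows) + 1]] <<- data.frame(
      serial = length(rows) + 1L, name = name, element = element,
      res_name = res_name, res_id = res_id, subunit = subunit,
      stringsAsFactors = FALSE)
    coords[[length(coords) + 1]] <<- xyz
  }
  # generic residue: CA at p, backbone offsets along the local tangent,
  # CB along the (possibly inward) normal
  add_residue <- function(res, sub, p, u_hat, t_hat, cb_dir = 1) {
    rn <- res_name_of(res)
    add_atom("N", "N", rn, res, sub, p - 1.46 * t_hat)
    add_atom("CA", "C", rn, res, sub, p)
    add_atom("C", "C", rn, res, sub, p + 1.52 * t_hat)
    add_atom("O", "O", rn, res, sub, p + 1.52 * t_hat + c(0, 0, 1.23))
    add_atom("CB", "C", rn, res, sub, p + cb_dir * 1.53 * u_hat)
    if (rn %in% c("GLU", "ASP")) {
      pre <- if (rn == "GLU") "OE" else "OD"
      base <- p + cb_dir * 1.53 * u_hat
      add_atom(paste0(pre, "1"), "O", rn, res, sub, base + 1.2 * u_hat * cb_dir + c(0, 0, 0.5))
      add_atom(paste0(pre, "2"), "O", rn, res, sub, base + 1.2 * u_hat * cb_dir - c(0, 0, 0.5))
    }
  }
  dirs <- function(az_deg) {
    a <- az_deg * pi / 180
    list(u = c(cos(a), sin(a), 0), t = c(-sin(a), cos(a), 0))
  }
  for (s in 0:3) {
    phi <- 90 * s
    # pore / S6: residues 428-444 ascending in z; CA just outside the
    # gate ring so that CB (pointing inward) sits at pore_radius
    for (k in 0:16) {
      res <- 428 + k
      az <- phi + 2.5 * k        # gentle twist, keeps CAs non-collinear
      d <- dirs(az)
      p <- cyl_point(pore_radius + 1.53, az, 1.5 * k)
      add_residue(res, s, p, d$u, d$t, cb_dir = -1)
    }
    # elbow / C-linker tip: residues 458-464, below the pore
    for (k in 0:6) {
      res <- 458 + k
      az <- phi + 20 + 5 * k
      d <- dirs(az)
      p <- cyl_point(elbow_radius, az, -10 - 0.4 * k)
      add_residue(res, s, p, d$u, d$t, cb_dir = 1)
      if (res == 464) {
        nz <- p + 1.2 * d$u  # side-chain amine pointing outward
        add_atom("NZ", "N", "LYS", res, s, nz)
        add_atom("HZ1", "H", "LYS", res, s, nz + 1.0 * d$u)
      }
    }
    # HCN domain of THIS subunit sits across the pore so that its M155
    # backbone O faces K464's NZ of subunit (s+2): K464(s+2) lies at
    # azimuth phi+180+50, and its NZ + contact vector is where O goes.
    az464 <- phi + 180 + 50      # azimuth of the partner K464 site
    d464 <- dirs(az464)
    nz_partner <- cyl_point(elbow_radius, az464, -10 - 0.4 * 6) +
      1.2 * d464$u
    o155 <- nz_partner + contact_distance * d464$u
    for (k in 0:7) {
      res <- 150 + k
      az <- az464 + 14 + 6 * (k - 5)
      d <- dirs(az)
      p <- cyl_point(elbow_radius + 6, az, -12 + 0.3 * k)
      if (res == 155) {
        rn <- "MET"
        # place the backbone around the prescribed carbonyl O position
        add_atom("N", "N", rn, res, s, o155 + 2.9 * d464$u - 1.4 * d464$t)
        add_atom("CA", "C", rn, res, s, o155 + 2.4 * d464$u)
        add_atom("C", "C", rn, res, s, o155 + 1.23 * d464$u)
        add_atom("O", "O", rn, res, s, o155)
        add_atom("CB", "C", rn, res, s, o155 + 2.4 * d464$u + c(0, 0, 1.5))
      } else {
        add_residue(res, s, p, d$u, d$t, cb_dir = 1)
      }
    }
    # S2/S3 linker acidics near (but outside contact range of) the same
    # partner K464 site
    for (k in 0:6) {
      res <- 242 + k
      az <- az464 - 16 + 5 * (k - 3)
      d <- dirs(az)
      p <- cyl_point(elbow_radius + 7.5, az, -8 + 0.3 * k)
      add_residue(res, s, p, d$u, d$t, cb_dir = -1)
    }
  }
  atoms <- do.call(rbind, rows)
  # canonical order: subunit, then residue, then insertion order
  ord <- order(atoms$subunit, atoms$res_id, seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  X <- do.call(rbind, coords)[ord, , drop = FALSE]
  domains <- data.frame(
    domain = c("HCN-domain", "TM", "TM", "CL"),
    start = c(150, 242, 428, 458), end = c(157, 248, 444, 464))
  topo <- channel_topology(atoms, domains)
  channel_ensemble(topo, array(X, c(nrow(X), 3, 1)),
                   state_label = state_label)
}

cl_block_indices <- function(topology) {
  d <- topology$domains
  if (is.null(d)) stop("topology carries no domain labels")
  keep <- d$domain %in% c("CL", "CNBD")
  res <- unlist(lapply(which(keep), function(i) d$start[i]:d$end[i]))
  lapply(0:3, function(s)
    which(topology$atoms$res_id %in% res & topology$atoms$subunit == s))
}

pore_axis_of <- function(start_frame, topology, upper = 436, lower = 432) {
  up <- colMeans(start_frame[
    resolve_selection(topology, selection_spec(upper, 0:3, "CA")), ,
    drop = FALSE])
  lo <- colMeans(start_frame[
    resolve_selection(topology, selection_spec(lower, 0:3, "CA")), ,
    drop = FALSE])
  list(point = lo, dir = (up - lo) / vnorm(up - lo))
}

#' Generate an ensemble with a prescribed C-linker/CNBD rotation
#'
#' Each frame starts from the starting structure; the CL/CNBD block of
#' every subunit is rotated about the pore axis by an angle drawn
#' independently per (frame, subunit) from N(rotation_mean,
#' rotation_sd), and isotropic Gaussian positional noise is added
#' per atom according to the residue's amplitude. Pore atoms receive
#' noise only, never rotation. The drawn angles are kept as ground
#' truth in `$truth`.
#'
#' @param start one-frame starting ensemble from [build_toy_tetramer()]
#' @param n_replicas,n_frames ensemble dimensions (frames per replica)
#' @param rotation_mean,rotation_sd degrees
#' @param noise_amplitude either one sigma (Angstrom, per coordinate)
#'   for all atoms, or a named vector keyed by residue number (residues
#'   absent from the vector get 0)
#' @param seed RNG seed; streams are split per replica so replicas stay
#'   independent yet reproducible
#' @return [channel_ensemble()] with a `truth` element (data.frame:
#'   replica, frame, subunit, theta)
#' @export
generate_rotated_ensemble <- function(start, n_replicas = 1, n_frames = 10,
                                      rotation_mean = 0, rotation_sd = 0,
                                      noise_amplitude = 0, seed = 1) {
  stopifnot(rotation_sd >= 0)
  topo <- start$topology
  X0 <- get_frame(start, 1)
  block <- cl_block_indices(topo)
  axis <- pore_axis_of(X0, topo)
  na <- nrow(X0)
  sigma <- if (length(noise_amplitude) == 1 && is.null(names(noise_amplitude)))
    rep(noise_amplitude, na)
  else {
    s <- rep(0, na)
    hit <- match(as.character(topo$atoms$res_id), names(noise_amplitude))
    s[!is.na(hit)] <- noise_amplitude[hit[!is.na(hit)]]
    s
  }
  coords <- array(NA_real_, c(na, 3, n_replicas * n_frames))
  replica <- rep(seq_len(n_replicas), each = n_frames)
  truth <- list()
  k <- 0
  for (r in seq_len(n_replicas)) {
    set.seed(seed * 10000L + r)
    for (f in seq_len(n_frames)) {
      k <- k + 1
      X <- X0
      theta <- rnorm(4, rotation_mean, rotation_sd)
      for (s in 0:3) {
        idx <- block[[s + 1]]
        X[idx, ] <- rotate_about_axis(X[idx, , drop = FALSE], theta[s + 1],
                                      axis$point, axis$dir)
      }
      if (any(sigma > 0))
        X <- X + matrix(rnorm(3 * na, 0, rep(sigma, 3)), na, 3)
      coords[, , k] <- X
      truth[[k]] <- data.frame(replica = r, frame = f, subunit = 0:3,
                               theta = theta)
    }
  }
  e <- channel_ensemble(topo, coords, replica, state_label = start$state_label)
  e$truth <- do.call(rbind, truth)
  e
}

#' Generate a trajectory with scripted contact occupancy
#'
#' Per frame and per symmetric placement of the contact, a Bernoulli
#' draw with probability `p` decides whether the acceptor atoms sit in
#' bonded geometry (donor-acceptor distance `d_on`, donor-H-acceptor
#' angle `angle_on`) or at `d_off` along the donor's outward direction.
#' The acceptor residue's matching atoms are translated rigidly. Draws
#' are stored as ground truth.
#'
#' @param start one-frame starting ensemble
#' @param donor_res,donor_atoms,acceptor_res,acceptor_atoms,role contact
#'   specification as in [contact_definition()]
#' @param p occupancy probability in `[0, 1]`
#' @param n_frames frames per replica
#' @param n_replicas replica count
#' @param d_on,angle_on,d_off bonded/unbonded geometry parameters
#' @param seed RNG seed (split per replica)
#' @return [channel_ensemble()] with `$truth` (replica, frame,
#'   donor_subunit, bonded)
#' @export
generate_contact_trajectory <- function(start, donor_res = 464,
                                        donor_atoms = "sidechain-N",
                                        acceptor_res = 155,
                                        acceptor_atoms = "backbone-O",
                                        role = "opposite", p = 0.5,
                                        n_frames = 100, n_replicas = 1,
                                        d_on = 2.9, angle_on = 170,
                                        d_off = 6.0, seed = 1) {
  stopifnot(p >= 0, p <= 1)
  topo <- start$topology
  X0 <- get_frame(start, 1)
  pairs <- role_pairs(role)
  setup <- lapply(seq_len(nrow(pairs)), function(kk) {
    don <- resolve_selection(topo, selection_spec(
      donor_res, pairs$donor_subunit[kk], donor_atoms))[1]
    acc <- resolve_selection(topo, selection_spec(
      acceptor_res, pairs$acceptor_subunit[kk], acceptor_atoms))
    hyd <- attached_hydrogens(topo, don, X0)
    if (length(hyd) == 0)
      stop("donor has no attached hydrogen in the starting structure")
    list(don = don, acc = acc, hyd = hyd[1])
  })
  # bonded position: along H direction at the prescribed D-H-A angle,
  # at distance d_on from the donor
  bonded_pos <- function(D, H) {
    u <- (H - D) / vnorm(H - D)
    h <- vnorm(H - D)
    # in-plane perpendicular to u (any stable choice)
    ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    t1 <- pracma_cross(u, ref); t1 <- t1 / vnorm(t1)
    alpha <- (180 - angle_on) * pi / 180  # deviation from collinear
    w <- cos(alpha) * u + sin(alpha) * t1
    # solve |H + L w - D| = d_on for L > 0
    b <- 2 * h * cos(alpha)
    L <- (-b + sqrt(b^2 - 4 * (h^2 - d_on^2))) / 2
    H + L * w
  }
  na <- nrow(X0)
  coords <- array(NA_real_, c(na, 3, n_replicas * n_frames))
  replica <- rep(seq_len(n_replicas), each = n_frames)
  truth <- list(); k <- 0
  for (r in seq_len(n_replicas)) {
    set.seed(seed * 10000L + r)
    for (f in seq_len(n_frames)) {
      k <- k + 1
      X <- X0
      bonded <- runif(4) < p
      for (kk in seq_len(nrow(pairs))) {
        s <- setup[[kk]]
        D <- X0[s$don, ]; H <- X0[s$hyd, ]
        u <- (H - D) / vnorm(H - D)
        target <- if (bonded[kk]) bonded_pos(D, H) else D + d_off * u
        shift <- target - X0[s$acc[1], ]
        X[s$acc, ] <- sweep(X0[s$acc, , drop = FALSE], 2, shift, "+")
      }
      coords[, , k] <- X
      truth[[k]] <- data.frame(replica = r, frame = f,
                               donor_subunit = 0:3, bonded = bonded)
    }
  }
  e <- channel_ensemble(topo, coords, replica,
                        state_label = start$state_label)
  e$truth <- do.call(rbind, truth)
  e
}

#' Generate synthetic steady-state activation recordings
#'
#' Tail amplitudes follow the Boltzmann model with additive Gaussian
#' noise; optional activation time courses follow a delayed single
#' exponential with voltage-dependent tau.
#'
#' @param V_half,z_delta,amp_satV Boltzmann truth
#' @param voltages command voltages, mV (default -150..-70 in 10 mV
#'   steps)
#' @param noise_sd Gaussian noise on the relative tail amplitude
#' @param n_recordings number of independent recordings
#' @param temperature Kelvin
#' @param tau_ms,delay_ms when non-NULL, an activation trace
#'   (t_ms, I) is generated per recording at the most hyperpolarised
#'   voltage with this time constant and onset delay
#' @param trace_noise_sd Gaussian noise on the trace, fraction of the
#'   steady-state amplitude
#' @param seed RNG seed
#' @return list with `recordings` (list of data.frames voltage_mV,
#'   rel_tail) and `traces` (list of data.frames t_ms, I, or NULL)
#' @export
generate_activation_traces <- function(V_half = -100.6, z_delta = 4,
                                       amp_satV = 1,
                                       voltages = seq(-150, -70, by = 10),
                                       noise_sd = 0.02, n_recordings = 10,
                                       temperature = 293.15,
                                       tau_ms = NULL, delay_ms = 0,
                                       trace_noise_sd = 0, seed = 1) {
  set.seed(seed)
  recordings <- vector("list", n_recordings)
  traces <- if (is.null(tau_ms)) NULL else vector("list", n_recordings)
  for (i in seq_len(n_recordings)) {
    y <- boltzmann_model(voltages, V_half, z_delta, amp_satV, temperature) +
      rnorm(length(voltages), 0, noise_sd)
    recordings[[i]] <- data.frame(voltage_mV = voltages, rel_tail = y)
    if (!is.null(tau_ms)) {
      t_ms <- seq(0, delay_ms + 6 * tau_ms, length.out = 400)
      amp <- boltzmann_model(min(voltages), V_half, z_delta, amp_satV,
                             temperature)
      I <- ifelse(t_ms < delay_ms, 0,
                  amp * (1 - exp(-(t_ms - delay_ms) / tau_ms)))
      I <- I + rnorm(length(I), 0, trace_noise_sd * amp)
      traces[[i]] <- data.frame(t_ms = t_ms, I = I)
    }
  }
  list(recordings = recordings, traces = traces,
       truth = list(V_half = V_half, z_delta = z_delta,
                    amp_satV = amp_satV, tau_ms = tau_ms,
                    delay_ms = delay_ms))
}

#' Generate synthetic concentration-binding data
#'
#' Hill-governed mean F/Fmax per concentration, averaged over
#' `n_patches` noisy patches.
#'
#' @param BC50,H Hill truth (micromolar / dimensionless)
#' @param concentrations micromolar; default subsaturating series up to
#'   the saturating 2.5
#' @param noise_sd per-patch Gaussian noise on F/Fmax
#' @param n_patches patches averaged per concentration
#' @param seed RNG seed
#' @return data.frame (conc_uM, F_over_Fmax) of averaged data
#' @export
generate_binding_data <- function(BC50 = 0.40, H = 1.5,
                                  concentrations = c(0.05, 0.1, 0.25, 0.5,
                                                     1, 2.5),
                                  noise_sd = 0.02, n_patches = 5,
                                  seed = 1) {
  set.seed(seed)
  y <- vapply(concentrations, function(cc)
    mean(hill_model(cc, BC50, H) + rnorm(n_patches, 0, noise_sd)),
    numeric(1))
  data.frame(conc_uM = concentrations, F_over_Fmax = y)
}

#' Generate a synthetic cPCF image pair
#'
#' The red reference-dye image has uniform intensity over the free-dye
#' regions; the green image is `scale` times the red plus a dome-only
#' bound-ligand signal of `bound_fraction * f_max`, with Gaussian noise
#' on both channels.
#'
#' @param bound_fraction ground-truth bound fraction in `[0, 1]`
#' @param f_max saturating dome intensity
#' @param scale green/red scaling of the free-dye signal
#' @param noise_sd additive Gaussian noise per pixel
#' @param dim image size (rows, cols)
#' @param seed RNG seed
#' @return list usable with [cpcf_subtract()] plus `truth`
#' @export
generate_cpcf_images <- function(bound_fraction = 0.5, f_max = 1000,
                                 scale = 0.8, noise_sd = 1,
                                 dim = c(64, 64), seed = 1) {
  set.seed(seed)
  nr <- dim[1]; nc <- dim[2]
  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  roi_bath <- col <= nc %/% 4
  roi_pipette <- col >= nc - nc %/% 8
  cen <- c(nr / 2, nc / 2)
  roi_dome <- (row - cen[1])^2 + (col - cen[2])^2 <= (min(nr, nc) / 6)^2
  roi_dome <- roi_dome & !roi_bath & !roi_pipette
  r0 <- 100
  red <- matrix(r0, nr, nc) + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
  green <- scale * r0 + bound_fraction * f_max * roi_dome +
    matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
  list(green = green, red = red, roi_dome = roi_dome, roi_bath = roi_bath,
       roi_pipette = roi_pipette, f_max = f_max,
       truth = list(bound_fraction = bound_fraction, scale = scale))
}
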