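#' Residue-wise RMSF over an ensemble
#'
#' Per replica, frames are superimposed onto the replica-average
#' structure over `alignment_spec` (two-pass: align to the first frame,
#' average, re-align to that average). The RMSF of an atom is the root
#' mean square displacement from its time-mean position; a residue's
#' RMSF is the unweighted mean over its selected atoms. Residues with no
#' atoms matching the selection (glycine under a side-chain filter) are
#' omitted.
#'
#' @param ensemble a [channel_ensemble()]
#' @param selection a [selection_spec()]; default all heavy side-chain
#'   atoms
#' @param alignment_spec [selection_spec()] for the pre-RMSF alignment
#'   (default pore C-alpha, residues 428-444); NULL disables alignment
#' @return data.frame with columns res_id, subunit, replica, rmsf
#'   (Angstrom)
#' @export
rmsf <- function(ensemble,
                 selection = selection_spec(atoms = "sidechain-nonH"),
                 alignment_spec = selection_spec(428:444, 0:3, "CA")) {
  topo <- ensemble$topology
  sel_idx <- resolve_selection(topo, selection)
  align_idx <- if (is.null(alignment_spec)) NULL else
    resolve_selection(topo, alignment_spec)
  a <- topo$atoms
  reps <- unique(ensemble$replica)
  out <- list()
  for (r in reps) {
    fidx <- which(ensemble$replica == r)
    if (length(fidx) < 2)
      stop("RMSF needs >= 2 frames per replica (replica ", r, ")")
    frames <- lapply(fidx, function(f) get_frame(ensemble, f))
    if (!is.null(align_idx)) {
      frames <- lapply(frames, function(X)
        superimpose_pore(X, frames[[1]], align_idx)$coords)
      avg <- Reduce(`+`, frames) / length(frames)
      frames <- lapply(frames, function(X)
        superimpose_pore(X, avg, align_idx)$coords)
    }
    avg <- Reduce(`+`, frames) / length(frames)
    # per-atom mean squared displacement from the time mean
    msd <- Reduce(`+`, lapply(frames, function(X) rowSums((X - avg)^2))) /
      length(frames)
    atom_rmsf <- sqrt(msd)
    tab <- data.frame(res_id = a$res_id[sel_idx],
                      subunit = a$subunit[sel_idx],
                      rmsf = atom_rmsf[sel_idx])
    res <- aggregate(rmsf ~ res_id + subunit, tab, mean)
    res$replica <- r
    out[[length(out) + 1]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("res_id", "subunit", "replica", "rmsf")]
}

#' Significance-masked RMSF difference between two states
#'
#' For each residue, the per-(subunit, replica) RMSF values of the
#' reference state are compared with those of the other state by a
#' two-sample t-test; residues whose difference is not significant at
#' `alpha` are reset to zero. Unmasked entries carry
#' `mean(reference) - mean(other)`, so negative values mark residues
#' more mobile in the other state.
#'
#' @param table_ref,table_other RMSF tables from [rmsf()] over the same
#'   residue universe
#' @param alpha significance level (default 0.05, raw per-residue
#'   p-values, no multiplicity correction)
#' @param variant `"welch"` (default) or `"pooled"` t-test
#' @return data.frame with res_id, delta (Angstrom), p_value, masked
#' @export
delta_rmsf <- function(table_ref, table_other, alpha = 0.05,
                       variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  common <- intersect(unique(table_ref$res_id), unique(table_other$res_id))
  if (length(common) == 0) stop("no shared residues between RMSF tables")
  out <- lapply(sort(common), function(res) {
    x <- table_ref$rmsf[table_ref$res_id == res]
    y <- table_other$rmsf[table_other$res_id == res]
    if (length(x) < 2 || length(y) < 2)
      stop("residue ", res, " has fewer than 2 samples per group")
    tt <- two_sample_ttest(x, y, variant)
    delta <- if (tt$p_value < alpha) mean(x) - mean(y) else 0
    data.frame(res_id = res, delta = delta, p_value = tt$p_value,
               masked = tt$p_value >= alpha)
  })
  do.call(rbind, out)
}

#' Gate geometry: opposite C-beta distances
#'
#' For each gate residue, the C-beta to C-beta distance of the two
#' opposite subunit pairs (0,2) and (1,3) is measured per frame,
#' averaged per (pair, replica), and summarised with n = 2 pairs x
#' replicas.
#'
#' @param ensemble a [channel_ensemble()]
#' @param gate_res_ids gate residue numbers (default I432/T436/Q440)
#' @return list of class `gate_metrics`: `per_frame` (res_id, pair,
#'   replica, frame, distance), `per_run` (res_id, pair, replica, mean),
#'   `summary` (res_id, mean, sem, n)
#' @export
gate_distances <- function(ensemble, gate_res_ids = c(432, 436, 440)) {
  topo <- ensemble$topology
  cb <- lapply(gate_res_ids, function(res) {
    idx <- vapply(0:3, function(s) {
      i <- resolve_selection(topo, selection_spec(res, s, "CB"),
                             allow_empty = TRUE)
      if (length(i) != 1)
        stop("residue ", res, " subunit ", s, ": C-beta atom missing")
      i
    }, integer(1))
    idx
  })
  nf <- n_frames(ensemble)
  rows <- list()
  for (f in seq_len(nf)) {
    X <- get_frame(ensemble, f)
    for (g in seq_along(gate_res_ids)) {
      idx <- cb[[g]]
      d02 <- vnorm(X[idx[1], ] - X[idx[3], ])
      d13 <- vnorm(X[idx[2], ] - X[idx[4], ])
      rows[[length(rows) + 1]] <- data.frame(
        res_id = gate_res_ids[g], pair = c("0-2", "1-3"),
        replica = ensemble$replica[f], frame = f,
        distance = c(d02, d13))
    }
  }
  per_frame <- do.call(rbind, rows)
  per_run <- aggregate(distance ~ res_id + pair + replica, per_frame, mean)
  summ <- do.call(rbind, lapply(split(per_run, per_run$res_id), function(d)
    data.frame(res_id = d$res_id[1], mean = mean(d$distance),
               sem = sem(d$distance), n = nrow(d))))
  rownames(summ) <- NULL
  structure(list(per_frame = per_frame, per_run = per_run, summary = summ),
            class = "gate_metrics")
}

#' Side-chain RMSF of the gate-forming residues
#'
#' [rmsf()] restricted to the gate residues, heavy side-chain atoms.
#'
#' @inheritParams gate_distances
#' @param alignment_spec passed to [rmsf()]
#' @return RMSF table (res_id, subunit, replica, rmsf)
#' @export
gate_rmsf <- function(ensemble, gate_res_ids = c(432, 436, 440),
                      alignment_spec = selection_spec(428:444, 0:3, "CA")) {
  rmsf(ensemble,
       selection = selection_spec(gate_res_ids, 0:3, "sidechain-nonH"),
       alignment_spec = alignment_spec)
}
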