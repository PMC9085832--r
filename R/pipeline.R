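#' Write a tidy result table as TSV
#'
#' One row per measurement with the conventional columns (state,
#' replica, subunit or subunit_pair, metric, value).
#'
#' @param df data.frame
#' @param path output file
#' @export
write_result_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_tsv
#' @param path TSV file to read
#' @export
read_result_tsv <- function(path) read.delim(path, sep = "\t")

as_contact_definition <- function(x) {
  if (inherits(x, "contact_definition")) return(x)
  do.call(contact_definition, x)
}

#' Run the full two/three-state comparison pipeline
#'
#' For every state: contact occurrence frequencies for each definition,
#' the rotation summary against the state's starting structure, the
#' side-chain RMSF table, and the gate metrics. For every non-reference
#' state: the significance-masked RMSF difference against the reference
#' state and t-tests on rotation (per subunit x replica means) and each
#' contact (per pair x replica frequencies). Deterministic given its
#' inputs.
#'
#' @param states named list; each element either a [channel_ensemble()]
#'   or a character vector of per-replica PDB paths
#' @param starts named list of starting structures per state (one-frame
#'   ensemble, frame matrix, or a PDB path); states absent from the
#'   list reuse their first frame
#' @param contacts list of [contact_definition()]s (or lists of
#'   arguments for it)
#' @param reference_state name of the reference state (default: first)
#' @param gate_res_ids gate residues (default 432, 436, 440)
#' @param rotation_args extra arguments for
#'   [build_rotation_reference()]
#' @param alpha significance level for masking and tests
#' @param outdir when non-NULL, TSV tables are written there
#' @return list of class `compare_report` with per-state results
#'   (`$states`), pairwise comparisons (`$comparisons`) and a summary
#'   data.frame (`$summary`: state, metric, mean, sem, n)
#' @export
run_compare <- function(states, starts = list(), contacts = list(),
                        reference_state = names(states)[1],
                        gate_res_ids = c(432, 436, 440),
                        rotation_args = list(), alpha = 0.05,
                        outdir = NULL) {
  if (length(states) < 1 || is.null(names(states)))
    stop("states must be a non-empty named list")
  load_state <- function(x, label) {
    if (inherits(x, "channel_ensemble")) return(x)
    if (is.character(x)) {
      missing <- x[!file.exists(x)]
      if (length(missing) > 0)
        stop("state '", label, "': missing ensemble file(s): ",
             paste(missing, collapse = ", "))
      return(read_ensemble_files(x, state_label = label))
    }
    stop("state '", label, "' is neither an ensemble nor file paths")
  }
  ensembles <- lapply(names(states), function(nm)
    load_state(states[[nm]], nm))
  names(ensembles) <- names(states)
  if (!reference_state %in% names(states))
    stop("unknown reference_state: ", reference_state)
  start_frame_of <- function(nm) {
    s <- starts[[nm]]
    if (is.null(s)) return(get_frame(ensembles[[nm]], 1))
    if (inherits(s, "channel_ensemble")) return(get_frame(s, 1))
    if (is.character(s)) return(get_frame(read_multimodel_pdb(s), 1))
    as.matrix(s)
  }
  stage <- function(what, nm, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed for state '%s': %s",
                   what, nm, conditionMessage(e)), call. = FALSE))
  }
  contacts <- lapply(contacts, as_contact_definition)
  per_state <- lapply(names(ensembles), function(nm) {
    e <- ensembles[[nm]]
    start <- start_frame_of(nm)
    ref <- stage("rotation-reference", nm, do.call(
      build_rotation_reference,
      c(list(start_frame = start, topology = e$topology), rotation_args)))
    list(
      contacts = stage("contacts", nm, lapply(contacts, function(def)
        contact_frequency(e, def))),
      rotation = stage("rotation", nm, rotation_summary(e, ref)),
      rmsf = stage("rmsf", nm, rmsf(e)),
      gate = stage("gate", nm, gate_distances(e, gate_res_ids)))
  })
  names(per_state) <- names(ensembles)
  ref_nm <- reference_state
  comparisons <- lapply(setdiff(names(per_state), ref_nm), function(nm) {
    a <- per_state[[ref_nm]]; b <- per_state[[nm]]
    rot_test <- two_sample_ttest(a$rotation$per_run$angle,
                                 b$rotation$per_run$angle, alpha = alpha)
    contact_tests <- lapply(seq_along(contacts), function(k)
      two_sample_ttest(a$contacts[[k]]$per_pair_per_replica$frequency,
                       b$contacts[[k]]$per_pair_per_replica$frequency,
                       alpha = alpha))
    list(other = nm,
         delta_rmsf = delta_rmsf(a$rmsf, b$rmsf, alpha = alpha),
         rotation_test = rot_test, contact_tests = contact_tests)
  })
  names(comparisons) <- setdiff(names(per_state), ref_nm)
  summary <- do.call(rbind, lapply(names(per_state), function(nm) {
    p <- per_state[[nm]]
    rows <- data.frame(state = nm, metric = "rotation_deg",
                       mean = p$rotation$mean, sem = p$rotation$sem,
                       n = p$rotation$n)
    for (k in seq_along(contacts)) {
      cf <- p$contacts[[k]]
      rows <- rbind(rows, data.frame(
        state = nm,
        metric = sprintf("contact_%d_%d_pct", cf$definition$donor_res,
                         cf$definition$acceptor_res),
        mean = 100 * cf$mean, sem = 100 * cf$sem, n = cf$n))
    }
    for (i in seq_len(nrow(p$gate$summary))) {
      g <- p$gate$summary[i, ]
      rows <- rbind(rows, data.frame(
        state = nm, metric = sprintf("gate_%d_cb_dist_A", g$res_id),
        mean = g$mean, sem = g$sem, n = g$n))
    }
    rows
  }))
  report <- structure(list(states = per_state, comparisons = comparisons,
                           summary = summary, alpha = alpha,
                           reference_state = ref_nm),
                      class = "compare_report")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_result_tsv(summary, file.path(outdir, "summary.tsv"))
    for (nm in names(per_state)) {
      write_result_tsv(per_state[[nm]]$rotation$per_run,
                       file.path(outdir, paste0("rotation_", nm, ".tsv")))
      write_result_tsv(per_state[[nm]]$rmsf,
                       file.path(outdir, paste0("rmsf_", nm, ".tsv")))
      write_result_tsv(per_state[[nm]]$gate$per_run,
                       file.path(outdir, paste0("gate_", nm, ".tsv")))
    }
    for (nm in names(comparisons))
      write_result_tsv(comparisons[[nm]]$delta_rmsf,
                       file.path(outdir,
                                 paste0("delta_rmsf_", ref_nm, "_vs_",
                                        nm, ".tsv")))
  }
  report
}

#' @export
print.compare_report <- function(x, ...) {
  cat("compare_report (reference state:", x$reference_state, ")\n")
  print(x$summary, row.names = FALSE)
  for (nm in names(x$comparisons)) {
    cm <- x$comparisons[[nm]]
    cat(sprintf("%s vs %s: rotation p = %.3g%s; %d residues unmasked in dRMSF\n",
                x$reference_state, nm, cm$rotation_test$p_value,
                if (cm$rotation_test$significant) " (*)" else "",
                sum(!cm$delta_rmsf$masked)))
  }
  invisible(x)
}
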