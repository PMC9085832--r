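#' @importFrom stats sd aggregate coef t.test rnorm runif median setNames
#'   approx cor residuals
#' @importFrom utils read.delim write.table
NULL

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT", "H", "H1", "H2", "H3", "HA",
                    "HA2", "HA3")

#' Construct a channel topology
#'
#' A topology holds the per-atom bookkeeping shared by every frame of an
#' ensemble: atom names (PDB convention), residue identity and number,
#' subunit index 0-3, and flags marking hydrogens and backbone atoms.
#' The channel is assumed to be a C4-symmetric homotetramer, so the
#' "opposite" subunit of subunit `i` is `(i + 2) %% 4` and the adjacent
#' subunit is `(i + 1) %% 4`.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `res_name`, `res_id`, `subunit`. Columns `is_hydrogen` and
#'   `is_backbone` are derived when absent.
#' @param domains optional data.frame with columns `domain`, `start`, `end`
#'   annotating residue ranges (e.g. HCN-domain, TM, CL, CNBD).
#' @return object of class `channel_topology`
#' @export
channel_topology <- function(atoms, domains = NULL) {
  req <- c("serial", "name", "element", "res_name", "res_id", "subunit")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0)
    stop("atoms table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(atoms$subunit %in% 0:3))
    stop("subunit indices must lie in 0..3")
  atoms$serial <- as.integer(atoms$serial)
  atoms$res_id <- as.integer(atoms$res_id)
  atoms$subunit <- as.integer(atoms$subunit)
  if (is.null(atoms$is_hydrogen))
    atoms$is_hydrogen <- toupper(atoms$element) == "H"
  if (is.null(atoms$is_backbone))
    atoms$is_backbone <- atoms$name %in% BACKBONE_NAMES
  # residue numbering must be non-decreasing within each subunit
  for (s in unique(atoms$subunit)) {
    r <- atoms$res_id[atoms$subunit == s]
    if (is.unsorted(r))
      stop("res_id not sorted within subunit ", s)
  }
  # atom names unique within a residue
  key <- paste(atoms$subunit, atoms$res_id, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate atom name within a residue: ",
         key[duplicated(key)][1])
  structure(list(atoms = atoms, subunit_count = 4L, domains = domains),
            class = "channel_topology")
}

#' Opposite / adjacent subunit maps of a C4 tetramer
#'
#' @param i subunit index or vector of indices in 0..3
#' @return subunit index/indices in 0..3
#' @export
opposite_subunit <- function(i) (i + 2L) %% 4L

#' @rdname opposite_subunit
#' @export
adjacent_subunit <- function(i) (i + 1L) %% 4L

#' Construct a structural ensemble
#'
#' An ensemble couples one topology with a stack of coordinate frames and
#' replica bookkeeping. Frames belonging to the same replica (independent
#' simulation) must be contiguous.
#'
#' @param topology a [channel_topology()]
#' @param coords numeric array `n_atoms x 3 x n_frames` (Angstrom)
#' @param replica integer vector, one replica id per frame
#' @param state_label free-form state tag, e.g. `"apo-WT"`, `"cAMP-WT"`,
#'   `"variant-K464E"`
#' @return object of class `channel_ensemble`
#' @export
channel_ensemble <- function(topology, coords, replica = NULL,
                             state_label = "state") {
  stopifnot(inherits(topology, "channel_topology"))
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  na <- nrow(topology$atoms)
  if (dim(coords)[1] != na || dim(coords)[2] != 3)
    stop("coords must be n_atoms x 3 x n_frames with n_atoms = ", na)
  if (!all(is.finite(coords)))
    stop("non-finite coordinates in ensemble")
  nf <- dim(coords)[3]
  if (is.null(replica)) replica <- rep(1L, nf)
  if (length(replica) != nf)
    stop("replica vector length must equal the frame count")
  # contiguity: replica ids must not re-appear after a switch
  rle_ids <- rle(replica)$values
  if (anyDuplicated(rle_ids))
    stop("frames of one replica must be contiguous")
  structure(list(topology = topology, coords = coords,
                 replica = as.integer(replica), state_label = state_label),
            class = "channel_ensemble")
}

#' @export
print.channel_ensemble <- function(x, ...) {
  cat(sprintf(
    "channel_ensemble '%s': %d atoms, %d frames, %d replica(s)\n",
    x$state_label, dim(x$coords)[1], dim(x$coords)[3],
    length(unique(x$replica))))
  invisible(x)
}

n_frames <- function(e) dim(e$coords)[3]
n_atoms <- function(e) dim(e$coords)[1]

#' Extract one frame as an n_atoms x 3 matrix
#' @param ensemble a [channel_ensemble()]
#' @param i frame index
#' @export
get_frame <- function(ensemble, i) ensemble$coords[, , i, drop = TRUE]

#' Atom selection specification
#'
#' Declarative selection of atoms by residue, subunit and an atom filter.
#' Named filters:
#' \describe{
#'   \item{CA, CB}{the respective single atom per residue}
#'   \item{backbone-O}{exactly the carbonyl oxygen `O`}
#'   \item{sidechain-nonH}{all heavy side-chain atoms (excludes N, CA, C,
#'     O and every hydrogen)}
#'   \item{sidechain-O / sidechain-N}{heavy side-chain oxygens / nitrogens}
#'   \item{all-nonH}{every heavy atom}
#'   \item{backbone}{N, CA, C, O and their hydrogens}
#' }
#' Any other character vector is treated as an explicit atom-name list.
#'
#' @param res_ids integer vector of residue numbers, or NULL for all
#' @param subunits subset of 0:3
#' @param atoms filter keyword or explicit atom-name vector
#' @export
selection_spec <- function(res_ids = NULL, subunits = 0:3,
                           atoms = "all-nonH") {
  stopifnot(all(subunits %in% 0:3))
  structure(list(res_ids = res_ids, subunits = as.integer(subunits),
                 atoms = atoms), class = "selection_spec")
}

#' Resolve a selection to sorted atom indices
#'
#' @param topology a [channel_topology()]
#' @param spec a [selection_spec()]
#' @param allow_empty return integer(0) instead of erroring when nothing
#'   matches (used internally when residues legitimately lack atoms of a
#'   class, e.g. glycine side chains)
#' @return sorted integer vector of atom indices (1-based)
#' @export
resolve_selection <- function(topology, spec, allow_empty = FALSE) {
  a <- topology$atoms
  keep <- a$subunit %in% spec$subunits
  if (!is.null(spec$res_ids)) keep <- keep & a$res_id %in% spec$res_ids
  filt <- spec$atoms
  if (length(filt) == 1L && filt %in% c(
    "CA", "CB", "backbone-O", "sidechain-nonH", "sidechain-O",
    "sidechain-N", "all-nonH", "backbone")) {
    keep <- keep & switch(filt,
      "CA" = a$name == "CA",
      "CB" = a$name == "CB",
      "backbone-O" = a$name == "O",
      "sidechain-nonH" = !a$is_backbone & !a$is_hydrogen,
      "sidechain-O" = !a$is_backbone & toupper(a$element) == "O",
      "sidechain-N" = !a$is_backbone & toupper(a$element) == "N",
      "all-nonH" = !a$is_hydrogen,
      "backbone" = a$is_backbone)
  } else {
    keep <- keep & a$name %in% filt
  }
  idx <- sort(which(keep))
  if (length(idx) == 0 && !allow_empty)
    stop("selection is empty (res_ids = ",
         paste(spec$res_ids, collapse = ","), "; subunits = ",
         paste(spec$subunits, collapse = ","), "; atoms = ",
         paste(spec$atoms, collapse = ","), ")")
  idx
}

guess_element <- function(name) {
  nm <- gsub("^[0-9]+", "", toupper(name))
  ifelse(substr(nm, 1, 1) == "H", "H", substr(nm, 1, 1))
}

scan_model_atom_counts <- function(lines) {
  # counts ATOM/HETATM records per MODEL block; a file without MODEL
  # records is a single implicit model
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0) {
    return(sum(grepl("^(ATOM|HETATM)", lines)))
  }
  ends <- c(model_starts[-1] - 1L, length(lines))
  vapply(seq_along(model_starts), function(k) {
    blk <- lines[model_starts[k]:ends[k]]
    sum(grepl("^(ATOM|HETATM)", blk))
  }, integer(1))
}

#' Read a multi-model PDB file as an ensemble
#'
#' Each MODEL/ENDMDL block becomes one frame; the four chains are mapped
#' onto subunit indices via `chain_map`. Atom order must be identical
#' across models.
#'
#' @param path PDB file
#' @param chain_map named integer vector mapping chain IDs to subunits
#'   0..3 (default `c(A=0, B=1, C=2, D=3)`)
#' @param replica_id replica id recorded for all frames of this file
#' @param state_label ensemble state tag
#' @return a [channel_ensemble()]
#' @export
read_multimodel_pdb <- function(path, chain_map = c(A = 0, B = 1, C = 2, D = 3),
                                replica_id = 1L, state_label = "state") {
  if (!file.exists(path)) stop("no such file: ", path)
  counts <- scan_model_atom_counts(readLines(path, warn = FALSE))
  if (length(counts) > 1 && length(unique(counts)) > 1) {
    bad <- which(counts != counts[1])[1]
    stop(sprintf(
      "model %d has %d atoms where model 1 has %d (file %s)",
      bad, counts[bad], counts[1], path))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  unknown <- setdiff(unique(at$chain), names(chain_map))
  if (length(unknown) > 0)
    stop("chain(s) not in chain_map: ", paste(unknown, collapse = ", "))
  elem <- at$elesy
  elem[is.na(elem) | elem == ""] <- guess_element(at$elety[is.na(elem) | elem == ""])
  atoms <- data.frame(
    serial = at$eleno, name = at$elety, element = elem,
    res_name = at$resid, res_id = at$resno,
    subunit = as.integer(chain_map[at$chain]),
    stringsAsFactors = FALSE)
  # reorder so that subunits come in 0..3 blocks (stable within subunit)
  ord <- order(atoms$subunit, seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  topo <- channel_topology(atoms)
  nf <- nrow(pdb$xyz)
  coords <- array(NA_real_, c(nrow(atoms), 3, nf))
  for (k in seq_len(nf)) {
    m <- matrix(pdb$xyz[k, ], ncol = 3, byrow = TRUE)
    coords[, , k] <- m[ord, , drop = FALSE]
  }
  channel_ensemble(topo, coords, replica = rep(as.integer(replica_id), nf),
                   state_label = state_label)
}

#' Write an ensemble as multi-model PDB file(s)
#'
#' Subunits 0-3 are written as chains A-D, coordinates at PDB precision
#' (3 decimals). An ensemble with several replicas is written as one file
#' per replica, suffixed `_rep<replica_id>` before the extension.
#'
#' @param ensemble a [channel_ensemble()]
#' @param path output file; used as a stem when several replicas exist
#' @return invisibly, the vector of files written
#' @export
write_multimodel_pdb <- function(ensemble, path) {
  if (n_frames(ensemble) == 0) stop("ensemble has no frames")
  reps <- unique(ensemble$replica)
  a <- ensemble$topology$atoms
  chain <- c("A", "B", "C", "D")[a$subunit + 1L]
  files <- character(0)
  for (r in reps) {
    f <- if (length(reps) == 1) path else {
      ext <- sub("^.*(\\.[A-Za-z0-9]+)$", "\\1", path)
      if (ext == path) ext <- ""
      stem <- if (nzchar(ext)) substr(path, 1, nchar(path) - nchar(ext)) else path
      paste0(stem, "_rep", r, ext)
    }
    idx <- which(ensemble$replica == r)
    xyz <- t(vapply(idx, function(k) as.numeric(t(ensemble$coords[, , k])),
                    numeric(3 * nrow(a))))
    bio3d::write.pdb(pdb = NULL, file = f, xyz = xyz,
                     type = rep("ATOM", nrow(a)),
                     resno = a$res_id, resid = a$res_name,
                     eleno = a$serial, elety = a$name, chain = chain,
                     elesy = a$element)
    files <- c(files, f)
  }
  invisible(files)
}

#' Read one ensemble from a set of per-replica PDB files
#'
#' @param paths character vector of multi-model PDB files, one per replica
#' @param replica_regex regex with one capture group extracting the
#'   replica id from the file name (default `"_rep([0-9]+)"`); when it
#'   does not match, replicas are numbered by position
#' @inheritParams read_multimodel_pdb
#' @export
read_ensemble_files <- function(paths, chain_map = c(A = 0, B = 1, C = 2, D = 3),
                                replica_regex = "_rep([0-9]+)",
                                state_label = "state") {
  stopifnot(length(paths) >= 1)
  ids <- regmatches(basename(paths), regexec(replica_regex, basename(paths)))
  rep_ids <- vapply(seq_along(paths), function(k) {
    if (length(ids[[k]]) == 2) as.integer(ids[[k]][2]) else k
  }, integer(1))
  parts <- lapply(seq_along(paths), function(k)
    read_multimodel_pdb(paths[k], chain_map, replica_id = rep_ids[k],
                        state_label = state_label))
  topo <- parts[[1]]$topology
  for (p in parts[-1])
    if (!identical(dim(p$coords)[1], dim(parts[[1]]$coords)[1]))
      stop("replica files disagree in atom count")
  coords <- array(unlist(lapply(parts, function(p) p$coords)),
                  c(n_atoms(parts[[1]]), 3,
                    sum(vapply(parts, n_frames, integer(1)))))
  replica <- unlist(lapply(parts, function(p) p$replica))
  channel_ensemble(topo, coords, replica, state_label)
}
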