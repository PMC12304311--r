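#' Parse a multi-model PDB file into a state ensemble
#'
#' Reads MODEL/ENDMDL blocks (NMR-style ensembles; a file without MODEL
#' records is treated as a single implicit model) and reduces every model to
#' representative-atom coordinates: the Cbeta atom for non-glycine residues,
#' the Calpha atom for glycine. Residues lacking their representative atom
#' are dropped consistently across all models and the drops are reported via
#' `message()`. Heteroatoms, waters and ligands are ignored.
#'
#' Alternate locations are resolved to the highest-occupancy altloc, ties
#' broken by altloc identifier order, so parsing is deterministic.
#'
#' @param file path to a PDB file, or a character vector of PDB lines.
#' @param state_label name to attach to the resulting ensemble.
#' @param chains optional chain filter; by default the first protein chain
#'   in the file is used.
#' @return a [state_ensemble()] with one [conformer()] per model.
#' @export
parse_multimodel_structure <- function(file, state_label = "state", chains = NULL) {
  if (length(file) > 1L || grepl("\n", file[1], fixed = TRUE)) {
    lines <- unlist(strsplit(file, "\n", fixed = TRUE))
    file <- tempfile(fileext = ".pdb")
    on.exit(unlink(file), add = TRUE)
    writeLines(lines, file)
  } else {
    if (!file.exists(file)) stop("no such file: ", file)
    lines <- readLines(file)
  }
  .check_atom_records(lines)

  pdb <- bio3d::read.pdb(file, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  atom <- pdb$atom
  is_atom <- atom$type == "ATOM"
  if (!any(is_atom)) stop("zero usable residues: no ATOM records")

  keep_chain <- if (is.null(chains)) {
    atom$chain[which(is_atom)[1L]]
  } else {
    chains
  }
  sel <- is_atom & atom$chain %in% keep_chain &
    atom$elety %in% c("CA", "CB")
  if (!any(sel)) stop("zero usable residues in chain(s) ",
                      paste(keep_chain, collapse = ","))

  at <- atom[sel, , drop = FALSE]
  at$row <- which(sel)  # row in the full atom table, for xyz lookup
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$key <- paste(at$chain, at$resno, at$insert, sep = "|")

  # altloc: per residue+atom-name keep highest occupancy, ties by altloc order
  at <- at[order(at$key, at$elety, -at$o, at$alt), , drop = FALSE]
  at <- at[!duplicated(paste(at$key, at$elety)), , drop = FALSE]

  res_keys <- unique(at$key)
  rep_row <- integer(0)
  keep_key <- character(0)
  dropped <- character(0)
  for (k in res_keys) {
    rows <- at[at$key == k, , drop = FALSE]
    resname <- rows$resid[1L]
    want <- if (identical(resname, "GLY")) "CA" else "CB"
    hit <- which(rows$elety == want)
    if (length(hit) == 1L) {
      rep_row <- c(rep_row, rows$row[hit])
      keep_key <- c(keep_key, k)
    } else {
      dropped <- c(dropped, paste0(rows$chain[1L], ":", rows$resno[1L],
                                   " (", resname, ", no ", want, ")"))
    }
  }
  if (length(dropped)) {
    message("dropped ", length(dropped), " residue(s) lacking their representative atom: ",
            paste(dropped, collapse = ", "))
  }
  if (length(rep_row) == 0L) stop("zero usable residues after representative-atom selection")

  kept <- at[match(keep_key, at$key), , drop = FALSE]
  ord <- order(kept$chain, kept$resno)
  kept <- kept[ord, , drop = FALSE]
  rep_row <- rep_row[ord]
  ids <- residue_ids(kept$chain, kept$resno, kept$resid)

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n_models <- nrow(xyz)
  confs <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    co <- cbind(xyz[m, 3L * (rep_row - 1L) + 1L],
                xyz[m, 3L * (rep_row - 1L) + 2L],
                xyz[m, 3L * (rep_row - 1L) + 3L])
    if (!all(is.finite(co))) {
      stop("model ", m, " is missing coordinates for residues: ",
           paste(ids$label[!stats::complete.cases(co)], collapse = ", "))
    }
    confs[[m]] <- conformer(ids, co)
  }
  state_ensemble(state_label, confs)
}

# Pre-scan ATOM/HETATM records: numeric coordinate fields and consistent
# per-model ATOM counts, with line-numbered errors (bio3d is permissive).
.check_atom_records <- function(lines) {
  is_rec <- grepl("^(ATOM  |HETATM)", lines)
  for (ln in which(is_rec)) {
    l <- lines[ln]
    if (nchar(l) < 54L) stop("malformed ATOM record at line ", ln, ": too short")
    xyz <- c(substr(l, 31, 38), substr(l, 39, 46), substr(l, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(xyz)))) {
      stop("malformed ATOM record at line ", ln, ": non-numeric coordinates")
    }
  }
  model_starts <- grep("^MODEL", lines)
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_starts) != length(model_ends)) {
    stop("unbalanced MODEL/ENDMDL records (",
         length(model_starts), " MODEL vs ", length(model_ends), " ENDMDL)")
  }
  if (length(model_starts) > 1L) {
    counts <- mapply(function(a, b) sum(is_rec[a:b]), model_starts, model_ends)
    if (length(unique(counts)) != 1L) {
      stop("models have inconsistent atom counts: ",
           paste(counts, collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Assemble per-state average distance matrices into a state library
#'
#' @param ensembles named list of [state_ensemble()] objects (names are the
#'   state labels), or a list whose elements carry `state_label`s.
#' @return an object of class `state_library` with fields `states`,
#'   `matrices` (one average [distance_matrix()] per state) and
#'   `residue_ids` (the shared index).
#' @export
state_library <- function(ensembles) {
  if (length(ensembles) < 2L) stop("a state library needs at least 2 states for reweighting")
  labels <- unname(vapply(ensembles, function(e) e$state_label, ""))
  if (anyDuplicated(labels)) stop("state labels must be unique")
  ref <- ensembles[[1L]]$residue_ids$label
  for (k in seq_along(ensembles)) {
    if (!identical(ensembles[[k]]$residue_ids$label, ref)) {
      bad <- c(setdiff(ref, ensembles[[k]]$residue_ids$label),
               setdiff(ensembles[[k]]$residue_ids$label, ref))
      stop("state ", labels[k], " has a mismatched residue index: ",
           paste(utils::head(bad, 10L), collapse = ", "))
    }
  }
  mats <- lapply(ensembles, average_distance_matrix)
  names(mats) <- labels
  structure(list(states = labels, matrices = mats,
                 residue_ids = ensembles[[1L]]$residue_ids),
            class = "state_library")
}

#' @export
print.state_library <- function(x, ...) {
  cat("state_library:", length(x$states), "states (",
      paste(x$states, collapse = ", "), "),",
      nrow(x$residue_ids), "residues\n")
  invisible(x)
}
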