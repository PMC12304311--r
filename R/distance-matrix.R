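#' Residue identity table
#'
#' Residues are identified publicly by author chain id and author residue
#' number as printed in the structure file ("chain:resnum"); matrices carry
#' these labels as dimnames. Internal matrix indices are positional with an
#' explicit id-to-index map, so files with different numbering schemes are
#' never renumbered silently.
#'
#' @param chain character vector of chain ids.
#' @param resno integer vector of author residue numbers.
#' @param resname character vector of three-letter residue names.
#' @return a data.frame with columns `chain`, `resno`, `resname`, `label`.
#' @export
residue_ids <- function(chain, resno, resname) {
  stopifnot(length(chain) == length(resno), length(resno) == length(resname))
  df <- data.frame(chain = as.character(chain),
                   resno = as.integer(resno),
                   resname = as.character(resname),
                   stringsAsFactors = FALSE)
  df$label <- paste0(df$chain, ":", df$resno)
  if (anyDuplicated(df$label)) {
    stop("duplicate residue identities: ",
         paste(unique(df$label[duplicated(df$label)]), collapse = ", "))
  }
  # strictly ordered within each chain
  for (ch in unique(df$chain)) {
    r <- df$resno[df$chain == ch]
    if (any(diff(r) <= 0)) stop("residue numbers not strictly increasing in chain ", ch)
  }
  df
}

#' Single conformer of representative-atom coordinates
#'
#' One structural model reduced to one point per residue: the Cbeta atom for
#' non-glycine residues and the Calpha atom for glycine.
#'
#' @param ids residue identity table from [residue_ids()].
#' @param coords numeric matrix, one row per residue, columns x/y/z in Angstrom.
#' @return an object of class `conformer`.
#' @export
conformer <- function(ids, coords) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, nrow(coords) == nrow(ids))
  if (!all(is.finite(coords))) stop("non-finite coordinates in conformer")
  rownames(coords) <- ids$label
  structure(list(residue_ids = ids, coords = coords), class = "conformer")
}

#' A conformational state as an ensemble of conformers
#'
#' @param state_label name of the state (e.g. "A", "I1", "I2").
#' @param conformers list of [conformer()] objects sharing one residue table.
#' @return an object of class `state_ensemble` with fields `state_label`,
#'   `conformers`, `n_conf`, `residue_ids`.
#' @export
state_ensemble <- function(state_label, conformers) {
  if (length(conformers) < 1L) stop("state ensemble needs at least one conformer")
  ref <- conformers[[1L]]$residue_ids$label
  for (k in seq_along(conformers)) {
    if (!identical(conformers[[k]]$residue_ids$label, ref)) {
      stop("conformer ", k, " has a different residue set than conformer 1")
    }
  }
  structure(list(state_label = state_label,
                 conformers = conformers,
                 n_conf = length(conformers),
                 residue_ids = conformers[[1L]]$residue_ids),
            class = "state_ensemble")
}

#' Symmetric inter-residue distance matrix
#'
#' @param values symmetric numeric matrix of distances (Angstrom), zero diagonal.
#' @param ids residue identity table; labels become dimnames.
#' @param mask logical matrix of per-pair validity (TRUE = usable); defaults
#'   to all TRUE off the diagonal.
#' @return an object of class `distance_matrix`.
#' @export
distance_matrix <- function(values, ids, mask = NULL) {
  values <- as.matrix(values)
  n <- nrow(ids)
  stopifnot(nrow(values) == n, ncol(values) == n)
  if (is.null(mask)) mask <- matrix(TRUE, n, n)
  stopifnot(identical(dim(mask), dim(values)))
  diag(mask) <- TRUE  # diagonal is identically zero and always valid
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-8))) {
    stop("distance matrix is not symmetric")
  }
  if (any(abs(diag(values)) > 1e-9)) stop("distance matrix diagonal is not zero")
  off <- values[mask & row(values) != col(values)]
  if (any(!is.finite(off)) || any(off <= 0)) {
    stop("unmasked off-diagonal distances must be finite and positive")
  }
  dimnames(values) <- list(ids$label, ids$label)
  dimnames(mask) <- dimnames(values)
  structure(list(values = values, residue_ids = ids, mask = mask),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("distance_matrix:", nrow(x$values), "residues,",
      sum(x$mask[upper.tri(x$mask)]), "of",
      sum(upper.tri(x$mask)), "pairs unmasked\n")
  invisible(x)
}

#' Pairwise distances of one conformer
#'
#' Euclidean distances between representative atoms, the per-model matrices
#' that state averages are built from.
#'
#' @param c a [conformer()].
#' @return a [distance_matrix()].
#' @export
conformer_distance_matrix <- function(c) {
  stopifnot(inherits(c, "conformer"))
  if (!all(is.finite(c$coords))) stop("non-finite coordinates")
  d <- as.matrix(stats::dist(c$coords))
  distance_matrix(d, c$residue_ids)
}

#' State-average distance matrix
#'
#' Elementwise mean of the per-conformer distance matrices of an ensemble;
#' the per-state matrix used by the reweighting objective.
#'
#' @param e a [state_ensemble()].
#' @return a [distance_matrix()].
#' @export
average_distance_matrix <- function(e) {
  stopifnot(inherits(e, "state_ensemble"))
  if (e$n_conf < 1L) stop("empty ensemble")
  acc <- conformer_distance_matrix(e$conformers[[1L]])$values
  if (e$n_conf > 1L) {
    for (k in 2:e$n_conf) {
      acc <- acc + conformer_distance_matrix(e$conformers[[k]])$values
    }
  }
  distance_matrix(acc / e$n_conf, e$residue_ids)
}

#' Difference distance matrix between two states
#'
#' Signed elementwise difference `a - b`; antisymmetric under argument swap.
#' Used to localize where two conformational states diverge.
#'
#' @param a,b [distance_matrix()] objects sharing residue identities.
#' @return a plain numeric matrix (Angstrom) with residue-label dimnames.
#' @export
difference_distance_matrix <- function(a, b) {
  stopifnot(inherits(a, "distance_matrix"), inherits(b, "distance_matrix"))
  if (!identical(a$residue_ids$label, b$residue_ids$label)) {
    unmatched <- c(setdiff(a$residue_ids$label, b$residue_ids$label),
                   setdiff(b$residue_ids$label, a$residue_ids$label))
    stop("residue index mismatch: ", paste(unmatched, collapse = ", "))
  }
  a$values - b$values
}

#' Per-conformer distance samples for one residue pair
#'
#' @param e a [state_ensemble()].
#' @param i,j residue labels ("chain:resnum") or positional indices.
#' @return numeric vector of length `n_conf`, conformer order preserved.
#' @export
pair_distance_samples <- function(e, i, j) {
  stopifnot(inherits(e, "state_ensemble"))
  idx <- function(r) {
    if (is.character(r)) {
      m <- match(r, e$residue_ids$label)
      if (is.na(m)) stop("unknown residue id: ", r)
      m
    } else {
      r <- as.integer(r)
      if (r < 1L || r > nrow(e$residue_ids)) stop("residue index out of range: ", r)
      r
    }
  }
  ii <- idx(i); jj <- idx(j)
  if (ii == jj) stop("degenerate pair: i and j refer to the same residue")
  vapply(e$conformers, function(cf) {
    sqrt(sum((cf$coords[ii, ] - cf$coords[jj, ])^2))
  }, numeric(1))
}

#' Write / read a distance matrix as TSV
#'
#' Row and column headers are residue labels ("chain:resnum"); values are in
#' Angstrom. Masked entries are written as NA.
#'
#' @param x a [distance_matrix()].
#' @param path output file.
#' @return `path`, invisibly (writer); a [distance_matrix()] (reader).
#' @export
write_distance_tsv <- function(x, path) {
  stopifnot(inherits(x, "distance_matrix"))
  v <- x$values
  v[!x$mask] <- NA_real_
  df <- data.frame(residue = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @param resnames optional residue names for the reconstructed identity
#'   table (the TSV stores only chain:resnum labels); defaults to "UNK".
#' @export
read_distance_tsv <- function(path, resnames = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  labs <- df$residue
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- labs
  parts <- strsplit(labs, ":", fixed = TRUE)
  ids <- residue_ids(vapply(parts, `[`, "", 1L),
                     as.integer(vapply(parts, `[`, "", 2L)),
                     resnames %||% rep("UNK", length(labs)))
  mask <- !is.na(v)
  v[is.na(v)] <- 0
  v <- (v + t(v)) / 2  # guard against asciification round-off
  distance_matrix(v, ids, mask & t(mask))
}

#' Binary matrix container with JSON sidecar
#'
#' Doubles in native endianness plus a sidecar `<path>.json` carrying the
#' residue identities, matrix dimension and units, for large matrices where
#' TSV is wasteful.
#'
#' @param x a [distance_matrix()].
#' @param path output file (sidecar written alongside).
#' @export
write_distance_bin <- function(x, path) {
  stopifnot(inherits(x, "distance_matrix"))
  con <- file(path, "wb")
  on.exit(close(con))
  v <- x$values
  v[!x$mask] <- NA_real_
  writeBin(as.vector(v), con, size = 8L)
  side <- list(n_res = nrow(v), units = "angstrom", order = "column-major",
               residue_ids = x$residue_ids[, c("chain", "resno", "resname")])
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_distance_bin
#' @export
read_distance_bin <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- side$n_res
  con <- file(path, "rb")
  on.exit(close(con))
  v <- matrix(readBin(con, "double", n * n, size = 8L), n, n)
  ids <- residue_ids(side$residue_ids$chain, side$residue_ids$resno,
                     side$residue_ids$resname)
  mask <- !is.na(v)
  v[is.na(v)] <- 0
  distance_matrix(v, ids, mask & t(mask))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
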