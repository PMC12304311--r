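#' Harmonize activity measurements onto a pKd-equivalent scale
#'
#' Activity values (molar Kd, Ki or IC50) are converted to their negative
#' base-10 logarithm; IC50-derived values additionally receive a +0.35 log
#' unit offset to place them on the pKd scale, equivalent to dividing the
#' IC50 by a constant factor. (Note log10(2.3) = 0.3617; the conventional
#' offset applied here is exactly 0.35, and the two round-tripped constants
#' disagree slightly — the offset is the operative rule.) Kd and Ki are
#' treated without distinction.
#'
#' Passing an already-harmonized record back in is rejected, so the offset
#' can never be applied twice.
#'
#' @param measure character vector: "Kd", "Ki" or "IC50".
#' @param value positive concentrations in molar units.
#' @param compound optional compound ids.
#' @return a data.frame of class `activity_record` with columns `compound`,
#'   `measure`, `value`, `p_value` (-log10 molar) and `harmonized_pkd`.
#' @export
harmonize_activity <- function(measure, value, compound = NULL) {
  if (inherits(measure, "activity_record") || inherits(value, "activity_record")) {
    stop("input is already harmonized; refusing to apply the offset twice")
  }
  measure <- as.character(measure)
  bad <- setdiff(unique(measure), c("Kd", "Ki", "IC50"))
  if (length(bad)) stop("unknown measure type(s): ", paste(bad, collapse = ", "))
  value <- as.numeric(value)
  if (any(!is.finite(value)) || any(value <= 0)) {
    stop("activity values must be positive finite molar concentrations")
  }
  p <- -log10(value)
  out <- data.frame(compound = compound %||% paste0("cpd", seq_along(value)),
                    measure = measure, value = value, p_value = p,
                    harmonized_pkd = p + ifelse(measure == "IC50", 0.35, 0),
                    stringsAsFactors = FALSE)
  class(out) <- c("activity_record", "data.frame")
  out
}

#' Truncate a distance label to the modelled range
#'
#' Distance labels are clamped to the 1-20 Angstrom range the distance
#' predictor operates on.
#'
#' @param d numeric distances (Angstrom).
#' @param lo,hi truncation bounds (Angstrom).
#' @return clamped distances.
#' @export
truncate_distance_label <- function(d, lo = 1, hi = 20) {
  if (any(!is.finite(d))) stop("non-finite distance label")
  pmin(pmax(d, lo), hi)
}

#' Curate protein-ligand complex records
#'
#' Keeps complexes with exactly one parseable ligand, at most `max_atoms`
#' ligand atoms and at most `max_length` protein residues (both bounds
#' inclusive); every dropped record gets a single reason (the first failing
#' check in the fixed order unparseable > multiple/zero ligands > ligand
#' size > protein length), so the drop reasons partition the dropped set.
#'
#' @param records data.frame with columns `protein_length`, `ligand_atoms`,
#'   `n_ligands`, `parseable` (logical); extra columns pass through.
#' @param max_length maximum protein length kept (residues).
#' @param max_atoms maximum ligand atom count kept.
#' @return list with `kept` (subset of `records`) and `dropped` (subset plus
#'   a `reason` column).
#' @export
curate_complexes <- function(records, max_length = 384, max_atoms = 128) {
  need <- c("protein_length", "ligand_atoms", "n_ligands", "parseable")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack column(s): ", paste(miss, collapse = ", "))
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(reason) & !records$parseable] <- "unparseable ligand"
  reason[is.na(reason) & records$n_ligands != 1L] <- "not exactly one ligand"
  reason[is.na(reason) & records$ligand_atoms > max_atoms] <- "ligand too large"
  reason[is.na(reason) & records$protein_length > max_length] <- "protein too long"
  kept <- records[is.na(reason), , drop = FALSE]
  dropped <- records[!is.na(reason), , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- reason[!is.na(reason)]
  else dropped$reason <- character(0)
  list(kept = kept, dropped = dropped)
}

# per-column min-max scaling to [0,1]; constant columns map to 0.5
.minmax_cols <- function(m, what) {
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    rng <- range(x, na.rm = TRUE)
    if (!all(is.finite(rng))) stop("column ", colnames(m)[j] %||% j, " is all-missing")
    if (rng[2] - rng[1] < .Machine$double.eps) {
      warning("constant ", what, " column '", colnames(m)[j] %||% j,
              "'; normalized scores set to 0.5")
      out[, j] <- ifelse(is.na(x), NA_real_, 0.5)
    } else {
      out[, j] <- (x - rng[1]) / (rng[2] - rng[1])
    }
  }
  out
}

#' Normalize per-model predicted affinities
#'
#' Min-max scales every model column of a compound-by-model affinity table
#' to \[0, 1\], preserving within-column rank order; higher means stronger
#' predicted affinity. Constant columns map to 0.5 with a warning.
#'
#' @param affinity numeric matrix, compounds (rows, named) by models (columns,
#'   named), of predicted affinities on a higher-is-stronger scale (e.g. pKd).
#' @return matrix of normalized scores, same shape and dimnames.
#' @export
normalize_model_scores <- function(affinity) {
  affinity <- as.matrix(affinity)
  if (length(affinity) == 0L) stop("empty affinity table")
  .minmax_cols(affinity, "affinity")
}

#' Overall affinity score: conservative min-aggregate over models
#'
#' Per compound, the minimum normalized predicted affinity across the model
#' columns — a compound only scores high when every model agrees. Compounds
#' with any missing prediction are flagged ineligible (NA score) rather than
#' imputed, since a min over imputed values silently inflates scores.
#'
#' @param normalized matrix from [normalize_model_scores()].
#' @return data.frame with columns `compound`, `overall_score`, `eligible`.
#' @export
overall_affinity_score <- function(normalized) {
  normalized <- as.matrix(normalized)
  eligible <- !apply(normalized, 1L, anyNA)
  score <- ifelse(eligible, apply(normalized, 1L, min), NA_real_)
  data.frame(compound = rownames(normalized) %||% paste0("cpd", seq_len(nrow(normalized))),
             overall_score = score, eligible = eligible,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-model compound ranks
#'
#' Competition ("min") ranking within each model column, rank 1 = strongest
#' predicted affinity; tied compounds share the better rank.
#'
#' @inheritParams normalize_model_scores
#' @return integer matrix of ranks, same shape; NA predictions rank NA.
#' @export
model_ranks <- function(affinity) {
  affinity <- as.matrix(affinity)
  out <- apply(affinity, 2L, function(x) {
    r <- rep(NA_integer_, length(x))
    ok <- !is.na(x)
    r[ok] <- as.integer(rank(-x[ok], ties.method = "min"))
    r
  })
  dimnames(out) <- dimnames(affinity)
  out
}

#' Normalized ligand-to-functional-residue distance scores
#'
#' Min-max normalizes the predicted minimum ligand distance to each named
#' functional residue across the screened library: 0 = closest compound,
#' 1 = farthest. `scope = "global"` normalizes over all residues jointly
#' instead of per residue.
#'
#' @param residue_distances numeric matrix, compounds by functional residues
#'   (columns named "chain:resnum"), of minimum ligand distances (Angstrom).
#' @param residues functional residue labels to score (must be columns).
#' @param scope "per_residue" (default) or "global" normalization.
#' @return matrix of distance scores in \[0, 1\].
#' @export
distance_scores <- function(residue_distances, residues = colnames(residue_distances),
                            scope = c("per_residue", "global")) {
  scope <- match.arg(scope)
  residue_distances <- as.matrix(residue_distances)
  miss <- setdiff(residues, colnames(residue_distances))
  if (length(miss)) stop("missing functional residue column(s): ",
                         paste(miss, collapse = ", "))
  m <- residue_distances[, residues, drop = FALSE]
  if (any(m < 0, na.rm = TRUE)) stop("distances must be nonnegative")
  if (scope == "per_residue") return(.minmax_cols(m, "distance"))
  rng <- range(m, na.rm = TRUE)
  if (rng[2] - rng[1] < .Machine$double.eps) {
    warning("constant distance table; scores set to 0.5")
    return(matrix(0.5, nrow(m), ncol(m), dimnames = dimnames(m)))
  }
  (m - rng[1]) / (rng[2] - rng[1])
}

#' Candidate selection criteria
#'
#' Defaults mirror the screening rule: select a compound when its overall
#' affinity score exceeds `overall_score_min` OR it ranks better than
#' `rank_cutoff` (1-based, strictly below, so ranks 1 to 9 by default) in
#' any single model, AND all of its functional-residue distance scores are
#' strictly below `distance_score_max`.
#'
#' @param overall_score_min overall-affinity-score threshold (default 0.3).
#' @param rank_cutoff per-model rank cutoff, exclusive (default 10).
#' @param distance_score_max distance-score ceiling, exclusive (default 0.5).
#' @param residues functional residue labels the distance clause applies to.
#' @return a list of class `selection_criteria`.
#' @export
selection_criteria <- function(overall_score_min = 0.3, rank_cutoff = 10,
                               distance_score_max = 0.5, residues = NULL) {
  stopifnot(overall_score_min >= 0, overall_score_min <= 1,
            rank_cutoff >= 1, distance_score_max >= 0, distance_score_max <= 1)
  structure(list(overall_score_min = overall_score_min,
                 rank_cutoff = rank_cutoff,
                 distance_score_max = distance_score_max,
                 residues = residues),
            class = "selection_criteria")
}

#' Select screening candidates
#'
#' Applies the selection rule of [selection_criteria()] and records, per
#' selected compound, which affinity clause fired together with its scores
#' and best rank. Ineligible compounds (missing predictions) are never
#' selected.
#'
#' @param scores data.frame from [overall_affinity_score()].
#' @param ranks matrix from [model_ranks()].
#' @param dscores matrix from [distance_scores()].
#' @param criteria a [selection_criteria()].
#' @return an object of class `candidate_set`: `selected` (compound ids) and
#'   `rationale` (per-compound data.frame of clause outcomes for all
#'   compounds, selected or not).
#' @export
select_candidates <- function(scores, ranks, dscores, criteria = selection_criteria()) {
  stopifnot(inherits(criteria, "selection_criteria"))
  ids <- scores$compound
  if (!identical(ids, rownames(ranks) %||% ids) &&
      !identical(sort(ids), sort(rownames(ranks)))) {
    stop("compound index mismatch between scores and ranks")
  }
  ranks <- ranks[ids, , drop = FALSE]
  dscores <- dscores[ids, , drop = FALSE]
  if (!is.null(criteria$residues)) {
    dscores <- dscores[, criteria$residues, drop = FALSE]
  }
  best_rank <- suppressWarnings(apply(ranks, 1L, min, na.rm = TRUE))
  best_rank[!is.finite(best_rank)] <- NA_integer_
  worst_d <- apply(dscores, 1L, max)
  score_clause <- !is.na(scores$overall_score) &
    scores$overall_score > criteria$overall_score_min
  rank_clause <- !is.na(best_rank) & best_rank < criteria$rank_cutoff
  dist_clause <- !is.na(worst_d) & worst_d < criteria$distance_score_max
  selected <- scores$eligible & (score_clause | rank_clause) & dist_clause
  rationale <- data.frame(compound = ids,
                          overall_score = scores$overall_score,
                          best_rank = best_rank,
                          max_distance_score = worst_d,
                          eligible = scores$eligible,
                          score_clause = score_clause,
                          rank_clause = rank_clause,
                          distance_clause = dist_clause,
                          selected = selected,
                          stringsAsFactors = FALSE, row.names = NULL)
  rationale$fired <- ifelse(!selected, "",
                            ifelse(score_clause & rank_clause, "score+rank",
                                   ifelse(score_clause, "score", "rank")))
  structure(list(selected = ids[selected], rationale = rationale,
                 criteria = criteria),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("candidate_set:", length(x$selected), "of", nrow(x$rationale),
      "compounds selected\n")
  if (length(x$selected)) cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
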