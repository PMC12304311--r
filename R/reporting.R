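#' Run the state-library stage and write its artifacts
#'
#' Builds the state library from the given ensembles, then writes to
#' `out_dir`: per-state average distance matrices (TSV), pairwise difference
#' distance matrices, the per-pair ANOVA F map, the top discriminative
#' pairs, per-pair distance-distribution summaries for those pairs, and a
#' config echo (JSON). Reruns from the same inputs are byte-identical.
#'
#' @param ensembles named list of [state_ensemble()] objects, or the
#'   `ensembles` element of [generate_state_library()].
#' @param out_dir output directory (created if needed).
#' @param top_k how many discriminative pairs to summarize.
#' @param config optional config echo to serialize alongside the outputs.
#' @return invisibly, a list with the `library`, `f_map` and `top_pairs`.
#' @export
run_states <- function(ensembles, out_dir, top_k = 4L, config = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lib <- state_library(ensembles)
  for (s in lib$states) {
    write_distance_tsv(lib$matrices[[s]], file.path(out_dir, paste0("state_", s, "_mean.tsv")))
  }
  cmb <- utils::combn(lib$states, 2L)
  for (k in seq_len(ncol(cmb))) {
    a <- cmb[1L, k]; b <- cmb[2L, k]
    dd <- difference_distance_matrix(lib$matrices[[b]], lib$matrices[[a]])
    utils::write.table(data.frame(residue = rownames(dd), dd, check.names = FALSE),
                       file.path(out_dir, paste0("diff_", b, "_minus_", a, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  fm <- anova_f_map(ensembles)
  write_f_map_tsv(fm, file.path(out_dir, "f_map.tsv"))
  tp <- top_discriminative_pairs(fm, top_k)
  utils::write.table(tp, file.path(out_dir, "top_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  # per-state distribution summaries for the top pairs
  summ <- do.call(rbind, lapply(seq_len(nrow(tp)), function(r) {
    do.call(rbind, lapply(ensembles, function(e) {
      x <- pair_distance_samples(e, tp$i[r], tp$j[r])
      data.frame(i = tp$i[r], j = tp$j[r], state = e$state_label,
                 mean = mean(x), sd = stats::sd(x), stringsAsFactors = FALSE)
    }))
  }))
  if (!is.null(summ)) {
    utils::write.table(summ, file.path(out_dir, "top_pair_distributions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  .write_config_echo(config, out_dir, "states")
  invisible(list(library = lib, f_map = fm, top_pairs = tp))
}

#' Run the reweighting stage over a ligand panel and write the report
#'
#' Fits state populations for every prediction in the panel and writes a
#' per-ligand table (weights, MSE, pair count, coverage, predominant state,
#' margin), optional per-state shifts against an apo baseline, and, when a
#' panel truth is supplied, a recovery-accuracy column plus a grouped
#' summary of mean recovered weights by planted state.
#'
#' @param lib a [state_library()].
#' @param panel named list of predicted distance matrices.
#' @param out_dir output directory.
#' @param apo optional apo-baseline prediction (same type as panel entries).
#' @param truth optional `synthetic_truth` from [generate_ligand_panel()].
#' @param config optional config echo.
#' @return invisibly, the per-ligand report data.frame.
#' @export
run_reweight <- function(lib, panel, out_dir, apo = NULL, truth = NULL,
                         config = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(names(panel))) names(panel) <- sprintf("L%02d", seq_along(panel))
  apo_w <- if (!is.null(apo)) reweight_populations(apo, lib)$weights else NULL
  rows <- lapply(names(panel), function(lg) {
    r <- reweight_populations(panel[[lg]], lib)
    ps <- predominant_state(r)
    row <- data.frame(ligand = lg, t(as.numeric(r$weights)),
                      mse = r$mse, n_pairs = r$n_pairs, coverage = r$coverage,
                      converged = r$converged,
                      predominant = ps$state, margin = ps$margin,
                      ambiguous = ps$ambiguous, stringsAsFactors = FALSE)
    names(row)[2:(1 + length(lib$states))] <- paste0("w_", lib$states)
    if (!is.null(apo_w)) {
      sh <- population_shift(r$weights, apo_w)
      shr <- data.frame(t(sh))
      names(shr) <- paste0("shift_", lib$states)
      row <- cbind(row, shr)
    }
    row
  })
  report <- do.call(rbind, rows)
  if (!is.null(truth)) {
    planted <- truth$dominant_states[report$ligand]
    report$planted_state <- unname(planted)
    report$recovered <- report$predominant == report$planted_state
  }
  utils::write.table(report, file.path(out_dir, "populations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "populations.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(truth)) {
    grp <- stats::aggregate(report[paste0("w_", lib$states)],
                            by = list(planted_state = report$planted_state), mean)
    utils::write.table(grp, file.path(out_dir, "group_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  .write_config_echo(config, out_dir, "reweight")
  invisible(report)
}

#' Run the screening-triage stage and write the candidate report
#'
#' Normalizes the affinity table, computes overall scores, per-model ranks
#' and distance scores, applies the selection criteria, and writes the
#' normalized tables, the candidate CSV and the per-compound rationale JSON
#' plus summary counts.
#'
#' @param affinity compounds-by-models affinity matrix (higher = stronger).
#' @param residue_distances compounds-by-functional-residue distance matrix
#'   (Angstrom).
#' @param out_dir output directory.
#' @param criteria a [selection_criteria()].
#' @param config optional config echo.
#' @return invisibly, the `candidate_set`.
#' @export
run_screen <- function(affinity, residue_distances, out_dir,
                       criteria = selection_criteria(), config = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  norm <- normalize_model_scores(affinity)
  scores <- overall_affinity_score(norm)
  ranks <- model_ranks(affinity)
  dsc <- distance_scores(residue_distances,
                         criteria$residues %||% colnames(residue_distances))
  cand <- select_candidates(scores, ranks, dsc, criteria)
  utils::write.table(data.frame(compound = rownames(norm), norm, check.names = FALSE),
                     file.path(out_dir, "normalized_affinity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(compound = rownames(dsc), dsc, check.names = FALSE),
                     file.path(out_dir, "distance_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(cand$rationale[cand$rationale$selected, , drop = FALSE],
                   file.path(out_dir, "candidates.csv"), row.names = FALSE)
  jsonlite::write_json(list(criteria = unclass(criteria),
                            n_compounds = nrow(cand$rationale),
                            n_selected = length(cand$selected),
                            rationale = cand$rationale),
                       file.path(out_dir, "rationale.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  .write_config_echo(config, out_dir, "screen")
  invisible(cand)
}

# every stage serializes its config echo so a rerun from the echo is
# byte-identical
.write_config_echo <- function(config, out_dir, stage) {
  echo <- list(stage = stage, config = if (is.null(config)) list() else unclass(config))
  jsonlite::write_json(echo, file.path(out_dir, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
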