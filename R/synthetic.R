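#' Run code under a temporary RNG seed
#'
#' Every generator is a pure function of its config (seed included): the
#' global RNG state is saved, seeded, and restored, so generation never
#' perturbs a caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-stage substream seed
#'
#' Deterministically maps (run seed, stage name) to a 31-bit seed so each
#' pipeline stage gets an independent, reproducible stream.
#'
#' @param seed integer run seed.
#' @param stage character stage name.
#' @return integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

#' Synthetic-generator configuration
#'
#' The defaults mirror the conditions of the kinase study the pipeline is
#' built around: 3 conformational states deposited as 20-model ensembles, a
#' 12-ligand panel in groups of 6/2/4 dominant on the three states, an
#' 8 Angstrom inter-state displacement of a planted contiguous block,
#' 0.3 Angstrom within-state coordinate jitter, and 0.2 Angstrom prediction
#' noise.
#'
#' @param seed mandatory integer seed.
#' @param n_states number of conformational states (>= 2 for reweighting).
#' @param n_res residues in the pseudo-chain.
#' @param n_conf conformers per state.
#' @param inter_state_displacement Angstrom displacement of the planted
#'   block between states.
#' @param intra_state_jitter per-coordinate Gaussian sd (Angstrom) within a
#'   state.
#' @param prediction_noise Gaussian sd (Angstrom) added to mixture matrices.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(seed,
                             n_states = 3L,
                             n_res = 150L,
                             n_conf = 20L,
                             inter_state_displacement = 8,
                             intra_state_jitter = 0.3,
                             prediction_noise = 0.2) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_states >= 1L, n_res >= 3L, n_conf >= 1L,
            inter_state_displacement >= 0, intra_state_jitter >= 0,
            prediction_noise >= 0)
  structure(list(seed = as.integer(seed), n_states = as.integer(n_states),
                 n_res = as.integer(n_res), n_conf = as.integer(n_conf),
                 inter_state_displacement = inter_state_displacement,
                 intra_state_jitter = intra_state_jitter,
                 prediction_noise = prediction_noise),
            class = "generator_config")
}

# self-avoiding pseudo-C-alpha chain: persistent random walk, 3.8 A steps,
# >= 3 A clearance to non-adjacent residues (best-effort with retries)
.sa_chain <- function(n_res, bond = 3.8, min_sep = 3.0, max_try = 200L) {
  coords <- matrix(0, n_res, 3L)
  dir <- c(1, 0, 0)
  for (i in 2:n_res) {
    best <- NULL
    best_min <- -Inf
    for (t in seq_len(max_try)) {
      pd <- dir + stats::rnorm(3L, sd = 0.8)
      pd <- pd / sqrt(sum(pd^2))
      cand <- coords[i - 1L, ] + bond * pd
      dmin <- if (i > 2L) {
        prev <- coords[seq_len(i - 2L), , drop = FALSE]
        min(sqrt(rowSums((prev - matrix(cand, i - 2L, 3L, byrow = TRUE))^2)))
      } else Inf
      if (dmin >= min_sep) {
        best <- cand
        dir <- pd
        break
      }
      if (dmin > best_min) {
        best_min <- dmin
        best <- cand
      }
    }
    coords[i, ] <- best
  }
  coords
}

#' Generate a synthetic state library with known ground truth
#'
#' Builds a base self-avoiding 3D chain of pseudo-residues; each state
#' beyond the first displaces one planted contiguous residue block (about a
#' fifth of the chain, recorded in the truth) by
#' `inter_state_displacement` Angstrom in a state-specific random direction;
#' each conformer adds Gaussian coordinate jitter of sd
#' `intra_state_jitter`. Distances are then derived through the regular
#' ensemble machinery, so synthetic matrices are guaranteed metric.
#' Reproducible from the config seed.
#'
#' @param cfg a [generator_config()].
#' @return list with `library` ([state_library()]), `ensembles` (named list
#'   of [state_ensemble()]), `truth` (class `synthetic_truth`: planted block
#'   range, displacement directions, config echo).
#' @export
generate_state_library <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$n_states >= 2L && cfg$inter_state_displacement == 0) {
    warning("inter_state_displacement is 0: states are indistinguishable")
  }
  state_names <- if (cfg$n_states <= 3L) {
    c("A", "I1", "I2")[seq_len(cfg$n_states)]
  } else {
    c("A", paste0("I", seq_len(cfg$n_states - 1L)))
  }
  resnames <- rep(c("ALA", "VAL", "LEU", "SER", "THR", "PHE", "GLY"),
                  length.out = cfg$n_res)
  ids <- residue_ids(rep("A", cfg$n_res), seq_len(cfg$n_res), resnames)
  .with_seed(derive_seed(cfg$seed, "state_library"), {
    base <- .sa_chain(cfg$n_res)
    blk_len <- max(3L, round(cfg$n_res / 5))
    blk_start <- sample.int(cfg$n_res - blk_len + 1L, 1L)
    block <- blk_start:(blk_start + blk_len - 1L)
    dirs <- matrix(0, cfg$n_states, 3L)
    ensembles <- vector("list", cfg$n_states)
    for (s in seq_len(cfg$n_states)) {
      coords_s <- base
      if (s > 1L) {
        u <- stats::rnorm(3L)
        u <- u / sqrt(sum(u^2))
        dirs[s, ] <- u
        coords_s[block, ] <- coords_s[block, ] +
          matrix(u * cfg$inter_state_displacement, blk_len, 3L, byrow = TRUE)
      }
      confs <- lapply(seq_len(cfg$n_conf), function(m) {
        conformer(ids, coords_s + matrix(stats::rnorm(3L * cfg$n_res,
                                                      sd = cfg$intra_state_jitter),
                                         cfg$n_res, 3L))
      })
      ensembles[[s]] <- state_ensemble(state_names[s], confs)
    }
    names(ensembles) <- state_names
    lib <- state_library(ensembles)
    truth <- structure(list(kind = "state_library",
                            planted_block = range(block),
                            displacement_dirs = dirs,
                            config = unclass(cfg)),
                       class = "synthetic_truth")
    list(library = lib, ensembles = ensembles, truth = truth)
  })
}

#' Generate a noisy "predicted" distance matrix with known mixture weights
#'
#' Emulates a distance-predictor output for a ligand-bound ensemble: the
#' convex mixture of the library's state matrices under `true_w`, plus
#' symmetric Gaussian noise (added to the mixed matrix and symmetrized by
#' averaging with its transpose, since a predictor emits matrices, not
#' coordinates), then truncated to the 1-20 Angstrom prediction range via
#' [truncate_distance_label()]. Pairs whose pre-truncation value falls
#' outside that range are saturated by the truncation and carry no mixture
#' information, so they are masked; reweighting excludes masked pairs.
#'
#' @param lib a [state_library()].
#' @param true_w simplex weights over `lib$states` (named or in state order).
#' @param noise_sd Gaussian noise sd (Angstrom).
#' @param seed integer seed.
#' @return list with `prediction` (a [distance_matrix()] with subclass
#'   `predicted_distance_matrix`) and `truth` (`synthetic_truth` carrying
#'   `true_weights`).
#' @export
generate_predicted_matrix <- function(lib, true_w, noise_sd = 0.2, seed = 1L) {
  stopifnot(inherits(lib, "state_library"))
  if (is.null(names(true_w))) names(true_w) <- lib$states
  w <- state_weights(true_w[lib$states])
  mix <- ensemble_distance(w, lib)$values
  n <- nrow(mix)
  .with_seed(derive_seed(seed, "predicted_matrix"), {
    if (noise_sd > 0) {
      E <- matrix(stats::rnorm(n * n, sd = noise_sd), n, n)
      noisy <- mix + (E + t(E)) / 2
    } else noisy <- mix
    diag(noisy) <- 0
    mask <- noisy >= 1 & noisy <= 20
    diag(mask) <- TRUE
    vals <- truncate_distance_label(noisy)
    diag(vals) <- 0
    pred <- distance_matrix(vals, lib$residue_ids, mask)
    class(pred) <- c("predicted_distance_matrix", class(pred))
    truth <- structure(list(kind = "predicted_matrix",
                            true_weights = as.numeric(w),
                            states = lib$states,
                            noise_sd = noise_sd, seed = as.integer(seed)),
                       class = "synthetic_truth")
    list(prediction = pred, truth = truth)
  })
}

#' Generate a ligand panel with planted predominant states
#'
#' A synthetic analog of a kinase inhibitor panel: each ligand gets true
#' weights that put `dominance` on its planted dominant state with the
#' remainder split evenly over the other states, and a noisy predicted
#' matrix via [generate_predicted_matrix()]. The default panel shape is 12
#' ligands in groups of 6/2/4 dominant on the first/second/third state.
#'
#' @param lib a [state_library()] (3 states for the default panel shape).
#' @param dominant_states character vector of planted states, one per
#'   ligand; default 6/2/4 over the library's three states.
#' @param dominance weight placed on the planted state; must exceed
#'   1/n_states.
#' @param noise_sd prediction noise sd (Angstrom).
#' @param seed integer seed.
#' @return list with `panel` (named list of predictions) and `truth`
#'   (`synthetic_truth` with per-ligand planted states and weight matrix).
#' @export
generate_ligand_panel <- function(lib, dominant_states = NULL, dominance = 0.7,
                                  noise_sd = 0.2, seed = 42L) {
  stopifnot(inherits(lib, "state_library"))
  K <- length(lib$states)
  if (is.null(dominant_states)) {
    if (K != 3L) stop("default panel shape needs a 3-state library")
    dominant_states <- rep(lib$states, times = c(6L, 2L, 4L))
  }
  if (!all(dominant_states %in% lib$states)) {
    stop("unknown dominant state(s): ",
         paste(setdiff(dominant_states, lib$states), collapse = ", "))
  }
  if (dominance <= 1 / K || dominance > 1) {
    stop("dominance must lie in (1/n_states, 1]")
  }
  n_lig <- length(dominant_states)
  ligand_ids <- sprintf("L%02d", seq_len(n_lig))
  W <- matrix((1 - dominance) / (K - 1), n_lig, K,
              dimnames = list(ligand_ids, lib$states))
  for (l in seq_len(n_lig)) W[l, dominant_states[l]] <- dominance
  panel <- vector("list", n_lig)
  for (l in seq_len(n_lig)) {
    panel[[l]] <- generate_predicted_matrix(lib, W[l, ], noise_sd,
                                            seed = derive_seed(seed, ligand_ids[l]))$prediction
  }
  names(panel) <- ligand_ids
  truth <- structure(list(kind = "ligand_panel",
                          ligands = ligand_ids,
                          states = lib$states,
                          dominant_states = stats::setNames(dominant_states, ligand_ids),
                          true_weights = W,
                          dominance = dominance, noise_sd = noise_sd,
                          seed = as.integer(seed)),
                     class = "synthetic_truth")
  list(panel = panel, truth = truth)
}

#' Generate a screening library with planted passers
#'
#' Emulates a multi-model virtual screen: planted passers receive strong
#' predicted affinity in every model and short distances (2-3 Angstrom) to
#' all functional residues; decoys receive weak-to-middling affinities, a
#' fraction of them "single-model stars" (strong in exactly one model, to
#' exercise the conservative min-aggregate), and every decoy is placed far
#' (14-15 Angstrom) from at least one functional residue so the distance
#' clause rejects it under library-relative normalization. Also emits a
#' mixed-measure activity table (Kd/Ki/IC50) for the harmonization path.
#'
#' @param n_compounds library size.
#' @param n_models number of prediction models (base + fine-tuned ensemble).
#' @param n_passers planted passers (must not exceed `n_compounds`).
#' @param residues functional residue labels.
#' @param star_frac fraction of decoys made single-model stars.
#' @param seed integer seed.
#' @return list with `affinity` (compounds x models matrix, pKd-like scale),
#'   `residue_distances` (compounds x residues, Angstrom), `activity`
#'   ([harmonize_activity()] input columns `compound`, `measure`, `value`),
#'   `truth` (`synthetic_truth` with the planted passer ids).
#' @export
generate_screening_library <- function(n_compounds = 200L, n_models = 11L,
                                       n_passers = 12L,
                                       residues = c("A:745", "A:762", "A:855"),
                                       star_frac = 0.1, seed = 1L) {
  stopifnot(n_compounds >= 1L, n_models >= 1L)
  if (n_passers > n_compounds) stop("more planted passers than compounds")
  .with_seed(derive_seed(seed, "screening_library"), {
    ids <- sprintf("C%04d", seq_len(n_compounds))
    passers <- if (n_passers > 0L) sample(ids, n_passers) else character(0)
    is_p <- ids %in% passers
    aff <- matrix(stats::runif(n_compounds * n_models, 4, 7),
                  n_compounds, n_models,
                  dimnames = list(ids, c("base", paste0("FT", seq_len(max(0L, n_models - 1L))))[seq_len(n_models)]))
    aff[is_p, ] <- stats::runif(sum(is_p) * n_models, 8.5, 9.5)
    decoys <- which(!is_p)
    stars <- decoys[stats::runif(length(decoys)) < star_frac]
    for (d in stars) aff[d, sample.int(n_models, 1L)] <- stats::runif(1L, 8.5, 9.5)
    dist <- matrix(stats::runif(n_compounds * length(residues), 10, 12),
                   n_compounds, length(residues),
                   dimnames = list(ids, residues))
    for (d in decoys) {
      far <- sample.int(length(residues), 1L)
      dist[d, far] <- stats::runif(1L, 14, 15)
    }
    if (any(is_p)) {
      dist[is_p, ] <- stats::runif(sum(is_p) * length(residues), 2, 3)
    }
    activity <- data.frame(compound = ids,
                           measure = sample(c("Kd", "Ki", "IC50"), n_compounds,
                                            replace = TRUE),
                           value = 10^-stats::runif(n_compounds, 5, 9),
                           stringsAsFactors = FALSE)
    truth <- structure(list(kind = "screening_library",
                            planted_passers = sort(passers),
                            single_model_stars = ids[stars],
                            seed = as.integer(seed)),
                       class = "synthetic_truth")
    list(affinity = aff, residue_distances = dist, activity = activity,
         truth = truth)
  })
}

#' Write a state ensemble as a minimal multi-model PDB fixture
#'
#' One MODEL/ENDMDL block per conformer. Non-glycine residues are written
#' with a dummy CA and a CB at the representative coordinate; glycine with a
#' CA at the representative coordinate, so parsing the file with
#' [parse_multimodel_structure()] round-trips the coordinates.
#'
#' @param e a [state_ensemble()].
#' @param path output file.
#' @export
write_multimodel_pdb <- function(e, path) {
  stopifnot(inherits(e, "state_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  ids <- e$residue_ids
  for (m in seq_len(e$n_conf)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 0L
    co <- e$conformers[[m]]$coords
    for (r in seq_len(nrow(ids))) {
      gly <- ids$resname[r] == "GLY"
      if (!gly) {
        serial <- serial + 1L
        writeLines(sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                           serial, "CA", ids$resname[r], ids$chain[r], ids$resno[r],
                           co[r, 1] + 0.5, co[r, 2], co[r, 3], 1, 0, "C"), con)
      }
      serial <- serial + 1L
      writeLines(sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                         serial, if (gly) "CA" else "CB",
                         ids$resname[r], ids$chain[r], ids$resno[r],
                         co[r, 1], co[r, 2], co[r, 3], 1, 0, "C"), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Serialize / restore a synthetic-truth record
#'
#' Truth is written as JSON alongside every generated dataset so recovery
#' tests can compare against it; write then read round-trips.
#'
#' @param truth a `synthetic_truth`.
#' @param path JSON file.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(x$kind, "ligand_panel")) {
    # JSON arrays carry no names; restore them from the id fields
    names(x$dominant_states) <- x$ligands
    x$true_weights <- matrix(unlist(x$true_weights), nrow = length(x$ligands),
                             dimnames = list(x$ligands, x$states))
  }
  structure(x, class = "synthetic_truth")
}
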