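#' Simplex weights over conformational states
#'
#' @param w numeric weights, one per state; must lie in \[0, 1\] and sum to 1
#'   within 1e-6.
#' @param states state labels, same length and order as `w`.
#' @return an object of class `state_weights` (a named numeric vector).
#' @export
state_weights <- function(w, states = names(w)) {
  states <- states  # force before stripping names
  w <- as.numeric(w)
  if (is.null(states) || length(states) != length(w)) {
    stop("states must name every weight")
  }
  if (any(w < -1e-9) || any(w > 1 + 1e-9)) stop("weights must lie in [0, 1]")
  if (abs(sum(w) - 1) > 1e-6) stop("weights must sum to 1 (got ", sum(w), ")")
  names(w) <- states
  structure(w, class = "state_weights")
}

#' Ensemble-average distance matrix under given state weights
#'
#' The distance matrix of a conformational ensemble represented by simplex
#' weights over the library states: the elementwise convex combination of
#' the per-state average matrices.
#'
#' @param w a [state_weights()] whose states match the library.
#' @param lib a [state_library()].
#' @return a [distance_matrix()].
#' @export
ensemble_distance <- function(w, lib) {
  stopifnot(inherits(lib, "state_library"))
  if (!identical(names(w), lib$states)) {
    stop("weight states (", paste(names(w), collapse = ","),
         ") do not match library states (", paste(lib$states, collapse = ","), ")")
  }
  acc <- 0
  for (s in lib$states) acc <- acc + w[[s]] * lib$matrices[[s]]$values
  distance_matrix(acc, lib$residue_ids)
}

# Internal: align a prediction with a library on the intersection of residue
# labels and build the quadratic form of the mean-squared-error objective
#   MSE(w) = w' G w - 2 b' w + c
# over all ordered unmasked residue pairs (diagonal included; it is
# identically zero on both sides so it only enters the normalizer).
.reweight_problem <- function(p, lib) {
  stopifnot(inherits(lib, "state_library"))
  if (length(lib$states) < 2L) stop("need at least 2 states")
  plab <- p$residue_ids$label
  llab <- lib$residue_ids$label
  shared <- intersect(llab, plab)
  coverage <- length(shared) / max(length(llab), length(plab))
  if (coverage < 0.5) {
    stop(sprintf("residue coverage %.2f below 0.5; refusing to reweight", coverage))
  }
  pi <- match(shared, plab)
  li <- match(shared, llab)
  dhat <- p$values[pi, pi, drop = FALSE]
  keep <- p$mask[pi, pi, drop = FALSE]
  if (!any(keep)) stop("all prediction pairs are masked")
  A <- vapply(lib$states, function(s) {
    lib$matrices[[s]]$values[li, li, drop = FALSE][keep]
  }, numeric(sum(keep)))
  y <- dhat[keep]
  M <- length(y)
  list(G = crossprod(A) / M, b = drop(crossprod(A, y)) / M, c = mean(y^2),
       n_pairs = M, coverage = coverage, states = lib$states)
}

.mse_at <- function(prob, w) {
  max(0, drop(t(w) %*% prob$G %*% w - 2 * sum(prob$b * w) + prob$c))
}

#' Estimate conformational-state populations from a predicted distance matrix
#'
#' Fits simplex weights `w` over the library states so that the weighted
#' average of the state distance matrices is as close as possible, in mean
#' squared error over residue pairs, to the predicted matrix:
#' \deqn{\min_w \frac{1}{M}\sum_{(i,j)} (\bar d_{ij}(w) - \hat d_{ij})^2
#'   \quad \mathrm{s.t.}\ 0 \le w_s \le 1,\ \sum_s w_s = 1}
#' The optimized weights are interpreted as the conformational population of
#' each state. The objective is a convex quadratic, so the program is solved
#' exactly by enumerating Karush-Kuhn-Tucker systems over the possible
#' active sets (subsets of states allowed nonzero weight); with a handful of
#' states this is cheap, globally optimal, and recovers vertex solutions
#' exactly. Bounds are implemented closed (`[0, 1]`) so that pure-state
#' solutions are representable; boundary optima are reported as valid.
#'
#' When prediction and library residue indices differ, the intersection is
#' used and the coverage fraction reported; below 50% coverage the fit is
#' refused. Masked prediction pairs are excluded from the objective and the
#' normalizer is the number of pairs actually summed.
#'
#' @param p a prediction: [distance_matrix()] or predicted matrix from
#'   [generate_predicted_matrix()].
#' @param lib a [state_library()] with at least two states.
#' @return an object of class `reweight_result`: `weights`
#'   ([state_weights()]), `mse` (objective value at the optimum, squared
#'   Angstrom), `n_pairs`, `coverage`, `converged`, `restarts_used` (number
#'   of KKT subproblems solved).
#' @export
reweight_populations <- function(p, lib) {
  prob <- .reweight_problem(p, lib)
  K <- length(prob$states)
  best <- NULL
  best_any <- NULL
  n_solved <- 0L
  for (bits in seq_len(2^K - 1L)) {
    S <- which(bitwAnd(bits, 2^(seq_len(K) - 1L)) > 0L)
    k <- length(S)
    # equality-constrained stationary point on support S
    KKT <- rbind(cbind(2 * prob$G[S, S, drop = FALSE], rep(1, k)),
                 c(rep(1, k), 0))
    sol <- tryCatch(solve(KKT, c(2 * prob$b[S], 1)), error = function(e) NULL)
    if (is.null(sol)) next
    n_solved <- n_solved + 1L
    wS <- sol[seq_len(k)]
    lam <- sol[k + 1L]
    if (any(wS < -1e-9)) next
    w <- numeric(K)
    w[S] <- pmin(pmax(wS, 0), 1)
    w <- w / sum(w)
    obj <- .mse_at(prob, w)
    cand <- list(w = w, obj = obj)
    if (is.null(best_any) || obj < best_any$obj) best_any <- cand
    # KKT multipliers for states held at zero must be nonnegative
    if (k < K) {
      mu <- 2 * (drop(prob$G %*% w) - prob$b) + lam
      if (any(mu[-S] < -1e-7 * max(1, abs(lam)))) next
    }
    if (is.null(best) || obj < best$obj) best <- cand
  }
  converged <- !is.null(best)
  if (is.null(best)) {
    if (is.null(best_any)) stop("reweighting failed: no KKT system was solvable")
    warning("no KKT-verified optimum found; returning best feasible iterate")
    best <- best_any
  }
  structure(list(weights = state_weights(best$w, prob$states),
                 mse = best$obj,
                 n_pairs = prob$n_pairs,
                 coverage = prob$coverage,
                 converged = converged,
                 restarts_used = n_solved),
            class = "reweight_result")
}

#' @export
print.reweight_result <- function(x, ...) {
  cat("reweight_result: w = (",
      paste(sprintf("%s=%.3f", names(x$weights), x$weights), collapse = ", "),
      "), mse =", format(x$mse, digits = 4),
      "A^2 over", x$n_pairs, "pairs\n")
  invisible(x)
}

# all length-K nonnegative integer vectors summing to m (compositions)
.compositions <- function(K, m) {
  if (K == 1L) return(matrix(m, 1L, 1L))
  out <- NULL
  for (k in 0:m) {
    sub <- .compositions(K - 1L, m - k)
    out <- rbind(out, cbind(k, sub))
  }
  unname(out)
}

#' Brute-force simplex grid search (verification oracle)
#'
#' Exhaustively evaluates the reweighting objective on the lattice
#' `{w : w_s = k_s * step, sum(w) = 1}` and returns the minimizing lattice
#' point. Exists to cross-check [reweight_populations()]; deterministic.
#'
#' @inheritParams reweight_populations
#' @param step lattice spacing in (0, 0.5]; 1/step is rounded to an integer.
#' @return a `reweight_result` (with `restarts_used` = number of lattice
#'   points evaluated).
#' @export
simplex_grid_search <- function(p, lib, step = 0.05) {
  if (!(step > 0 && step <= 0.5)) stop("step must be in (0, 0.5]")
  if (inherits(lib, "state_library") && length(lib$states) == 1L) {
    # degenerate 1-state case: only one point on the simplex
    return(structure(list(weights = structure(1, names = lib$states,
                                              class = "state_weights"),
                          mse = NA_real_, n_pairs = NA_integer_, coverage = 1,
                          converged = TRUE, restarts_used = 1L),
                     class = "reweight_result"))
  }
  prob <- .reweight_problem(p, lib)
  m <- round(1 / step)
  W <- .compositions(length(prob$states), m) / m
  objs <- apply(W, 1L, function(w) .mse_at(prob, w))
  i <- which.min(objs)
  structure(list(weights = state_weights(W[i, ], prob$states),
                 mse = objs[i],
                 n_pairs = prob$n_pairs,
                 coverage = prob$coverage,
                 converged = TRUE,
                 restarts_used = nrow(W)),
            class = "reweight_result")
}

#' Predominant state of a reweighting result
#'
#' @param r a `reweight_result` or [state_weights()].
#' @return list with `state` (label of the maximum weight), `margin` (gap to
#'   the runner-up) and `ambiguous` (TRUE when the gap is below 1e-6; the
#'   first label in state order is then returned deterministically).
#' @export
predominant_state <- function(r) {
  w <- if (inherits(r, "reweight_result")) r$weights else r
  ord <- order(-as.numeric(w), seq_along(w))
  margin <- if (length(w) > 1L) as.numeric(w[ord[1L]] - w[ord[2L]]) else 1
  list(state = names(w)[ord[1L]], margin = margin, ambiguous = margin < 1e-6)
}

#' Population shift between two weight vectors
#'
#' Per-state signed change holo minus apo (e.g. ligand-bound populations
#' against an apo baseline); the deltas sum to zero by construction.
#'
#' @param holo,apo [state_weights()] with identical state order.
#' @return named numeric vector of per-state deltas.
#' @export
population_shift <- function(holo, apo) {
  if (!identical(names(holo), names(apo))) stop("state order mismatch between holo and apo")
  stats::setNames(as.numeric(holo) - as.numeric(apo), names(holo))
}
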