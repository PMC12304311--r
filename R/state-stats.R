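#' Per-residue-pair one-way ANOVA map across conformational states
#'
#' For every residue pair (i < j), the per-conformer distances of each state
#' form one group; a one-way ANOVA across states yields an F statistic and an
#' unadjusted two-sided p value. High-F pairs are the pairs whose distance
#' distributions best discriminate the states. The conformers of each state
#' are treated as independent samples and no adjustment is made for multiple
#' comparisons, so the p values are descriptive.
#'
#' Pairs with zero total variance get F = 0, p = 1 and are flagged
#' degenerate. Pairs with between-group variance but zero within-group
#' variance get F = Inf, p = 0.
#'
#' @param ensembles list of at least two [state_ensemble()] objects sharing
#'   one residue index, each with at least 2 conformers.
#' @return an object of class `f_map`: `residue_ids`, `f_values` and
#'   `p_values` (symmetric matrices, diagonal NA), `degenerate` (logical
#'   matrix), `group_sizes`, `df` (numerator/denominator degrees of freedom).
#' @export
anova_f_map <- function(ensembles) {
  if (length(ensembles) < 2L) stop("need at least 2 state ensembles")
  ref <- ensembles[[1L]]$residue_ids$label
  for (e in ensembles) {
    if (!identical(e$residue_ids$label, ref)) stop("residue index mismatch between ensembles")
    if (e$n_conf < 2L) stop("every ensemble needs n_conf >= 2 for ANOVA")
  }
  n_res <- length(ref)
  ut <- which(upper.tri(matrix(0, n_res, n_res)))
  # per state: n_conf x P matrix of pair distances
  per_state <- lapply(ensembles, function(e) {
    X <- vapply(e$conformers, function(cf) {
      as.matrix(stats::dist(cf$coords))[ut]
    }, numeric(length(ut)))
    t(matrix(X, nrow = length(ut)))  # n_conf x P even when P = 1
  })
  ns <- vapply(per_state, nrow, 0L)
  N <- sum(ns)
  k <- length(per_state)
  gmeans <- lapply(per_state, colMeans)
  grand <- Reduce(`+`, Map(`*`, gmeans, ns)) / N
  ssb <- Reduce(`+`, Map(function(m, n) n * (m - grand)^2, gmeans, ns))
  ssw <- Reduce(`+`, Map(function(X, m) {
    colSums((X - matrix(m, nrow(X), ncol(X), byrow = TRUE))^2)
  }, per_state, gmeans))
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  eps <- 1e-12
  degen <- (ssb + ssw) < eps
  f <- ifelse(degen, 0, ifelse(msw < eps, Inf, msb / msw))
  p <- ifelse(degen, 1, stats::pf(f, k - 1, N - k, lower.tail = FALSE))

  fill <- function(v, default) {
    m <- matrix(default, n_res, n_res, dimnames = list(ref, ref))
    m[ut] <- v
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- if (is.logical(default)) FALSE else NA
    m
  }
  structure(list(residue_ids = ensembles[[1L]]$residue_ids,
                 f_values = fill(f, NA_real_),
                 p_values = fill(p, NA_real_),
                 degenerate = fill(degen, FALSE),
                 group_sizes = stats::setNames(ns, vapply(ensembles, `[[`, "", "state_label")),
                 df = c(k - 1, N - k)),
            class = "f_map")
}

#' Top discriminative residue pairs of an F map
#'
#' The k residue pairs with the largest F statistics, i.e. the pairs most
#' effective at distinguishing the states. Degenerate (zero-variance) pairs
#' are not ranked. Ties are broken by (i, j) lexicographic order, and each
#' unordered pair appears once.
#'
#' @param f an `f_map` from [anova_f_map()].
#' @param k how many pairs to return.
#' @return data.frame with columns `i`, `j` (residue labels), `row`, `col`
#'   (positional indices, row < col), `f`, `p`, F-descending.
#' @export
top_discriminative_pairs <- function(f, k) {
  stopifnot(inherits(f, "f_map"), k >= 1)
  n <- nrow(f$f_values)
  ut <- upper.tri(f$f_values)
  ok <- ut & !f$degenerate & !is.na(f$f_values)
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    warning("no defined (non-degenerate) pairs in the F map")
    return(data.frame(i = character(0), j = character(0), row = integer(0),
                      col = integer(0), f = numeric(0), p = numeric(0)))
  }
  fv <- f$f_values[ok]
  pv <- f$p_values[ok]
  ord <- order(-fv, idx[, 1L], idx[, 2L])
  if (k > length(ord)) {
    warning("k = ", k, " exceeds the ", length(ord), " defined pairs; returning all")
    k <- length(ord)
  }
  sel <- ord[seq_len(k)]
  labs <- rownames(f$f_values)
  data.frame(i = labs[idx[sel, 1L]], j = labs[idx[sel, 2L]],
             row = idx[sel, 1L], col = idx[sel, 2L],
             f = fv[sel], p = pv[sel], row.names = NULL)
}

#' Binned distance distribution
#'
#' Bins distance samples on a fixed grid of width `width` starting at `lo`;
#' the last bin may be short when the range is not a multiple of the width.
#' Samples are clamped to `[lo, hi]` before binning. Bins are half-open
#' `[edge_k, edge_{k+1})` with the last bin closed, so edge samples bin
#' reproducibly. Given an already-binned distribution, the mass is resampled
#' onto the requested grid by interval overlap (mass-conserving), so
#' distributions tabulated on different native grids are comparable.
#'
#' @param samples numeric distance samples (Angstrom), or a
#'   `distance_distribution` to rebin.
#' @param lo,hi range (Angstrom).
#' @param width bin width (Angstrom); the conventional prediction grid uses
#'   0.19 over \[1, 20\].
#' @return an object of class `distance_distribution`: `bin_edges`
#'   (ascending, length nbins+1), `probs` (sum 1), `kind` ("binned").
#' @export
binned_distribution <- function(samples, lo = 1, hi = 20, width = 0.19) {
  if (!(lo < hi) || !(width > 0)) stop("need lo < hi and width > 0")
  n_full <- floor((hi - lo) / width + 1e-9)
  edges <- lo + width * (0:n_full)
  if (hi - edges[length(edges)] > 1e-9 * width) edges <- c(edges, hi)  # short final bin
  else edges[length(edges)] <- hi
  nb <- length(edges) - 1L
  if (inherits(samples, "distance_distribution")) {
    probs <- .rebin_overlap(samples$bin_edges, samples$probs, edges)
  } else {
    samples <- as.numeric(samples)
    if (length(samples) == 0L) stop("no samples to bin")
    if (any(!is.finite(samples))) stop("non-finite distance samples")
    x <- pmin(pmax(samples, lo), hi)
    b <- findInterval(x, edges, rightmost.closed = TRUE, left.open = FALSE)
    b[b > nb] <- nb
    probs <- tabulate(b, nbins = nb) / length(x)
  }
  structure(list(bin_edges = edges, probs = probs, kind = "binned"),
            class = "distance_distribution")
}

# mass-conserving overlap resampling between bin grids; mass outside the
# target range is clamped into the edge bins (mirroring clamp-then-bin)
.rebin_overlap <- function(from_edges, from_probs, to_edges) {
  nt <- length(to_edges) - 1L
  out <- numeric(nt)
  for (i in seq_along(from_probs)) {
    a <- from_edges[i]; b <- from_edges[i + 1L]
    if (b <= a || from_probs[i] == 0) next
    dens <- from_probs[i] / (b - a)
    out[1L] <- out[1L] + dens * max(0, min(b, to_edges[1L]) - a)
    out[nt] <- out[nt] + dens * max(0, b - max(a, to_edges[nt + 1L]))
    for (j in seq_len(nt)) {
      lo <- max(a, to_edges[j]); hi <- min(b, to_edges[j + 1L])
      if (hi > lo) out[j] <- out[j] + dens * (hi - lo)
    }
  }
  out / sum(out)
}

#' Mean and standard deviation of a binned distribution
#'
#' Moments over bin centers weighted by bin mass (population sd).
#'
#' @param d a `distance_distribution`.
#' @return named numeric vector `c(mean =, sd =)` in Angstrom.
#' @export
distribution_moments <- function(d) {
  stopifnot(inherits(d, "distance_distribution"))
  centers <- (d$bin_edges[-1] + d$bin_edges[-length(d$bin_edges)]) / 2
  m <- sum(d$probs * centers)
  v <- sum(d$probs * (centers - m)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

#' Gaussian kernel density estimate on a grid
#'
#' Scott's-rule bandwidth (as implemented by [stats::bw.nrd()]); the curve
#' integrates to ~1 over a grid wide enough to cover the data plus three
#' bandwidths. Used to display measured per-state distance distributions.
#'
#' @param samples at least two distance samples (Angstrom).
#' @param grid evaluation points (Angstrom); by default 512 points spanning
#'   the data range plus/minus three bandwidths.
#' @return data.frame with columns `x` (grid) and `density`.
#' @export
kde_curve <- function(samples, grid = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("need at least 2 samples for a KDE")
  h <- stats::bw.nrd(samples)
  if (!is.finite(h) || h <= 0) h <- max(1e-3, stats::sd(samples))
  if (is.null(grid)) {
    grid <- seq(min(samples) - 3 * h, max(samples) + 3 * h, length.out = 512L)
  }
  dens <- vapply(grid, function(g) mean(stats::dnorm((g - samples) / h)) / h,
                 numeric(1))
  data.frame(x = grid, density = dens)
}

#' Summarize a predicted indicator-pair distance against a state library
#'
#' For a conformational indicator pair (e.g. an alphaC-helix in/out distance),
#' reports the predicted mean and sd and the library state whose average
#' distance at that pair is nearest the predicted mean. Equidistant states
#' are flagged as a tie (first state in library order returned).
#'
#' @param p a [distance_matrix()] prediction or a `distance_distribution`
#'   for the pair.
#' @param lib a [state_library()].
#' @param i,j residue labels ("chain:resnum").
#' @return list with `mean`, `sd`, `nearest_state`, `tie`,
#'   `state_values` (the per-state library distances at the pair).
#' @export
indicator_pair_summary <- function(p, lib, i, j) {
  stopifnot(inherits(lib, "state_library"))
  labs <- lib$residue_ids$label
  if (!(i %in% labs) || !(j %in% labs)) stop("pair not present in the library index")
  if (inherits(p, "distance_distribution")) {
    mo <- distribution_moments(p)
    m <- mo[["mean"]]; s <- mo[["sd"]]
  } else if (inherits(p, "distance_matrix")) {
    if (!(i %in% p$residue_ids$label) || !(j %in% p$residue_ids$label)) {
      stop("pair not present in the prediction index")
    }
    if (!p$mask[i, j]) stop("pair (", i, ", ", j, ") is masked in the prediction")
    m <- p$values[i, j]; s <- 0
  } else stop("p must be a distance_matrix or distance_distribution")
  sv <- vapply(lib$states, function(st) lib$matrices[[st]]$values[i, j], numeric(1))
  gaps <- abs(sv - m)
  best <- which(gaps == min(gaps))
  list(mean = m, sd = s,
       nearest_state = lib$states[best[1L]],
       tie = length(best) > 1L,
       state_values = sv)
}

#' Write an F map or distribution to disk
#'
#' F maps go to TSV with residue-label headers; distributions to JSON
#' (edges, probs, kind).
#'
#' @param f an `f_map`.
#' @param path output file.
#' @export
write_f_map_tsv <- function(f, path) {
  stopifnot(inherits(f, "f_map"))
  df <- data.frame(residue = rownames(f$f_values), f$f_values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_f_map_tsv
#' @param d a `distance_distribution`.
#' @export
write_distribution_json <- function(d, path) {
  stopifnot(inherits(d, "distance_distribution"))
  jsonlite::write_json(list(bin_edges = d$bin_edges, probs = d$probs,
                            kind = d$kind),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_f_map_tsv
#' @export
read_distribution_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(bin_edges = x$bin_edges, probs = x$probs, kind = x$kind),
            class = "distance_distribution")
}
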