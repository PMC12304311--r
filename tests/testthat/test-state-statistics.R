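test_that("one-way ANOVA map reproduces hand-computed sums of squares", {
  # groups {1,2,3}, {2,3,4}, {3,4,5}: SSB = 6, MSB = 3, SSW = 6, MSW = 1
  ens <- groups_as_ensembles(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  fm <- anova_f_map(ens)
  expect_equal(fm$f_values["A:1", "A:2"], 3.0)
  expect_equal(unname(fm$df), c(2, 6))
  expect_equal(fm$p_values["A:1", "A:2"],
               pf(3, 2, 6, lower.tail = FALSE))
})

test_that("ANOVA map agrees with per-pair aov on a seeded ensemble set", {
  g <- small_library(seed = 13, n_res = 8, n_conf = 5)
  fm <- anova_f_map(g$ensembles)
  for (i in 1:3) for (j in (i + 3):8) {
    vals <- unlist(lapply(g$ensembles, pair_distance_samples, i = i, j = j))
    grp <- factor(rep(seq_along(g$ensembles), each = 5))
    fit <- summary(aov(vals ~ grp))[[1]]
    expect_equal(fm$f_values[i, j], fit[["F value"]][1], tolerance = 1e-10)
    expect_equal(fm$p_values[i, j], fit[["Pr(>F)"]][1], tolerance = 1e-10)
  }
})

test_that("zero-variance pairs are degenerate with F = 0, p = 1", {
  ens <- groups_as_ensembles(list(c(2, 2), c(2, 2), c(2, 2)))
  fm <- anova_f_map(ens)
  expect_equal(fm$f_values["A:1", "A:2"], 0)
  expect_equal(fm$p_values["A:1", "A:2"], 1)
  expect_true(fm$degenerate["A:1", "A:2"])
  expect_warning(tp <- top_discriminative_pairs(fm, 1), "no defined")
  expect_equal(nrow(tp), 0)
})

test_that("F map is label-symmetric under state permutation", {
  g <- small_library(seed = 21, n_res = 12, n_conf = 4)
  f1 <- anova_f_map(g$ensembles)
  f2 <- anova_f_map(g$ensembles[c(3, 1, 2)])
  expect_equal(f1$f_values, f2$f_values)
})

test_that("the planted discriminative block attains the maximum F", {
  g <- small_library(seed = 17, n_res = 50, n_conf = 10)
  fm <- anova_f_map(g$ensembles)
  blk <- g$truth$planted_block[1]:g$truth$planted_block[2]
  top <- top_discriminative_pairs(fm, 1)
  # a rigid block displacement moves block-to-rest pairs, so the max-F pair
  # must have exactly one endpoint inside the planted block
  expect_true(xor(top$row %in% blk, top$col %in% blk))
})

test_that("under the null the p < 0.05 fraction is near 0.05", {
  suppressWarnings({
    g <- generate_state_library(generator_config(seed = 31, n_res = 30,
                                                 n_conf = 10,
                                                 inter_state_displacement = 0))
  })
  fm <- anova_f_map(g$ensembles)
  frac <- mean(fm$p_values[upper.tri(fm$p_values)] < 0.05)
  expect_gt(frac, 0.05 - 0.045)
  expect_lt(frac, 0.05 + 0.045)
})

test_that("top pairs agree with a brute-force sort and break ties lexicographically", {
  g <- small_library(seed = 23, n_res = 15, n_conf = 4)
  fm <- anova_f_map(g$ensembles)
  tp <- top_discriminative_pairs(fm, 10)
  ut <- which(upper.tri(fm$f_values), arr.ind = TRUE)
  fv <- fm$f_values[upper.tri(fm$f_values)]
  ord <- order(-fv, ut[, 1], ut[, 2])[1:10]
  expect_equal(tp$row, ut[ord, 1])
  expect_equal(tp$col, ut[ord, 2])
  expect_equal(tp$f, fv[ord])
  expect_true(all(diff(tp$f) <= 0))
  expect_warning(all_p <- top_discriminative_pairs(fm, 1e6), "exceeds")
  expect_equal(nrow(all_p), sum(upper.tri(fm$f_values)))
})

test_that("binning follows the fixed-width half-open convention", {
  d <- binned_distribution(rep(5, 10), lo = 1, hi = 20, width = 0.19)
  expect_equal(length(d$bin_edges) - 1L, 100L)  # ceil(19 / 0.19)
  expect_equal(sum(d$probs), 1, tolerance = 1e-9)
  expect_equal(sum(d$probs > 0), 1L)  # point mass in a single bin
  # clamping precedes binning
  d2 <- binned_distribution(c(0.2, 25), lo = 1, hi = 20, width = 0.19)
  expect_equal(d2$probs[1], 0.5)
  expect_equal(d2$probs[100], 0.5)
  expect_error(binned_distribution(numeric(0)), "no samples")
  # uniform samples at large n put every bin near 1/100
  set.seed(4)
  du <- binned_distribution(runif(20000, 1, 20), 1, 20, 0.19)
  expect_lt(max(abs(du$probs - 0.01)), 0.004)
})

test_that("rebinning between native grids conserves mass and moments", {
  set.seed(8)
  x <- rnorm(5000, mean = 10, sd = 1.5)
  native <- binned_distribution(x, lo = 1, hi = 20, width = 0.3)  # apo-style grid
  reb <- binned_distribution(native, lo = 1, hi = 20, width = 0.19)
  expect_equal(sum(reb$probs), 1, tolerance = 1e-9)
  m1 <- distribution_moments(native)
  m2 <- distribution_moments(reb)
  expect_equal(m1[["mean"]], m2[["mean"]], tolerance = 0.02)
  expect_equal(m1[["sd"]], m2[["sd"]], tolerance = 0.05)
})

test_that("distribution moments match direct summation", {
  # two equal-mass bins centered at 4 and 6
  d <- binned_distribution(c(4, 6), lo = 3.5, hi = 6.5, width = 1)
  m <- distribution_moments(d)
  expect_equal(m[["mean"]], 5)
  expect_equal(m[["sd"]], 1)
  # single bin has sd 0
  d1 <- binned_distribution(rep(2, 5), lo = 1.5, hi = 2.5, width = 1)
  expect_equal(distribution_moments(d1)[["sd"]], 0)
  # random distribution against an independent weighted-moment computation
  set.seed(5)
  dr <- binned_distribution(runif(200, 2, 18), 1, 20, 0.19)
  cent <- (dr$bin_edges[-1] + dr$bin_edges[-length(dr$bin_edges)]) / 2
  mu <- sum(dr$probs * cent)
  sg <- sqrt(sum(dr$probs * cent^2) - mu^2)
  mm <- distribution_moments(dr)
  expect_equal(mm[["mean"]], mu)
  expect_equal(mm[["sd"]], sg, tolerance = 1e-12)
  # splitting bins in half leaves the mean unchanged (sd gains at most the
  # within-half-bin term)
  half <- binned_distribution(dr, 1, 20, 0.19 / 2)
  expect_equal(distribution_moments(half)[["mean"]], mm[["mean"]], tolerance = 1e-9)
  expect_lt(abs(distribution_moments(half)[["sd"]] - mm[["sd"]]), 0.19 / 4)
})

test_that("KDE is normalized, symmetric and resolves well-separated modes", {
  set.seed(6)
  x <- c(rnorm(500, 5, 0.3))
  k <- kde_curve(x)
  expect_true(all(k$density >= 0))
  expect_lt(abs(k$x[which.max(k$density)] - 5), 0.15)
  integral <- sum(k$density) * diff(k$x[1:2])
  expect_gt(integral, 0.99); expect_lt(integral, 1.01)
  bimodal <- kde_curve(c(rnorm(400, 4, 0.2), rnorm(400, 12, 0.2)),
                       grid = seq(2, 14, length.out = 600))
  dens <- bimodal$density
  peaks <- which(diff(sign(diff(dens))) == -2) + 1L
  peaks <- peaks[dens[peaks] > 0.1 * max(dens)]
  expect_equal(length(peaks), 2L)
  expect_error(kde_curve(3.2), "at least 2")
})

test_that("indicator-pair summary names the nearest library state", {
  g <- small_library(seed = 19, n_res = 40, n_conf = 8)
  lib <- g$library
  top <- top_discriminative_pairs(anova_f_map(g$ensembles), 1)
  i <- top$i; j <- top$j
  # a prediction equal to state A's value maps to state A
  pA <- lib$matrices[[1]]
  s <- indicator_pair_summary(pA, lib, i, j)
  expect_equal(s$nearest_state, lib$states[1])
  expect_false(s$tie)
  expect_equal(s$sd, 0)
  # dominant-state mixture maps to the dominant state at the planted pair
  pm <- ensemble_distance(state_weights(c(0.15, 0.7, 0.15), lib$states), lib)
  s2 <- indicator_pair_summary(pm, lib, i, j)
  expect_equal(s2$nearest_state, lib$states[2])
  # equidistant prediction is flagged as a tie: midpoint of the two states
  # with the smallest gap at this pair (the third state is strictly farther)
  sv <- sort(s$state_values)
  gaps <- diff(sv)
  pick <- which.min(gaps)
  fake <- pA
  fake$values[i, j] <- fake$values[j, i] <- mean(sv[pick + 0:1])
  s3 <- indicator_pair_summary(fake, lib, i, j)
  expect_true(s3$tie)
  # masked pair is an error
  msk <- pA
  msk$mask[i, j] <- msk$mask[j, i] <- FALSE
  expect_error(indicator_pair_summary(msk, lib, i, j), "masked")
})

test_that("distributions serialize to JSON and back", {
  d <- binned_distribution(c(3, 3.5, 7, 12), 1, 20, 0.19)
  f <- tempfile(fileext = ".json")
  write_distribution_json(d, f)
  d2 <- read_distribution_json(f)
  expect_equal(d2$probs, d$probs)
  expect_equal(d2$bin_edges, d$bin_edges)
  expect_equal(d2$kind, d$kind)
})
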