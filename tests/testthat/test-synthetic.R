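test_that("zero jitter collapses every conformer onto the state mean", {
  g <- generate_state_library(generator_config(seed = 2, n_res = 20, n_conf = 5,
                                               intra_state_jitter = 0))
  e <- g$ensembles[[2]]
  for (k in 2:e$n_conf) {
    expect_identical(e$conformers[[k]]$coords, e$conformers[[1]]$coords)
  }
  expect_equal(average_distance_matrix(e)$values,
               conformer_distance_matrix(e$conformers[[1]])$values)
})

test_that("generation is a pure function of the config seed", {
  cfg <- generator_config(seed = 33, n_res = 25, n_conf = 4)
  g1 <- generate_state_library(cfg)
  g2 <- generate_state_library(cfg)
  expect_identical(g1$library$matrices[[3]]$values, g2$library$matrices[[3]]$values)
  expect_identical(g1$truth$planted_block, g2$truth$planted_block)
  # generation restores the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(generate_state_library(cfg)); b <- runif(1)
  expect_identical(a, b)
  s1 <- generate_screening_library(n_compounds = 20, n_passers = 2, seed = 5)
  s2 <- generate_screening_library(n_compounds = 20, n_passers = 2, seed = 5)
  expect_identical(s1$affinity, s2$affinity)
  expect_error(generator_config(n_res = 10), "seed is mandatory")
  expect_warning(generate_state_library(
    generator_config(seed = 1, n_res = 10, n_conf = 2,
                     inter_state_displacement = 0)), "indistinguishable")
})

test_that("generated conformer matrices satisfy the ensemble invariants", {
  g <- generate_state_library(generator_config(seed = 44, n_res = 30, n_conf = 3))
  for (e in g$ensembles) {
    d <- conformer_distance_matrix(e$conformers[[1]])$values
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    set.seed(7)
    for (t in 1:100) {
      ijk <- sample.int(30, 3)
      expect_lte(d[ijk[1], ijk[2]],
                 d[ijk[1], ijk[3]] + d[ijk[3], ijk[2]] + 1e-9)
    }
    # self-avoidance keeps non-adjacent residues apart
    expect_gt(min(d[upper.tri(d)]), 1.5)
  }
})

test_that("predicted matrices mix the library states with recorded truth", {
  g <- small_library(seed = 50, n_res = 40, n_conf = 6)
  lib <- g$library
  # zero noise at a vertex reproduces the state matrix on unmasked pairs
  v <- generate_predicted_matrix(lib, c(1, 0, 0), noise_sd = 0, seed = 1)
  ok <- v$prediction$mask
  expect_equal(v$prediction$values[ok & upper.tri(ok)],
               lib$matrices[[1]]$values[ok & upper.tri(ok)])
  expect_equal(v$truth$true_weights, c(1, 0, 0))
  # zero noise at any w is recovered through the reweighting machinery
  p <- generate_predicted_matrix(lib, c(0.2, 0.5, 0.3), noise_sd = 0, seed = 2)
  r <- reweight_populations(p$prediction, lib)
  expect_lt(max(abs(as.numeric(r$weights) - c(0.2, 0.5, 0.3))), 1e-3)
  # noisy matrices are symmetric with all values inside the truncation range
  pn <- generate_predicted_matrix(lib, c(0.2, 0.5, 0.3), noise_sd = 0.5, seed = 3)
  expect_equal(pn$prediction$values, t(pn$prediction$values))
  off <- pn$prediction$values[upper.tri(pn$prediction$values)]
  expect_true(all(off >= 1 & off <= 20))
  # saturated pairs are masked
  expect_true(all(pn$prediction$values[!pn$prediction$mask] %in% c(1, 20)))
  expect_error(generate_predicted_matrix(lib, c(2, -1, 0), 0, 1), "\\[0, 1\\]")
})

test_that("ligand panels plant dominant states that reweighting recovers", {
  g <- small_library(seed = 60, n_res = 50, n_conf = 8)
  # pure states, zero noise: every ligand recovers its planted state
  pl <- generate_ligand_panel(g$library, dominance = 1, noise_sd = 0, seed = 7)
  expect_length(pl$panel, 12)
  expect_equal(as.integer(table(pl$truth$dominant_states)[g$library$states]),
               c(6L, 2L, 4L))
  for (lg in names(pl$panel)) {
    r <- predominant_state(reweight_populations(pl$panel[[lg]], g$library))
    expect_equal(r$state, unname(pl$truth$dominant_states[lg]))
  }
  # grouped means: ligands planted on s recover more of w_s than other groups
  pl2 <- generate_ligand_panel(g$library, dominance = 0.7, noise_sd = 0.2, seed = 8)
  W <- t(vapply(names(pl2$panel), function(lg) {
    as.numeric(reweight_populations(pl2$panel[[lg]], g$library)$weights)
  }, numeric(3)))
  colnames(W) <- g$library$states
  for (s in g$library$states) {
    own <- W[pl2$truth$dominant_states == s, s]
    other <- W[pl2$truth$dominant_states != s, s]
    expect_gt(mean(own), mean(other))
  }
  expect_error(generate_ligand_panel(g$library, dominance = 0.2), "dominance")
  expect_error(generate_ligand_panel(g$library, dominant_states = c("A", "Q")),
               "unknown dominant")
})

test_that("screening libraries plant passers that survive triage exactly", {
  scr <- generate_screening_library(n_compounds = 120, n_passers = 10, seed = 21)
  cs <- run_screen(scr$affinity, scr$residue_distances, tempfile())
  expect_setequal(cs$selected, scr$truth$planted_passers)
  # no planted passers: the distance clause rejects every decoy, including
  # single-model stars that pass the rank clause
  scr0 <- generate_screening_library(n_compounds = 60, n_passers = 0, seed = 22)
  cs0 <- run_screen(scr0$affinity, scr0$residue_distances, tempfile())
  expect_length(cs0$selected, 0)
  # passers-only library: every compound clears both affinity clauses; the
  # library-relative distance normalization still spreads scores over [0,1]
  scrP <- generate_screening_library(n_compounds = 8, n_passers = 8, seed = 23)
  norm <- normalize_model_scores(scrP$affinity)
  ranks <- model_ranks(scrP$affinity)
  expect_true(all(apply(ranks, 1, min) < 10 |
                    overall_affinity_score(norm)$overall_score > 0.3))
  expect_error(generate_screening_library(n_compounds = 3, n_passers = 5),
               "more planted passers")
  # mixed-measure activity table feeds harmonization
  h <- harmonize_activity(scr$activity$measure, scr$activity$value,
                          scr$activity$compound)
  expect_true(all(h$harmonized_pkd >= h$p_value))
  expect_setequal(unique(h$measure), c("Kd", "Ki", "IC50"))
})

test_that("truth records round-trip through JSON", {
  g <- small_library(seed = 70, n_res = 15, n_conf = 2)
  f <- tempfile(fileext = ".json")
  write_truth(g$truth, f)
  t2 <- read_truth(f)
  expect_equal(t2$planted_block, g$truth$planted_block)
  expect_equal(t2$config$seed, g$truth$config$seed)
  pl <- generate_ligand_panel(g$library, dominance = 0.8, noise_sd = 0, seed = 3)
  f2 <- tempfile(fileext = ".json")
  write_truth(pl$truth, f2)
  t3 <- read_truth(f2)
  expect_equal(unname(unlist(t3$dominant_states)), unname(pl$truth$dominant_states))
  expect_equal(unname(t3$true_weights), unname(pl$truth$true_weights),
               tolerance = 1e-12)
})

test_that("recovery error rises with noise and falls with state separation", {
  err_at <- function(noise, disp) {
    mean(vapply(1:3, function(k) {
      g <- generate_state_library(generator_config(seed = 200 + k, n_res = 40,
                                                   n_conf = 5,
                                                   inter_state_displacement = disp))
      w0 <- c(0.5, 0.3, 0.2)
      p <- generate_predicted_matrix(g$library, w0, noise_sd = noise,
                                     seed = 300 + k)$prediction
      max(abs(as.numeric(reweight_populations(p, g$library)$weights) - w0))
    }, numeric(1)))
  }
  grid <- expand.grid(noise = c(0, 0.3, 0.8), disp = c(4, 8, 12))
  grid$err <- mapply(err_at, grid$noise, grid$disp)
  for (d in unique(grid$disp)) {
    e <- grid$err[grid$disp == d][order(unique(grid$noise))]
    expect_true(all(diff(e) >= -1e-6))
  }
  for (s in unique(grid$noise)) {
    e <- grid$err[grid$noise == s][order(unique(grid$disp))]
    expect_true(all(diff(e) <= 1e-6 + 0.5 * e[-length(e)]))
  }
})
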