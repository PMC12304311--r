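# shared fixtures, all built in code

# two Pythagorean-triple conformers on three residues
tri_fixture <- function() {
  ids <- residue_ids(c("A", "A", "A"), 1:3, c("ALA", "ALA", "ALA"))
  list(ids = ids,
       c345 = conformer(ids, rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0))),
       c51213 = conformer(ids, rbind(c(0, 0, 0), c(5, 0, 0), c(0, 12, 0))))
}

rand_conformer <- function(n = 10, seed = 1, spread = 8) {
  set.seed(seed)
  ids <- residue_ids(rep("A", n), seq_len(n), rep("ALA", n))
  conformer(ids, matrix(rnorm(n * 3, sd = spread), n, 3))
}

small_library <- function(seed = 1, n_res = 40, n_conf = 6, ...) {
  generate_state_library(generator_config(seed = seed, n_res = n_res,
                                          n_conf = n_conf, ...))
}

# ensembles where one residue pair carries prescribed distance groups:
# residue 1 at the origin, residue 2 at (d, 0, 0) per conformer
groups_as_ensembles <- function(groups) {
  ids <- residue_ids(c("A", "A"), 1:2, c("ALA", "ALA"))
  lapply(seq_along(groups), function(s) {
    state_ensemble(paste0("S", s), lapply(groups[[s]], function(d) {
      conformer(ids, rbind(c(0, 0, 0), c(d, 0, 0)))
    }))
  })
}

# minimal hand-written two-model PDB text (ALA has CB, GLY only CA)
pdb_text_two_models <- function() {
  c("MODEL        1",
    "ATOM      1  CA  ALA A   1       0.500   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       3.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1       0.500   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  GLY A   2       5.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "END")
}
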