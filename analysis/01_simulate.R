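#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study inputs with known ground truth:
# a 3-state x 20-conformer state library (150 pseudo-residues, one planted
# block displaced 8 A between states, 0.3 A within-state jitter), a
# 12-ligand panel with planted predominant states (dominance 0.7, 0.2 A
# prediction noise, groups of 6/2/4), and a 200-compound x 11-model
# screening library with 12 planted passers. Fixture PDB files and truth
# records are written under results/simulated/.

suppressMessages(library(statepop))
seed <- 42L
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- generator_config(seed = seed, n_res = 150, n_conf = 20,
                        inter_state_displacement = 8,
                        intra_state_jitter = 0.3, prediction_noise = 0.2)
g <- generate_state_library(cfg)
write_truth(g$truth, file.path(out, "library_truth.json"))
for (s in names(g$ensembles)) {
  write_multimodel_pdb(g$ensembles[[s]], file.path(out, paste0("state_", s, ".pdb")))
}
cat(sprintf("state library: %d states x %d conformers, %d residues; planted block %d-%d\n",
            length(g$library$states), cfg$n_conf, cfg$n_res,
            g$truth$planted_block[1], g$truth$planted_block[2]))

pl <- generate_ligand_panel(g$library, dominance = 0.7, noise_sd = 0.2, seed = seed)
write_truth(pl$truth, file.path(out, "panel_truth.json"))
for (lg in names(pl$panel)) {
  write_distance_tsv(pl$panel[[lg]], file.path(out, paste0("panel_", lg, ".tsv")))
}
cat(sprintf("ligand panel: %d predictions (%s)\n", length(pl$panel),
            paste(sprintf("%s on %s", names(table(pl$truth$dominant_states)),
                          "planted"), collapse = ", ")))

scr <- generate_screening_library(n_compounds = 200, n_models = 11,
                                  n_passers = 12, seed = seed)
write_truth(scr$truth, file.path(out, "screen_truth.json"))
write.table(data.frame(compound = rownames(scr$affinity), scr$affinity,
                       check.names = FALSE),
            file.path(out, "screen_affinity.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(compound = rownames(scr$residue_distances),
                       scr$residue_distances, check.names = FALSE),
            file.path(out, "screen_distances.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.csv(scr$activity, file.path(out, "screen_activity.csv"), row.names = FALSE)
cat(sprintf("screening library: %d compounds x %d models, %d planted passers\n",
            nrow(scr$affinity), ncol(scr$affinity),
            length(scr$truth$planted_passers)))
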