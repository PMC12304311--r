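# statepop

Conformational-state populations from inter-residue distance matrices.

Kinases populate an active state and kinase-specific inactive states
(αC-helix in/out, DFG-in/out, open/closed activation loop). A model that
predicts an inter-residue distance matrix for a protein–ligand complex
implicitly predicts how the bound ensemble distributes over those states.
`statepop` is the downstream analysis toolkit for that idea, for structural
bioinformaticians working with multi-model ensembles and ensemble-aware
virtual screening:

- **State libraries** — parse multi-model PDB ensembles, reduce each model
  to representative atoms (Cβ; Cα for glycine), and average the per-model
  distance matrices into one matrix `d^s_ij` per state.
- **Population reweighting** — estimate simplex weights `w` minimizing

  ```
  MSE(w) = (1/M) Σ_(i,j) ( Σ_s d^s_ij w^s − d̂_ij )²,   0 ≤ w^s ≤ 1,  Σ_s w^s = 1
  ```

  against a predicted matrix `d̂`; the convex quadratic program is solved
  exactly by KKT active-set enumeration, with a brute-force simplex-grid
  oracle, predominant-state calls and population shifts vs an apo baseline.
- **State discrimination** — per-residue-pair one-way ANOVA F maps (no
  multiple-comparison adjustment; descriptive), difference distance
  matrices, binned distance distributions (0.19 Å grid over 1–20 Å) and
  Gaussian KDEs with summary moments.
- **Screening triage** — pKd harmonization (+0.35 log units for IC50),
  distance-label truncation to [1, 20] Å, complex curation (≤ 384 residues,
  ≤ 128 ligand atoms, exactly one ligand), per-model min–max normalization,
  a conservative min-aggregate overall affinity score, functional-residue
  distance scores, and candidate selection
  (`score > 0.3 OR any rank < 10, AND all distance scores < 0.5`).
- **Synthetic data** — geometry-first generators for every input with
  serialized ground truth, so parameter recovery and selection logic are
  fully testable offline.

## Worked example

```r
library(statepop)

g  <- generate_state_library(generator_config(seed = 42, n_res = 150))
pl <- generate_ligand_panel(g$library, dominance = 0.7, noise_sd = 0.2, seed = 42)

r <- reweight_populations(pl$panel$L07, g$library)
r
#> reweight_result: w = ( A=0.152, I1=0.701, I2=0.147 ), mse = 0.01787 A^2 over 4170 pairs
predominant_state(r)$state
#> [1] "I1"
pl$truth$dominant_states[["L07"]]
#> [1] "I1"
```

Ligand L07 was planted with 0.7 of its population on inactive state I1; the
fit recovers weights (0.15, 0.70, 0.15), so the predominant-state call
matches the planted truth. The fit used the 4170 pairs inside the 1–20 Å
prediction range (saturated pairs are masked), and the residual MSE
(~0.018 Å²) is the injected 0.2 Å prediction noise after symmetrization
halves its variance.

The full analysis lives in four scripts, each a thin driver over the
package that prints what it found and writes tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # state library + ligand panel + screening library, with truth
Rscript analysis/02_states.R    # difference matrices, ANOVA F map, top discriminative pairs
Rscript analysis/03_reweight.R  # per-ligand populations, predominant states, apo shifts
Rscript analysis/04_screen.R    # harmonization, scores, ranks, candidate selection
```

On the default simulation, stage 3 recovers 12/12 planted predominant
states and stage 4 selects exactly the 12 planted passers out of 200
compounds.

## Documentation

The methods vignette (`vignettes/state-populations.Rmd`) covers the model
and its assumptions, the exact solver, the binning and normalization
conventions, what the synthetic generator does and does not emulate, and
known limitations.
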