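---
title: "Estimating conformational-state populations from predicted distance matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating conformational-state populations from predicted distance matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statepop)
```

## The problem

Protein kinases interconvert between a conserved active state and one or
more kinase-specific inactive states, distinguished by the positions of the
αC-helix, the DFG motif at the start of the activation loop, and the P-loop.
A ligand that binds preferentially to one state shifts the population of the
ensemble toward it, so a predictor that emits an inter-residue distance
matrix for a protein–ligand complex implicitly encodes a population
estimate. `statepop` turns that implication into numbers: given a library of
per-state reference distance matrices and a predicted matrix for a bound
complex, it estimates the population of each state, quantifies which residue
pairs discriminate the states, and triages multi-model screening predictions
into candidate compounds.

## The reweighting model

Each conformational state $s$ is deposited as an ensemble of $N_\mathrm{conf}$
models. We reduce every model to one representative atom per residue — the
Cβ atom, or Cα for glycine, the convention under which αC-helix indicator
distances are defined — and use the elementwise average of the per-model
distance matrices as the state matrix:

$$ d^s_{ij} \;=\; \frac{1}{N_\mathrm{conf}} \sum_{n=1}^{N_\mathrm{conf}} d^{s(n)}_{ij}. $$

A population vector $\mathbf w = (w^s)$ on the simplex represents the
ensemble by the weighted average $\bar d_{ij}(\mathbf w) = \sum_s d^s_{ij}
w^s$, and the populations compatible with a predicted matrix
$\hat d_{ij}$ are taken as the minimizer of

$$ \mathrm{MSE}(\mathbf w) = \frac{1}{M} \sum_{(i,j)} \big( \bar d_{ij}(\mathbf w) - \hat d_{ij} \big)^2,
\qquad 0 \le w^s \le 1,\; \textstyle\sum_s w^s = 1, $$

where the sum runs over all ordered unmasked residue pairs (the identically
zero diagonal included; it only enters the normalizer $M$, which always
equals the number of pairs actually summed).

**Assumptions.** The bound ensemble is a mixture of the reference states
(no unmodelled fourth state); the predictor's point estimate is an unbiased,
homoscedastic observation of the mixture; and the 20 models of each state
are a fair sample of its basin. Violations show up as a large residual MSE,
which is always reported.

### Solving the program exactly

The objective is a convex quadratic in $\mathbf w$, so rather than running
an iterative SQP solver we solve the Karush–Kuhn–Tucker system exactly on
every candidate active set: for each nonempty subset of states allowed a
nonzero weight we solve the equality-constrained stationary system, keep the
solutions that are feasible and satisfy the sign conditions on the
multipliers of the zeroed states, and return the best. With $K$ states this
is $2^K - 1$ small linear solves — trivial for the 3-state problem, still
immediate for any library one would assemble by hand — and it is globally
optimal with no step-size or restart fragility. In particular pure-state
(vertex) solutions are recovered *exactly*, which is why the bounds are
implemented closed $[0,1]$: an open box has no attained minimum at a vertex.
`restarts_used` reports the number of KKT subproblems solved, and
`simplex_grid_search()` provides an independent brute-force lattice oracle
that the solver must dominate (a property the test suite asserts).

When prediction and library disagree on the residue index, the fit uses the
intersection and reports the coverage fraction, refusing below 50%: a silent
partial overlap would corrupt populations. Masked prediction pairs are
excluded from the objective.

## State discrimination

`anova_f_map()` runs, for every residue pair, a one-way ANOVA of the
per-conformer distances across states, treating the conformers of a state
as independent samples (the deposited models carry no ordering), and
reports unadjusted two-sided p values — deliberately no multiple-testing
correction, since the map is a descriptive screen for discriminative pairs,
not an inferential family. The sums of squares are computed vectorized over
all pairs; `stats::aov` on individual pairs is the oracle in the tests.
Zero-variance pairs are defined to F = 0, p = 1 and flagged degenerate so
the map stays total; pairs with between- but no within-group variance
(exact geometric fixtures) get F = ∞, p = 0.

Distance distributions use a fixed-width binning convention — half-open
bins, last bin closed, clamp to the range before binning — with 0.19 Å the
conventional prediction grid over [1, 20] Å and 0.3 Å a typical apo grid;
`binned_distribution()` resamples an already-binned distribution onto a new
grid by mass-conserving interval overlap so the two are comparable. Moments
are computed over bin centers; splitting bins in half therefore leaves the
mean exactly invariant while the sd can move by at most the within-half-bin
term (width/4). KDE curves use a Gaussian kernel with Scott's-rule
bandwidth (`stats::bw.nrd`) on a 512-point grid spanning the data ± 3
bandwidths; the rule is a display choice, not an inference.

## Screening triage

Activity records are harmonized onto the pKd scale: $p = -\log_{10}$ of the
molar value, with IC50-derived values offset by exactly +0.35 log units (Kd
and Ki are used without distinction). Distance labels are truncated to the
predictor's [1, 20] Å range. Complex curation keeps records with exactly one
parseable ligand, ≤ 128 ligand atoms and ≤ 384 residues, both bounds
inclusive, with one logged reason per drop.

Predicted affinities from the model ensemble are min–max normalized per
model (the simplest scheme on which a bounded threshold like 0.3 is
meaningful; constant columns map to 0.5 with a warning), and the **overall
affinity score** is the per-compound *minimum* across models — a
conservative consensus that a compound only wins when every model agrees,
which is what makes single-model outliers harmless. Ranks are 1-based
competition ranks, so "rank < 10" admits ranks 1–9. Ligand-to-functional-
residue distances are min–max normalized per residue (0 = closest). The
selection rule is: (overall score > 0.3 **or** any model rank < 10) **and**
all distance scores < 0.5. Missing predictions make a compound ineligible
rather than imputed, because a min-aggregate over imputed values silently
inflates scores.

One consequence of library-relative normalization is worth stating plainly:
distance scores are comparative, so in a degenerate library whose compounds
are all equally close to the target region, the farthest of them still maps
to score 1 and fails the distance clause. The scores order a library; they
are not absolute Ångström judgments.

## What the synthetic generator emulates — and what it does not

The generator works geometry-first: it builds a self-avoiding 3.8 Å-step
pseudo-Cα chain, displaces one planted contiguous block (about a fifth of
the chain) by a state-specific direction to create the states, jitters
coordinates per conformer, and only then derives distances through the same
code path real structures take. Synthetic matrices are therefore guaranteed
metric, which direct matrix perturbation would not be. Predicted matrices
are convex mixtures of the state matrices plus symmetric Gaussian noise
(added to the matrix, not the coordinates, since that is what a distance
head emits), truncated to [1, 20] Å; pairs saturated by the truncation carry
no mixture information and are masked. Defaults mirror the study shape:
3 states × 20 conformers, a 12-ligand panel in groups of 6/2/4, 8 Å
inter-state displacement, 0.3 Å jitter, 0.2 Å prediction noise, dominance
0.7.

What it does **not** emulate: real predictor error is structured (worse in
flexible regions, correlated along the sequence), real states differ by
concerted rearrangements rather than one rigid block, and real screening
decoys are not guaranteed to sit far from the target region. Passing the
recovery tests therefore demonstrates that the estimator and selection
logic are correct and well-conditioned under the stated noise model — not
that any particular real predictor is accurate.

## Numerical choices and degenerate inputs

- Solver tolerances: feasibility/multiplier slack 1e-9 relative; ties in
  `predominant_state()` below a 1e-6 margin are flagged ambiguous with a
  deterministic first-label fallback.
- Representative atoms: non-glycine residues lacking a Cβ are dropped
  everywhere (never silently substituted by Cα) and logged; altlocs resolve
  to highest occupancy, ties by identifier order.
- Residues are publicly identified as chain:author-number; matrices are
  never renumbered silently.
- Problem sizes in the test suite and acceptance runs: libraries of 80–150
  residues with 5–20 conformers per state, 20–50 seeded trials per
  property, a 200-compound × 11-model screen — sizes at which every stage
  completes in seconds while leaving the estimators' behavior clearly
  resolved.
- Randomness: every generator is a pure function of its config seed and
  restores the caller's RNG stream; per-stage seeds derive deterministically
  from one run seed via `derive_seed()`.

## Known limitations

- The active-set enumeration is exponential in the number of states; it is
  the right tool for the handful of states a curated library has, not for
  dozens.
- The reference-state residue count after representative-atom dropping is
  reported, not forced to any published count; deposited ensembles with
  unresolved residues will differ between files, and the intersection logic
  plus the coverage report make that auditable rather than invisible.
- The ANOVA treats conformers as independent; deposited models of one NMR
  ensemble are not strictly so, and the F map should be read as a ranking
  device, not a calibrated test.

## A worked run

```{r example, eval = FALSE}
g  <- generate_state_library(generator_config(seed = 42, n_res = 150))
pl <- generate_ligand_panel(g$library, dominance = 0.7, noise_sd = 0.2, seed = 42)
rep <- run_reweight(g$library, pl$panel, "results/reweight", truth = pl$truth)
sum(rep$recovered)  # ligands whose predominant state matches the planted one
```

The four scripts under `analysis/` run this end to end: simulate, state
statistics, reweighting, screening triage, each writing its tables under
`results/`.
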