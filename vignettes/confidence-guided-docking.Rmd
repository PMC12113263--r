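---
title: "Confidence-guided replica-exchange docking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-guided replica-exchange docking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(redock)
```

# The problem

Deep-learning structure predictors produce a single static model of a protein
complex together with a per-residue confidence estimate, pLDDT (predicted
local distance difference test, 0–100, stored in the PDB B-factor column).
For many complexes the individual partners are predicted well while the
docking orientation is wrong, and regions that move on binding are exactly
the regions the predictor is unsure about. `redock` turns those confidence
signals into a docking protocol: decide from the interface confidence
whether the predicted pose is trustworthy, then either refine it locally
with directed backbone flexibility or discard the orientation entirely and
re-dock the partners globally with temperature replica-exchange Monte Carlo.

# Confidence metrics and the gate

A residue is an *interface residue* when any of its heavy atoms lies within
8 Å of a heavy atom of the other partner; *interface contacts* are
cross-partner residue pairs whose Cβ atoms (Cα for glycine) are within 5 Å.
The *interface-pLDDT* is the plain mean of pLDDT over interface residues,
and the gate is

* interface-pLDDT ≥ 85 → **LOCAL**: the predicted orientation is plausible;
  refine near it.
* interface-pLDDT < 85 → **GLOBAL**: the orientation is unreliable; run a
  full rigid-body search.

A model whose partners are not even in contact has no interface and hence no
interface-pLDDT; we treat that as the strongest possible evidence of a
failed docking prediction and force the GLOBAL branch. The threshold (85)
and the mobile-residue threshold below are `pipeline_config()` parameters.

Per-residue pLDDT below 80 marks *mobile residues*: contiguous runs (same
chain, consecutive numbering) are kept when at least `min_run = 3` residues
long. The run-length floor is a design choice: one- or two-residue segments
give a backbone mover no meaningful lever arm, and the selection exists to
direct φ/ψ sampling, not to annotate single outliers.

# Flexibility metrics

Binding-induced conformational change between an unbound and a bound
conformation is quantified two ways, after per-chain global sequence
alignment (match +1, mismatch −1, linear gap −2; unaligned termini trimmed,
gapped positions excluded, and any chain under 30 % identity treated as a
pairing error):

* **per-residue RMSD** — one global Kabsch superposition over all mapped Cα
  atoms, then the per-residue Cα–Cα distance. The single global fit (rather
  than per-domain fits) means rigid-body domain motion shows up as elevated
  RMSD over the whole domain, which is the intended reading.
* **LDDT** — superposition-free: for every ordered residue pair (i, j),
  i ≠ j, whose *reference* Cα distance is under the 10 Å inclusion radius,
  the absolute difference between reference and model distances is tested
  against tolerances 0.5, 1, 2 and 4 Å; the pair score is the fraction of
  tolerances passed, the global score is the average over scored pairs, and
  per-residue scores restrict the average to pairs involving the residue.
  LDDT is computed on Cα only — the distance definitions here are written
  in terms of Cα coordinates — and self-pairs are excluded.

Both are invariant to rigid motion of either structure (LDDT by
construction, per-residue RMSD because superposition removes it), which the
test suite checks property-style.

# The docking engine

A *pose* is a fixed receptor plus the ligand, realized as internal
coordinates under a rigid transform (unit quaternion + translation).

**Moves.** Rigid moves draw an isotropic Gaussian translation whose
*expected magnitude* equals the schedule's `trans_mag` (the per-axis σ is
`trans_mag`/E|N₃(0,1)| = `trans_mag`/1.5958) and a rotation about a uniform
random axis through the ligand centroid with Gaussian angle (σ =
`rot_mag`). The global stage uses 4 Å / 8° moves, local refinement 1 Å / 3°.
Backbone moves pick one mobile segment on the ligand and add Gaussian φ/ψ
offsets (σ = 3°) to each of its residues, rotating all downstream atoms of
the chain; there is no loop closure, a deliberate simplification: the
contract preserved is *directed backbone sampling on low-confidence
segments*, not any specific mover chemistry. Because the pose holds the
receptor fixed, mobile segments on receptor chains are ignored (with a
warning when that empties the selection); refining the receptor backbone
would require a symmetric pose representation that is out of scope here.
In local mode, move types are drawn 3:1 backbone:rigid.

**Replica exchange.** Eight independent trajectories each hold one
configuration per temperature rung, kT = 1.5, 3 and 5 kcal/mol. Each rung
performs Metropolis updates at its own temperature; every 50 steps,
exchanges between adjacent rungs are attempted with the standard
parallel-tempering criterion min(1, exp((β_i − β_j)(E_i − E_j))),
alternating even/odd pairs. Snapshots of the coldest rung are recorded
every 50 steps. Swap frequency and snapshot cadence are engineering
defaults (exposed in the configuration); the temperatures, trajectory
count, and move magnitudes are protocol constants. A master seed spawns one
sub-seed per trajectory, so runs are bitwise reproducible.

**Scoring.** The energy model is pluggable (`score = function(pose)
-> energy`, lower better, deterministic, rigid-invariant for the whole
complex). The built-in `default_score()` is a coarse Cβ contact potential:
harmonic repulsion below 4 Å (k = 5 per Å²), a −1 reward per pair between
4 and 8 Å, nothing beyond. It is a deliberately simple surrogate standing
where a production pipeline would plug an all-atom force field; the
package's contribution is the protocol logic around the scorer, not the
scorer. Ranking uses the *interface score*: energy of the complex minus the
energy with the ligand displaced 500 Å along the center-of-mass axis.

**Clustering.** After the global stage the lowest-energy 20 % of decoys are
clustered greedily: the best decoy seeds a cluster and absorbs everything
within 5 Å ligand-Cα RMSD (the receptor is shared, so no superposition is
needed), repeating up to five representatives. Ligand RMSD is the
similarity metric because it is the quantity the decoys differ in under a
fixed receptor. Each representative seeds a local refinement run; when
fewer than five clusters emerge, all of them proceed.

# Evaluation

Model quality against a bound reference uses the standard docking metrics:
fnat (fraction of reference cross-partner residue contacts, 5 Å heavy-atom
rule, reproduced by the model), interface RMSD (backbone atoms of
reference-defined interface residues at 10 Å, jointly superposed), ligand
RMSD (superpose on receptor backbone, RMSD over ligand backbone), and

$$\mathrm{DockQ} = \tfrac13\left[f_\mathrm{nat}
 + \frac{1}{1+(I_\mathrm{rms}/1.5)^2}
 + \frac{1}{1+(L_\mathrm{rms}/8.5)^2}\right]$$

binned into CAPRI classes: incorrect (DockQ ≤ 0.23), acceptable
(0.23, 0.49], medium (0.49, 0.8), high (≥ 0.8). The boundary value 0.23 is
classified *incorrect* and 0.8 *high*, resolving the open/closed ambiguity
the same way the class definitions print it; the success flag is
DockQ > 0.23.

# Synthetic fixtures: what they emulate and what they do not

All tests run on generated toy complexes: two ideal-geometry peptides
(standard bond lengths 1.46/1.52/1.33 Å, helix φ/ψ = −57/−47°), placed
antiparallel with a planted clash-free native pose (closest heavy-atom
approach 4.5 Å, at least five Cβ pairs within 8 Å). Confidence profiles are
piecewise-constant with optional Gaussian noise, emulating the
low-confidence segments seen in real predicted models. Decoys at controlled
ligand-RMSD are produced by scaled rigid perturbation.

The planted landscape for sampler validation is
`funnel_score_factory()`: the contact potential minus a Gaussian basin of
depth 150 and width 6 Å in ligand-RMSD, centered on the native. The depth
is ~30× the hottest rung temperature and much larger than the spread of
the contact term, so the planted basin is the global minimum of the
landscape (cold minimization confirms the minimum sits within ~1 Å of the
native); the width is ~1.5× the global translation magnitude, giving a
capture radius of roughly 15 Å — where the basin term first exceeds the
hottest kT — so trajectories diffusing over the partner surface can find
it within a few thousand steps.

These fixtures exercise geometry, bookkeeping and sampling exactly, but
they are *not* proteins: no side chains beyond Cβ, no secondary-structure
rearrangement, no rugged all-atom landscape, no experimental noise. Passing
the planted-recovery tests demonstrates the correctness of the protocol
machinery — gate, search, exchange, clustering, ranking — under a landscape
whose answer is known, not docking accuracy on real complexes.

# Numerical choices and degenerate inputs

* pLDDT is kept on the 0–100 scale internally; inputs with maximum ≤ 1 are
  rescaled ×100 with a warning.
* Glycine (or any residue lacking Cβ) substitutes Cα in Cβ selections.
* Altloc conformers: highest occupancy kept, first on ties; model 1 of
  multi-model files; hydrogens dropped on read (all distance rules are
  heavy-atom rules).
* Empty interface → interface-pLDDT undefined (`NA`) → GLOBAL gate.
* LDDT with no pairs inside the inclusion radius, references without
  native contacts, and interfaces under 3 residues are errors, not
  silent zeros.
* Kabsch superposition constrains the rotation to determinant +1; ties in
  ROC threshold sweeps collapse equal scores to a single threshold; AUC is
  trapezoid-rule.
* Metropolis consumes a uniform variate only for uphill moves; downhill
  and zero-ΔE moves are accepted unconditionally.

# Problem sizes used in the test suite

The suites run on 36-residue complexes (20 + 16), with 8 trajectories ×
3 rungs × 5000 global steps and 500–1000 local steps per refinement start;
statistical checks use 10⁵ Metropolis trials and ≈10⁶ discrete
replica-exchange updates. These sizes were chosen so the full validation
runs on a single CPU in minutes while keeping every statistical test
well-powered.

# Known limitations

* Backbone flexibility is ligand-side only, Gaussian-φ/ψ, without loop
  closure; large concerted rearrangements are outside the move set.
* The default scorer has no electrostatics, desolvation or side-chain
  packing; it is a protocol-testing surrogate, and real applications
  should plug a physical score model.
* The receptor/ligand partition must be supplied by the user; nothing in a
  predicted model marks which partner should be held fixed.
* mmCIF, nucleic-acid chains and cofactors are not parsed.

# A worked example

```{r example, eval = FALSE}
toy <- make_toy_complex(seed = 3)            # planted native pose
set.seed(1)
wrong <- make_decoy(toy$native, 30)          # wrong-site starting model
model <- pose_complex(wrong)
conf <- make_confidence(model, baseline = 82) # fails the 85 gate

report <- run_docking_pipeline(
  model, "A_B", confidence = conf,
  config = pipeline_config(score = funnel_score_factory(toy$native),
                           local_steps = 500),
  seed = 1)
report$stages
#> "gate" "global" "cluster" "local" "rank"
min(sapply(report$final, function(f) pose_lrms(f$pose, toy$native)))
#> about 1 Angstrom: the planted pose is recovered
```
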