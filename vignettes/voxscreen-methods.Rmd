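---
title: "voxscreen: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{voxscreen: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

voxscreen implements a structure-based virtual-screening pipeline built
around a 3D convolutional scoring network: a binding site is delineated by
a flooding algorithm, rigid ligand poses are sampled inside it, each
protein--ligand pose is rasterized into a fixed-size multi-channel voxel
grid, a convolutional network regresses binding affinity (pK) from the
grid, pose scores are combined by Boltzmann-weighted averaging, and the
ranked library passes through a triage cascade (top-K, property filters,
SMARTS exclusions, ECFP4/Butina diversity clustering, drug-likeness
rules). This vignette documents the models, the parameters that matter,
the numerical choices, and what the synthetic-data experiments do and do
not demonstrate.

## Binding-site definition by flooding

The site is grown breadth-first from a seed point over a cubic lattice
anchored at the seed (the seed is itself a lattice point). A lattice point
joins the site iff it is

* **open** — no protein heavy atom within `occlusion_radius` (default
  2.0 Å, roughly a heavy-atom vdW radius plus a probe margin);
* **buried** — at least `burial_min_neighbors` (8) protein heavy atoms
  within `burial_radius` (8 Å), which prevents the flood from escaping
  into bulk solvent;
* **reachable** — connected to the seed through open+buried points
  (6-connectivity by default) within `max_radius` (12 Å) of the seed.

Flooding on a plain occupancy lattice (rather than a solvent-accessible
surface) is a deliberate, documented choice: the published description
names the algorithm but not its occupancy rule, so every rule above is
exposed in `flood_params()` and other readings are expressible. The site
**center** is the unweighted arithmetic mean of the flooded voxel centers
— the site is a spatial region, not a molecule, so atom-mass weighting
would be meaningless. If the flood keeps pressing against the
`max_radius` shell in more than half of the 26 lattice directions, an
"open-solvent" warning is emitted; the site is still returned because a
partially open site may be exactly what the user seeded.

The seed can be given directly (x, y, z) or derived from named pocket
residues (`seed_from_residues()`, the centroid of their heavy atoms), the
usual route when mutagenesis or template alignment identifies the pocket.

## Pose sampling and featurization

Poses are rigid placements: the ligand's heavy-atom centroid moves to the
site center, a uniform random rotation (Shoemake's quaternion
construction) and a translation uniform in a ball of radius `t_max`
(default 4 Å) are applied, and the pose is rejected if any ligand--protein
heavy-atom pair comes closer than `clash_factor` (0.75) times the sum of
the pair's Bondi van der Waals radii. The package does not dock: the
scorer consumes poses from any source, and random clash-free placement is
the documented built-in pose generator.

Rasterization writes each heavy atom into the voxel
`floor((x - origin)/spacing)` of a `n^3` box centered on the site
(default n = 30, spacing = 1 Å). Channels are element groups (C, N, O, S,
P, halogen, other) crossed with role (protein/ligand): 14 binary channels.
Occupancy is binary by design — the grid encodes the *presence* of atom
types, like color channels in an image; a Gaussian-density option is
deliberately out of scope. Hydrogens are ignored throughout the package
(grids, clash checks, flooding): heavy-atom-only is the simplest
defensible convention and protonation states are never inferred.

Two augmentation routes exist:

* `augment_complex()` applies one random rigid motion (rotation +
  translation up to 2 Å) to protein and ligand jointly about the site
  center — the classic anti-memorization augmentation, exact on
  coordinates;
* `augment_grid_rotations()` applies proper 90-degree lattice rotations
  directly to finished grids. These 24 cube rotations are *exact* voxel
  permutations (verified against re-rasterization of rotated
  coordinates), so they add rotated training views with zero
  interpolation error and carry labels over unchanged.

## The scoring network

The default architecture follows the published layer sequence: five
convolutions of 32×3³, 64×3³, 64×3³, 64×3³, 64×2³ filters, a 256-unit
ReLU dense layer, and a linear scalar output (predicted pK; higher =
stronger predicted binding). Strides and pooling are not published; the
default uses stride-1 valid convolutions with 2³ max-pools after the
second and fourth convolutions, which keeps the flattened size at 1,728
for a 30³ input. The layer list is fully configurable
(`conv3d_layer()`, `maxpool_layer()`, `dense_layer()`), so other readings
of the sequence are expressible; shape chains are validated at build time
with the offending layer named.

Training minimizes mean-squared error on pK with ADAM (mini-batches of
64, learning rate 1e-3 by default), with an optional decoupled weight
decay on weight matrices. Initialization is He-style for ReLU layers,
deterministic given the seed; shuffling comes from the config seed; the
C++ core (im2col + BLAS GEMM) contains no randomness of its own, so a
trained model is a pure function of (data, seeds, config) on a given
machine. `lr = 0` provably leaves parameters untouched, which the tests
use as an optimizer sanity check. A NaN loss aborts with a
learning-rate hint rather than returning garbage.

Pose ensembles are combined by Boltzmann-weighted averaging
`S = sum(s_i e^{beta s_i}) / sum(e^{beta s_i})` with a max-shift for
overflow safety. `beta` (default 1, in 1/pK units) interpolates between
the arithmetic mean (beta = 0) and the maximum (large beta). One
mathematical subtlety is worth recording: the weighted mean is *not*
monotone in every single input — `dS/ds_i = w_i (1 + beta (s_i - S))` is
negative when `s_i < S - 1/beta`, i.e. raising a far-below-average pose
score increases the weight carried by a low value and can lower the
ensemble. The properties that do hold (bounds by min/max, translation
equivariance, monotonicity in the maximum, the beta limits) are the ones
the test suite asserts.

Screening ranks compounds by descending ensemble score with
lexicographic id tie-breaks. Each compound's pose stream is seeded from a
hash of its *content* (elements + coordinates), so structurally identical
entries receive identical scores and results are invariant to library
order. Compounds with no placeable pose are ranked last and flagged —
never silently dropped.

## Triage cascade

Stage order is fixed: (1) top-K by rank (default 30,000); (2) molecular
weight strictly above 200 Da; (3) SMARTS exclusion (a molecule matching
*any* pattern is removed, the first matching pattern recorded); (4) ECFP4
fingerprints + Butina clustering at Tanimoto similarity ≥ 0.35, keeping
cluster representatives; (5) MW < 500 Da, cLogP < 5, PAINS pass, and an
optional externally supplied toxicology score (< 2.0). All inequalities
follow the printed thresholds verbatim, strict where printed strict. A
full per-compound audit trail records which stage removed each compound
and why.

Descriptor provenance: MW, Wildman--Crippen cLogP and Ertl TPSA come from
OpenBabel (via ChemmineR/ChemmineOB); Lipinski HBA is the N+O count;
Lipinski HBD is the count of N--H plus O--H bonds from an in-package
valence model; rotatable bonds are counted on the molecular graph with
the standard strict rule — single, non-ring, both ends non-terminal,
excluding amide *and* ester acyl bonds. The descriptor panel test pins
all six descriptors against values from an independent toolkit on a
50-molecule panel chosen where the major toolkits' conventions coincide
(neutral C/H/O aromatic and aliphatic chemistry; primary amines, sulfur
TPSA contributions and charged nitro groups are typed differently across
toolkits and are deliberately not in the panel).

ECFP4 is implemented in-package (no installed R package provides Morgan
fingerprints): two rounds of neighbor refinement over (bond order, atom
identifier) pairs, order-independent by sorting, all intermediate
identifiers hashed onto 2,048 bits with a 32-bit FNV scheme. Bit
positions are not comparable across toolkits (hashing differs everywhere);
what matters — and what is tested — is canonical invariance (same
molecule, same bits regardless of atom order) and discrimination.

Butina clustering follows the published greedy sphere-exclusion
procedure: neighbor counts at the cutoff, descending order with
lexicographic id tie-breaks, the top unassigned compound claims its
unassigned neighbors, repeat. The test suite checks equivalence against a
literal matrix-based transcription of the procedure on randomized sets.

The PAINS screen ships a curated, editable subset of well-known public
pan-assay-interference motifs (catechol, quinones, rhodanines, azo
dyes, ...) as a plain-text SMARTS file; a fuller catalog can be passed as
a file. The pass rule is 0 matches. The published "PAINS score < 0.6"
and "toxicology score < 2.0" come from a proprietary scale that cannot be
reproduced; the tox hook therefore accepts an external score column and
applies the printed cap, and ships no model of its own.

## Structure QC

`kabsch_superpose()` is the closed-form SVD solution with the determinant
correction (reflections never returned); degenerate (collinear) inputs
raise a conditioning error rather than returning an arbitrary rotation.
`backbone_rmsd()` pairs residues by index (with an optional offset; no
sequence alignment, which is out of scope) and uses N/CA/C by default,
CA-only being the common alternative. Clash detection applies the same
vdW rule as pose sampling, so an accepted pose always yields an empty
clash report at the same factor. pLDDT banding uses the AlphaFold DB
convention (≥ 90 very high, 70--90 confident, 50--70 low, < 50 very low;
boundaries inclusive upward), since the published analysis names the
bands but not the edges; scores are read from the B-factor column or a
CSV.

## Synthetic data: what it emulates, what it does not

The generators provide ground truth the real task lacks:

* `make_pocket()` builds hollow cuboid shells of pseudo-atoms (mixed
  C/N/O) around an empty cavity. The wall's inner face sits at
  `cavity_edge/2 + 1.5` Å so that, at the default 2 Å occlusion radius, a
  3 Å cavity floods to exactly 27 voxels — a fully known flooding answer.
  Pseudo-atoms are grouped into 8-atom pseudo-residues with standard
  names so pocket-residue listing and clash attribution work unchanged.
* `make_ligand_set()` grows random heavy-atom clusters (default 4--20
  atoms, C/N/O/S) with bonded distances 1.45--1.6 Å and a 1.2 Å minimum
  non-bonded separation.
* `true_affinity()` defines the recoverable signal:
  pK = 0.15 per ligand-atom/protein-N-or-O contact within 4 Å, minus 0.5
  per clashing pair, plus Gaussian noise (default sd 0.2). A contact-count
  model was chosen deliberately: given a fixed pocket it is approximately
  linear in the ligand's occupancy grid, so a voxel CNN can in principle
  learn it — ranking recovery then tests the featurizer and network, not
  quantum chemistry. The gain of 0.15 with a 10 Å default cavity places
  labels on a realistic pK-like scale (roughly 0--13, s.d. ≈ 3).
* `make_training_set()` composes pocket → ligand → pose → label → grid,
  one pose per complex, and emits a manifest of every derived seed;
  regeneration is bit-exact. Ligands that cannot be placed without
  clashes (very extended clusters in a small cavity) are redrawn
  deterministically; the default training size range is 4--14 atoms so
  redraws are rare.
* `make_screen_library()` emits SMILES libraries with *planted* triage
  outcomes: tiny molecules below the MW floor, nitro-capped tails for the
  SMARTS stage, and eight scaffold families with family-uniform stage-5
  traits (a catechol/PAINS family, a long-alkyl high-logP family, an
  over-500-Da family). Family-uniformity matters: whichever member Butina
  picks as representative, the stage-5 outcome is determined, so the
  expected survivor count of every stage is exact. The generator
  *verifies* its own plants (descriptor classes, PAINS hits, and the
  full intra/inter-family similarity structure against the Butina cutoff)
  and raises a plan error rather than returning an unverified truth.

What passing these tests shows: the geometry, featurization, training
loop, ranking and triage logic are correct and reproducible, and the
network can recover a learnable structure--affinity signal end to end.
What they do not show: performance on real protein--ligand complexes.
Real affinity is not a contact count; real pockets flex; real libraries
have property distributions the planted families do not imitate. The
synthetic results are software verification, not a virtual-screening
benchmark.

## Problem sizes and numerical choices

The test suite and the acceptance script use desk-scale sizes chosen as
the package's own study conditions:

* Ranking recovery trains on 500 synthetic complexes — 250 ligands
  contributing two sampled poses each, the `make_training_set()` default,
  since multiple poses per ligand teach the pose-dependence of the
  contact signal rather than ligand identity (and pose ensembles are how
  the screening method itself is defined) — with label noise sd 0.2 at a
  reduced 16³ grid, using a compact two-convolution network (8×3³, 8×3³,
  dense head), 4-fold exact-rotation augmentation, ADAM at 3e-3 with
  weight decay 0.2 and Polyak parameter averaging (decay 0.98) for 15
  epochs. It then screens 50 held-out compounds with the default 16-pose
  Boltzmann ensembles; Spearman correlation against the noise-free
  contact-model ranking is computed for three independent seeds. The
  published 30³ five-conv network cannot run on 16³ inputs (the shape
  chain bottoms out), and at full size a single CPU epoch over 500
  complexes takes minutes — the compact network is the documented
  scaled-down setting, and the full architecture's fidelity and capacity
  are exercised separately. Parameter averaging matters here: mini-batch
  trajectories on this loss are chaotic, and the averaged parameters are
  markedly more stable across seeds than any single end-of-training
  iterate.
* The capacity (memorization) check runs the full published layer
  sequence on 20³ grids — the smallest edge the printed sequence admits
  with its two pools — and must drive training MSE on 8
  arbitrary-labeled grids below 0.01.
* Flood-oracle equivalence uses randomized 220-atom occupancy mazes with
  a 6 Å flood radius, small enough that the brute-force full-lattice
  oracle is itself fast.

Numerical details worth knowing: ensemble averaging max-shifts before
exponentiating; Kabsch refuses near-collinear inputs (second singular
value below 1e-10 of the first); voxel indices use `floor`, so an atom
exactly on the box's upper face is outside; maxpool ignores a trailing
odd slice; ADAM uses the standard bias correction, and weight decay is
decoupled (never applied to biases). All randomness flows through
explicit seeds via one `with_seed()` gate that restores the caller's RNG
state; per-compound, per-complex and per-stage streams are derived with a
hash so results never depend on iteration order.

## Known limitations

* Binary occupancy discards sub-voxel geometry; at 1 Å spacing this puts
  a floor on pose-level accuracy of any grid-based scorer (the noise-free
  contact model itself, read back through the grid, correlates ~0.95 with
  its own labels at pose level).
* The SMILES lint rejects only structurally truncated records; OpenBabel
  silently normalizes some other malformed inputs rather than rejecting
  them.
* Butina clustering is O(n²) in fingerprints; fine for tens of
  thousands of compounds, not for millions (the published screen
  clustered only the top 30,000, which is the intended scale here too).
* Ligand SDF export writes V2000 with single-conformer coordinates only.
* The CLI's grid/model archives use R's native serialization; the CSV and
  JSON artifacts, which carry the scientific results, are byte-stable
  across identical runs and that is what the determinism checks assert.
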