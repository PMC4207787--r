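---
title: "Methods: ensemble-based screening for homo-dimer interface stabilizers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble-based screening for homo-dimer interface stabilizers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerstab)
```

## The problem

Some disease mutations do not break an enzyme's active site but destabilize
the protein-protein interface that holds its functional oligomer together.
A small molecule that binds at or near the weakened interface can act as a
*stabilizer*, restoring activity by shifting the monomer-dimer equilibrium.
Finding such molecules computationally differs from classical inhibitor
screening in two ways: the binding site is an interface pocket that may only
exist transiently (so a single crystal conformation is not enough), and
interface binders tend to be larger and more lipophilic than oral-drug rules
of thumb allow.

`dimerstab` implements the desk-scale computational protocol for this
problem as a chain of testable stages:

1. **Ensemble validation** — superposition, RMSD against the average
   structure, per-residue RMSF and pseudo B-factors, to check that a
   conformational ensemble is usable before anything downstream trusts it.
2. **Binding-site conformation selection** — an all-atom RMSD matrix over
   the binding-site atoms of every snapshot, Ward hierarchical clustering
   with a dendrogram cut, medoid ("centroid structure") extraction, and a
   population-density report for the chosen conformations.
3. **Pocket triage** — grid-probe cavity detection with volume, surface,
   lipophilic-surface and depth descriptors, a transparent [0,1]
   druggability score, and proximity filtering around the mutation site.
4. **Compound filtering** — physicochemical descriptors, a PPI-adapted
   drug-likeness filter, circular fingerprints with Tanimoto diversity
   (0.3) and scaffold (0.6) clustering, and substructure liability flags.
5. **Consensus docking analysis** — per-engine, per-conformation score
   tables are ranked, truncated to a top-N list each, and intersected;
   per-conformation consensus sets are pooled with provenance.
6. **Binding-energy rescoring** — rigid (single-trajectory) and relaxed
   (separate-trajectory) binding energies from per-snapshot energy streams
   with last-window averaging, then OR-threshold candidate selection.

Docking engines, molecular dynamics engines and vendor libraries are out of
scope: the package consumes their *outputs* (score tables, energy streams,
structure ensembles) and ships a synthetic generator that emulates those
outputs with planted ground truth, so the entire protocol runs and is
tested end-to-end on one machine.

## Models and conventions

### Superposition and fluctuation analysis

Rigid-body fits use the Kabsch SVD solution with a determinant correction
so no reflection can enter. Global RMSD traces are computed over backbone
atoms (N, CA, C, O) after superposition; fluctuation profiles default to
the C-alpha trace. Both selections are arguments, not constants. The
average structure is the iteratively re-superposed arithmetic mean
(tolerance 1e-6 Å on the mean's movement, at most 50 iterations); no
force-field minimization is applied to it, so it is a geometric reference,
not a physical conformation. Pseudo B-factors use the isotropic harmonic
relation `B = (8*pi^2/3) * RMSF^2`.

### Binding-site clustering

The conformation matrix holds, for every frame pair, the RMSD of the
binding-site selection after superposing one frame onto the other over that
same selection (a global-backbone superposition mode is available; which
alignment precedes the pocket RMSD is a genuine free choice, so both are
shipped and the local one is the default). The upper triangle is computed
and mirrored, which keeps the matrix exactly symmetric.

Clustering uses Ward's criterion in its `ward.D2` form — the Lance-Williams
recurrence on squared distances with heights reported on the distance scale
— via `stats::hclust`. The `ward.D` variant is a switch. The default cut
height is 1.3 Å and the number of clusters is *emergent*: a fixed-`k` mode
exists but is not the default, because the number of distinct binding-site
conformations is a property of the data. "Centroid structures" are medoids
(the member minimizing mean distance to its cluster, ties to the lowest
frame index): an actual snapshot that can be docked into, not an averaged
geometry. The tests verify the whole agglomeration against an independent
from-scratch implementation that recomputes the Ward objective from the
base matrix at every merge.

### Pockets and druggability

The detector embeds the structure in a cubic lattice (spacing 0.5-1.5 Å,
default 1.0 Å; the grid origin is snapped to the lattice so results are
exactly translation-invariant for shifts by whole cells). Cells inside any
atom's van der Waals radius (fixed published element radii, probe radius
1.4 Å) are protein; remaining cells within 4.5 Å of the vdW surface are
candidates; a candidate is buried if at least 18 of the 26 lattice scan
directions hit protein. Buried cells form pockets by face adjacency;
components under 30 ų are noise and dropped.

Descriptors: volume is cell count times cell volume; surface is the area of
cavity-cell faces not shared within the pocket; the lipophilic surface is
the part of that area whose nearest protein atom is an apolar carbon or
sulfur (apolar = no N/O within the 1.9 Å bond-inference distance); depth is
the largest grid-path distance from a pocket cell to unburied space, capped
at 10 Å (a fully enclosed void takes the cap). The druggability score is a
logistic combination of the normalized descriptors,

`plogis(-6 + 4 * min(V, 1500)/1500 + 3 * lipo/surface + 4 * depth/10)`,

monotone in each term and bounded in (0, 1). This score is deliberately
transparent and is **not** numerically equivalent to trained
machine-learning druggability scores from external webservers; only its
range and its triage role (keep pockets scoring above 0.80 near the
mutation site) carry over. Published per-pocket score values from such
tools are therefore not reproduction targets for this package.

### Compound filtering and similarity

Descriptors (molecular weight, Crippen-type logP, Ertl-type tPSA, donor and
acceptor-typed acceptor counts) come from the OpenBabel backend; rotatable
bonds are counted in-package as acyclic single bonds between non-terminal
heavy atoms, amides excluded. The PPI-adapted filter uses strict open
intervals: 100 < MW < 700, 0 < tPSA < 160, -4 < logP < 6, 0 < HBD < 5,
0 < HBA < 10, 0 < RotBonds < 15. The bounds are applied exactly as written
— strictly on both sides — which notably means a compound with zero
donors or zero acceptors fails. That is a faithful reading of the stated
ranges rather than a chemical judgement, and the rule table is a plain
data.frame argument that a user can replace.

Fingerprints are circular substructure fingerprints (radius 2, i.e.
diameter 4, folded to 2048 bits) with pharmacophoric atom typing (donor,
acceptor, halogen, acidic, basic) in the initial atom codes. Proprietary
functional-class fingerprints are replaced, not imitated: bit-for-bit
equality with commercial implementations is a non-goal, while the
functional-class-at-diameter-4 intent is preserved. SMILES are
canonicalized before hashing, so the bitset depends only on the molecular
graph, never on atom order or kekulization. Diversity selection is
sphere-exclusion (leader) clustering at Tanimoto distance 0.3 with a
deterministic processing order; scaffold grouping of actives is
single-linkage at similarity 0.6. Liability screening ships a small,
documented SMARTS subset (reactive groups and two PAINS-type motifs), not a
full curated catalogue.

### Consensus and binding energies

Score tables carry an explicit better-direction (positive higher-is-better
and negative lower-is-better scales both occur in practice). Ranking breaks
ties lexicographically by compound id; top-N truncation keeps all
boundary-tied compounds and warns. Intersections require two *different*
engines on the *same* conformation scoring the same compound universe —
mismatched universes are an error rather than a silent bias. Pooling
reports both the per-conformation counts with their sum and the union size:
the two coincide only when the per-conformation sets are disjoint, so both
readings are always surfaced instead of silently picking one.

The rigid protocol averages `E_complex - E_receptor - E_ligand` over the
last 20 snapshots with the component energies extracted from the complex
snapshots; the relaxed protocol subtracts last-window means of independent
component runs instead, so component relaxation — and implicitly entropic
effects — enter the estimate. Selection keeps compounds whose rigid *or*
relaxed energy is at least as favourable as -20 kcal/mol ("better than" is
read as more negative or equal, and the disjunction is deliberate), sorts
by the better of the two, and truncates to a configurable final count
(default 51). A fully specified toy pair potential (Lennard-Jones plus a
screened Coulomb term with distance-dependent dielectric `eps(r) = 4r`,
parameters shipped as a config table) lets the protocols run on explicit
coordinates; it makes no claim of force-field equivalence.

## The synthetic generator

`synth_spec()` fixes the study conditions; every artifact draws from a
named RNG substream of one master seed, so a single integer reproduces
every byte. Defaults: a 1500-snapshot ensemble at 1 ps spacing over a
two-chain helical toy dimer, 8 discrete binding-site states, a 5000-record
compound library with 30% planted filter violations, 10 planted binders
with true binding energy -25 kcal/mol (non-binders -5), Gaussian snapshot
noise of 2 kcal/mol, and a planted relaxation offset of 5 kcal/mol.

Two generator choices deserve their rationale:

* **State displacements are non-rigid patterns.** Each state displaces
  every binding-site atom along a fixed random unit direction scaled by
  the 3 Å amplitude. A *rigid* sub-motion of exactly the binding-site
  atoms would be removed by the Kabsch fit the distance matrix applies
  over those same atoms, making planted states invisible by construction;
  random per-atom patterns have negligible rigid component, so the planted
  separation survives superposition.
* **Amplitude 3 Å, thermal noise 0.15 Å.** Two frames of the same state
  differ by independent noise in both, giving intra-state RMSD near
  `sigma * sqrt(6)` (about 0.37 Å), while two states differ by about
  `amplitude * sqrt(2)` (above 4 Å, and at least 3 Å across random
  patterns). This realizes a well-separated conformational-selection
  scenario — intra below 0.5 Å, inter above 3 Å, separation an order of
  magnitude over thermal noise — where a 1.3 Å dendrogram cut must recover
  the states exactly; the recovery tests verify that the generated
  ensembles actually satisfy these separations before asserting recovery.

What the generator does **not** emulate: real MD ensembles have correlated,
anisotropic fluctuations and gradual (not discrete) conformational drift;
synthetic SMILES are valid but chemically arbitrary, and library
descriptors are planted rather than recomputed from the structures; docking
scores derive from one latent affinity per compound, so the two engines
disagree only through additive noise. Passing tests therefore demonstrate
that the *machinery* is correct under its stated assumptions, not that the
protocol's thresholds are optimal for any real system.

## Pipeline and reporting

`run_pipeline()` chains the stages with one structured log line each and
aborts with the stage name on failure. Planted truths (state labels, pass
flags, binder ids, true energies) are emitted alongside the synthetic data
and consumed only by the evaluation columns of the report (recovery
statistics), never by a stage's decision. The report excludes the
wall-clock timestamp from serialization so equal seeds give byte-identical
output, and a funnel check asserts the compound counts are monotone
nonincreasing from library to final candidates. On the toy dimer the
interface groove pocket typically scores below the 0.80 druggability floor;
the pipeline reports the floor count (usually zero) and proceeds with the
best-scoring pocket near the site, since the downstream synthetic docking
stage does not depend on pocket geometry.

Problem sizes in the default configuration — 1500 frames of a 480-atom
dimer, a 5000-compound library, top-2000 consensus lists, 40-snapshot
energy streams for every pooled compound — were chosen as the package's
standard desk-scale workload; the full run takes well under a minute on a
single CPU thanks to the compiled pairwise-RMSD and burial kernels.

## Numerical choices and degenerate inputs

* Kabsch requires at least 3 non-collinear selected atoms; collinearity is
  detected via the second singular value.
* The distance matrix validates symmetry, zero diagonal and finiteness;
  Ward height inversions (possible on non-metric input) raise a warning.
* Medoid ties resolve to the lowest frame index; ranking ties to the
  lexicographically smaller id; both make reruns reproducible.
* Altloc resolution keeps the highest occupancy, first on ties; atom
  serials wider than the PDB field are written modulo 100000 and residue
  numbers modulo 10000.
* Tanimoto of two empty bitsets is defined as 1.
* Hydrogens are excluded from "all-atom" selections and from the pocket
  grid by default (ensembles may or may not carry them); flags include
  them.
* Residue numbering is taken verbatim from input files; reports always
  print `chain:resno`, and no renumbering (including any author-vs-FASTA
  offset a source structure may carry) is ever applied.

## Known limitations

The druggability score is geometric and untrained; the toy potential is
not a force field; subpocket splitting is not implemented (pockets are
reported whole); stereochemistry is ignored throughout (no 3D generation);
and the visual-triage step of a real screening campaign — inspecting
poses for shape and polar complementarity — has no automated counterpart
here, so the pipeline's final list is a threshold-and-rank truncation.
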