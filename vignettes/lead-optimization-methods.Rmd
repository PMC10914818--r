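---
title: "Lead-structure optimization by deep Q-learning: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lead-structure optimization by deep Q-learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Given a synthesized lead compound — here the free
3,6-bis(benzimidazol-1-yl)pyridazine ligand of a nickel coordination
polymer with measured anticancer activity — the package searches the
chemical neighborhood of that lead for analogues that are
simultaneously more drug-like (QED), still synthetically accessible
(SA) and more strongly bound to a target receptor (predicted binding
free energy).  The search is cast as a reinforcement-learning problem
over molecular graph edits, followed by threshold screening of the
episode log and docking-pose validation of the survivors.

## The molecule-modification MDP

A state is a pair (molecule, steps taken); an episode starts at the
unmodified lead and ends after a fixed number of edit steps (default
16; the smoke configuration uses 8).  From any state the agent may
apply one of four action families:

* **atom addition** — attach a new C, N or O atom to any atom with free
  valence, by a bond of any feasible order;
* **bond addition** — close a ring between two unbonded atoms with
  spare valence, or increment the order of an existing non-aromatic
  bond;
* **bond removal** — decrement or delete a non-aromatic bond; if a
  deletion disconnects the graph, the largest fragment is kept so every
  state remains a single connected molecule;
* **no modification** — the identity action, always legal.

Valence bookkeeping uses kekulé bond orders and the convention that
implicit hydrogens are replaceable: an atom's free valence equals its
implicit-hydrogen count, so a methane carbon has free valence 4 and an
aromatic CH carbon 1 (ring substitution is allowed, as it must be for a
fully aromatic lead).  Fractional "aromatic = 1.5" accounting was
rejected because it breaks integral valence sums for pyrrole-type
nitrogen.  Aromatic bonds are frozen: never removed or incremented, so
perceived aromatic systems survive editing.  Triple bonds are limited
to C/N pairs.  Every candidate is valence-valid by construction, and
candidates are deduplicated by identity: canonical-SMILES equality as
the contract, implemented in the hot loop by a structural-invariant key
(converged circular atom codes plus the bond multiset).  Distinct keys
provably imply distinct molecules; the test suite verifies on an
exhaustive small-molecule universe that the key never wrongly merges
candidates that canonical SMILES would distinguish.

SMILES parsing, aromaticity perception, the hydrogen model and
canonical serialization delegate to OpenBabel; the editable graph, the
enumerator and everything downstream of it are this package's own.

## The learner

A deep Q-network scores candidate molecules directly (a merged
state-action value): the input is a circular (Morgan-type) fingerprint
of the candidate folded to a fixed width, with the normalized
steps-remaining clock appended.  The fingerprint carries **counts**
per folded slot rather than binary presence: substructure
multiplicities are what the additive parts of the reward respond to,
and keeping them makes the value function nearly linear in the
features, which a small network can learn quickly.  Rewards are
terminal-only — an episode is scored once, on its final molecule — and
propagate backwards through bootstrapped targets
`r + gamma * max Q_target(next candidates)` with a discount of 0.9 and
a target network synced every few episodes.  The scalar training
reward is `-affinity/10 + QED + SA` with configurable weights; the
three components are also logged separately per episode, so screening
never depends on the scalarization.

Exploration follows the linearly decaying epsilon-greedy schedule:
epsilon starts at 1.0 (pure random) and decreases by `1/episodes` per
episode, reaching 0 at the end of the run (6000 episodes at study
scale).  The schedule is stored in rational form and evaluated as
`1 - episode/denominator`, so the quartile values 0.75/0.5/0.25 are
exact doubles, not 1-ulp neighbors.  Greedy ties are broken by
lexicographic canonical SMILES.

Defaults at study scale follow the common deep-Q practice for this
problem family: 2048-slot radius-2 fingerprints, two hidden layers
(1024, 512), replay buffer 5000, batch 128, Adam at 1e-4.  The
smoke-scale configuration (`seeded_smoke_config()`) runs 200 episodes
of 8 edits with a 256-slot fingerprint, hidden layers (128, 64),
batch 32, learning rate 1e-3 and target sync every 10 episodes — sized
so the whole run finishes in about three minutes on one CPU while
still learning a clearly detectable policy (its episode rewards
stochastically dominate a pure-random agent's at `p < 1e-4`).

## The three rewards

**QED** is the standard eight-descriptor desirability score: molecular
weight, calculated logP, H-bond acceptors and donors, topological
polar surface area, rotatable bonds, aromatic rings and structural
alerts, each mapped through the published asymmetric-double-sigmoid
desirability functions and combined as a weighted geometric mean.
Descriptors are computed with OpenBabel (Wildman-Crippen logP, Ertl
TPSA); aromatic-ring counts come from the package's own ring
perception (cycle rank of the aromatic subgraph); the 116 structural
alerts are evaluated as SMARTS, with the two multi-component published
patterns expressed as count thresholds and an element-requirement
prefilter that skips patterns that cannot match a C/N/O molecule.
Agreement with the reference implementation is ~1e-3 on validation
molecules; the lead scores 0.502.

**SA** is the fragment-contribution synthetic-accessibility score: the
commonness score of every circular atom environment (radii 0-2,
emitted under the standard fingerprint rule that a larger-radius
environment only counts when its bond set is novel), averaged and
combined with complexity penalties (size, spiro atoms, bridgeheads,
macrocycles; stereo is identically zero here because generated edits
are stereo-agnostic) and a symmetry correction, mapped to the 1 (easy)
to 10 (hard) scale.  The packaged environment-score table
(`inst/extdata/sa_fragment_scores_[1-4].tsv`) keys the published
fragment-frequency scores by this package's own environment
identifiers; it was built by aligning per-atom environments on a
corpus spanning the lead's edit neighborhood, small C/N/O molecules
and common drug scaffolds, and environments outside the table fall
back to the conventional novelty default of -4.  Because the pipeline
treats 1 as "easiest", raw scores are rescaled to [0,1] by
`(10 - raw)/9`; the lead scores 0.853 (raw 2.32).

**Affinity** is a docking-predicted binding free energy in kcal/mol
(more negative = stronger).  The engine sits behind an adapter
(prepare ligand, invoke, parse) with parsers for both the Vina-style
result table and AutoDock DLG records, a recorded-report mock engine
for offline work, and caching by canonical SMILES.  For testing and
the smoke study the package substitutes a **deterministic surrogate**:
per-element contributions (C -0.20, N -0.75, O -0.65 kcal/mol), a
-0.8 kcal/mol bonus per H-bond donor, and a +1.6 kcal/mol penalty per
heavy atom beyond 26.  The parameters were fixed once so that (a) the
lead scores about -8 kcal/mol, matching the modal affinity of the
optimized episodes, (b) polar enrichment is rewarded, giving greedy
search a usable gradient, and (c) the penalty exceeds any single-atom
gain past the pivot, bounding the achievable range near -14.  The
surrogate emulates the *shape* of a docking objective, not its
physics: passing the learning tests says the optimizer works, not that
the surrogate ranks molecules as a docking engine would.

## Screening and docking validation

Screening applies the selection thresholds SA >= 0.6, QED >= 0.7 and
affinity <= -10 kcal/mol, inclusive — inclusive because a reported
selected candidate sits exactly at QED 0.70.  Passing records keep
stable episode order and are deduplicated by canonical SMILES keeping
the best scalar reward.  The module also reports, for each threshold
separately, the fraction of episodes with better values (computed both
inclusively and strictly, since the convention behind the published
percentages is unstated), kernel densities of each reward (Gaussian
kernel, Silverman bandwidth, renormalized to integrate to one, with
modes reported; a degenerate all-equal input is reported as a point
mass), and Spearman trends of each reward against the episode index.

Docking validation re-docks passing candidates: the grid box is 80 x
60 x 60 points at 0.375 A spacing centered at (23.895, 49.094,
134.275) in the receptor frame — emitted field-exactly in the engine's
`npts`/`spacing`/`gridcenter` dialect — with 20 binding poses
requested, sorted by energy with report order preserved among ties.
Hydrogen bonds between the best pose and the receptor use a
donor-acceptor heavy-atom cutoff of 3.5 A, classed strong <= 2.5 A <
moderate <= 3.5 A (a 3.3 A contact is "moderate"), with a
donor-H-acceptor angle criterion (>= 120 degrees) applied when the
donor's hydrogens are present; receptor structures without hydrogens
are assessed by distance only.  Receptor nitrogens are treated as
donor-capable, oxygens as acceptors, side-chain hydroxyls as both.
The optimized organic molecule is docked as the free ligand; how the
original study parameterized the nickel-coordinated complexes for the
validation engine is not reproducible from its text, so a metal-aware
mode is deliberately out of scope.

## Determinism and numerical choices

* One master seed drives network initialization, action selection and
  replay sampling through R's RNG; with the surrogate oracle an entire
  run is bit-reproducible (two smoke runs write byte-identical CSVs).
* 3-D embedding had to be rebuilt for determinism: OpenBabel's 3-D
  builder and rotor search are time-seeded and give different
  coordinates on every invocation.  The package instead takes
  OpenBabel's (deterministic) 2-D layout, lifts it with a seeded
  out-of-plane jitter of up to 0.45 A, and relaxes with deterministic
  steepest-descent MMFF94 minimization (UFF fallback), hydrogens added
  geometrically — isolated atoms get template-placed hydrogens, since
  their directions are otherwise randomized.  Same molecule + same
  seed gives bitwise-identical coordinates; different seeds reach
  different torsional basins.
* All fingerprint/identity hashing is double-precision integer
  arithmetic modulo 25-bit primes (products stay far below 2^53), so
  keys and features are platform-stable.
* Candidate identity tie-breaks, fragment-keeping rules (largest
  fragment, lowest-original-index on ties) and pose ordering (stable
  sort) are all deterministic by construction.

## Problem sizes used by the packaged analyses

The `analysis/` scripts and the test suite run the smoke-scale
conditions: 200 episodes x 8 edits (~1600 enumerations of ~100
candidates), screening over the resulting log, and mock-engine docking
of the survivors.  The brute-force equivalence check enumerates the
complete closure of reachable molecules with up to 4 heavy atoms
(several hundred molecules, every one compared against an independent
enumerator) plus a seeded 120-molecule sample of the 5-heavy-atom
layer.  Study-scale runs (6000 episodes, 16 edits, in-loop docking)
use exactly the same entry points with the default `agent_config()`
and a docking-adapter reward function.

## What the synthetic fixtures do and do not show

The toy receptor is a programmatically generated three-residue
fragment (ARG-515, ASN-519, LYS-520 — the contact residues of the
docking analysis) with idealized side-chain geometry; probe poses are
placed at exact donor-acceptor distances by construction.  Passing the
contact tests demonstrates the geometry and classification logic, not
binding-site realism.  Likewise the mock engine replays recorded
report text through the production parsers: it validates the adapter
round trip, while real-engine energies remain engine- and
receptor-dependent.  The surrogate-driven learning results demonstrate
that the optimizer improves what it is rewarded for; with a real
docking oracle the reward landscape is rougher and noisier, and more
episodes (the study's 6000) are expected to be needed.

## Known limitations

* Generated edits are stereo-agnostic; input stereo descriptors are
  preserved in the cached canonical SMILES of parsed molecules but not
  through edits.
* The SA fragment table covers the lead's edit neighborhood and common
  scaffolds; far outside it, unseen environments take the -4 novelty
  default, biasing SA pessimistic (harder) relative to the full
  published catalog.
* QED rotatable bonds use the plain SMARTS definition rather than the
  strict amide-excluding variant; differences are small and within the
  validation tolerance.
* The docking adapter has no metal parameterization; complexes are
  docked as free organic ligands.
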