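---
title: "Enumerating and classifying elementary reaction spaces on CHON graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enumerating and classifying elementary reaction spaces on CHON graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxnspace)
```

## The model

`rxnspace` works on the bond-electron (BE) matrix picture of a molecule
(Dugundji–Ugi formalism): a symmetric integer matrix whose off-diagonal
entries are bond orders and whose diagonal holds lone (non-bonding)
electron counts. The package restricts itself to neutral closed-shell
molecules over C, H, O and N, for which the Lewis structure is fully
determined by the bond matrix: every atom sits at its fixed neutral valence
(H 1, O 2, N 3, C 4) and the lone-electron count is a function of the
element alone (O two pairs, N one, C and H none). Hydrogens are explicit
atoms, because an elementary step must be able to break bonds to hydrogen.

An elementary reaction step (ERS) is a rewrite of the BE matrix that breaks
`n` bond-order units and forms `m`, written *bnfm*. The workhorse is
**b2f2** — break two bonds, form two — the simplest ERS that produces
non-trivial products for closed-shell systems: for every pair of distinct
bonds (A,B) and (C,D), both rearrangements {(A,C),(B,D)} and {(A,D),(B,C)}
are attempted. Breaking decrements one unit of bond order (a double bond
breaks to a single bond); forming increments one unit, including between
already-bonded atoms, which is how π bonds form. A candidate survives if
the product is again a valid neutral closed-shell graph (all bond orders in
0–3, every atom at its fixed valence) and differs from the reactant. In the
general *bnfm* engine the formed bonds are pairings of the 2n endpoint
slots left by the broken units; for *bnf(n−1)* one pairing slot pair stays
open, which necessarily leaves two atoms under-coordinated, so on
fixed-valence CHON those families are enumerated but always filtered to the
empty set (a methane b2f1 candidate would be a carbene).

### Model reactions and graph depth

Exhaustive enumeration over a large compound library generates a reaction
space dominated by near-duplicates: the same local transformation embedded
in different molecular surroundings. The **graphically-defined model
reaction** collapses these: it is the smallest reaction with the same
number and type of bond changes as its parent, where bond types are made
unique out to a chosen graph **depth** from the reactive atoms (the atoms
incident to a broken or formed bond). At depth 1 — the convention behind
"reaction graph depth 1" (RGD1-style) datasets — the reactive atoms and
their immediate bonded neighbors are retained and every severed bond is
replaced by a cap hydrogen.

Two design choices make the truncation well-behaved:

* **Only single bonds are severed.** A neighbor attached to a retained atom
  through a bond of order ≥ 2 on either side of the reaction is itself
  retained, transitively. Every cap is then a 1-for-1 hydrogen replacement
  (bond order 1), so each retained atom keeps its exact coordination number
  — hybridization of the reaction center is preserved by construction. No
  rule for capping a lost multiple bond is ever needed.
* **Caps are truncated back to caps.** Re-running model generation at the
  same depth replaces a cap hydrogen by a cap hydrogen, so the operation is
  a fixed point (idempotent). The test suite checks idempotence,
  bond-change-type preservation and hybridization preservation on 1,000
  seeded random parents.

One documented consequence of the single-bond severing rule: a ring that
does not contain reactive atoms can be opened by truncation (both its
attachment bonds are severed independently). This mirrors the minimal-cap
philosophy; no ring-retention heuristic is applied.

### Canonicalization and deduplication

Uniqueness of molecules and reactions is decided by canonical hashing. A
molecule's hash is its canonical plain SMILES; the atom order underlying it
comes from a BLISS canonical permutation (via `igraph`) of an auxiliary
vertex-colored graph in which atoms are colored by element and each bond
contributes a subdivision vertex colored by bond order (BLISS has no edge
colors). A reaction hash is the two side strings — fragments sorted
lexicographically — joined in sorted order, so a reaction and its reverse
hash identically and enumeration counts each transformation once. The hash
is *species-level*: two reactions interconverting the same reactants and
products through different atom mappings collapse to one key. This matters
for identity reactions (below) and for symmetry-equivalent sites (all
abstractions of homotopic hydrogens count once).

Counts of "unique reactions for molecule X" are sensitive to exactly these
conventions (species-level vs mapping-level keys, treatment of identity
products, structural filters applied by a given pipeline). For
γ-ketohydroperoxide (`O=CCCOO`), the worked example throughout this
package, the convention above yields 38 unique b2f2 reactions; the naive
brute-force reference enumerator reproduces the same set independently,
while the tally quoted in the RGD1 dataset documentation for the same
molecule is 34. The four-reaction gap is consistent with an unstated
additional filter or dedup convention in the dataset's generating pipeline
and is surfaced, not hidden: the acceptance checks print the full
38-reaction list for audit.

### Aromatic input, kekulization and other numerical choices

* Aromatic SMILES input is kekulized to alternating integer orders before
  the graph is built (the BE matrix needs integers). Every aromatic atom
  one bond short of its valence must receive exactly one double bond; a
  deterministic backtracking matching over the aromatic bonds assigns them,
  with ties between kekulé forms broken by atom order. Pyrrole-type
  nitrogen must be written `[nH]`.
* Charged or radical species are rejected everywhere (`[N+](=O)[O-]`-style
  charge-separated nitro groups included); hypervalent kekulization is not
  attempted. This keeps the enumerator's valence filter exact.
* Enumeration output is sorted by reaction hash, so runs are reproducible
  without seeds; the only seeded components are the synthetic-data
  generators, which thread a single integer seed through every draw and
  restore the caller's RNG state.
* Degenerate inputs: a bond-less reactant enumerates to an empty list; a
  reaction with zero bond changes is rejected by the classifiers as
  degenerate (conformer pairs are not reactions).

## Reaction features

For the technical-validation style summaries the package computes, per
reaction: the *bnfm* signature (counted in bond-order units, so an
ethene-to-ethyne change counts one broken π unit); the molecularity class
*mrnp* (connected components per side, direction-normalized so n ≥ m, ties
keeping the given direction); the heavy-atom count; the reactive-atom
element census; and the bond-type change census with unordered element-pair
labels and bond orders pooled (C–H ≡ H–C, single/double/triple together).
All structural features are direction-invariant; only the
forward/backward labeling of energies is not.

**Identity reactions** — equal canonical species multisets on both sides
with nonzero bond changes, e.g. a symmetric double hydrogen transfer — are
flagged separately. Their reaction enthalpy is structurally zero, which
both makes them a stress test for ML featurizations and a distortion for
enthalpy regressions, so the Bell–Evans–Polanyi fit excludes them by
default (`exclude_identity = TRUE`). The BEP fit itself is ordinary least
squares of activation energy on reaction enthalpy over both directions,
i.e. points (ΔH, ΔE‡fwd) and (−ΔH, ΔE‡bwd); per-*bnfm* classes with fewer
than two members are reported with counts only.

## Dataset records and the energy ledger

The csv layout carries kcal/mol differences (`DE_F, DE_B, DG_F, DG_B, DH`),
the HDF5 layout absolute Hartree energies and Å geometries; nothing is
converted silently on read. The ledger is recomputed with
1 Hartree = 627.509474 kcal/mol, and `validate_records()` reports (never
mutates):

* anomalous barriers (ΔE‡ < 0 or > 500 kcal/mol, either direction) — the
  bounds used to weed out failed geometry optimizations;
* duplicate TS conformers: same model-reaction index `X` of `MR_X_Y` with
  forward and backward barriers equal within `1e-4` kcal/mol (both partners
  reported);
* stored-vs-recomputed drift beyond `0.01` kcal/mol (csv rounding scale);
* geometry row counts that disagree with the atom count of the parsed
  SMILES (the TS shares the reactant atom set).

HDF5 access goes through a bundled `python`/`h5py` helper with JSON
interchange; the grouped one-group-per-record layout is canonical and a
flat single-record layout is auto-detected as a fallback, with the detected
dialect reported.

## What the synthetic data does and does not emulate

`random_molecules()` draws connected valence-valid CHON molecules (random
heavy-atom tree, optional ring/unsaturation upgrades, hydrogen fill) — it
emulates the *combinatorial* population an enumeration pipeline sweeps, not
the empirical frequency profile of a curated compound library (no
functional-group priors, no synthesizability bias). `synthetic_dataset()`
produces records whose reaction SMILES are real depth-1 model reactions of
enumerated b2f2 steps and whose Hartree fields are drawn so that each
derived kcal/mol field reproduces exactly, with clean barriers confined to
(0, 200) kcal/mol — the observed order of magnitude in such datasets.
Energies are *self-consistent, not physical*: no correlation between
barrier and bond changes, thermal corrections drawn uniformly, geometries
placeholder chains with correct atom counts. A green validator and ledger
suite therefore demonstrates bookkeeping correctness, not chemical accuracy
of any quantity; conversely the planted-defect tests (anomalous barrier,
duplicate conformer, broken ledger) show the validator finds all and only
the corruptions it claims to find.

## Problem sizes used by the test suite

Chosen as the package's own trade-off between coverage and turnaround:
round-trip properties on 300 seeded random molecules (1–7 heavy atoms),
model-reaction contracts on 1,000 seeded random parents (3–6 heavy atoms),
oracle-equivalence of the optimized enumerator against the naive
brute-force reference on the complete exhaustive set of 571 CHON molecules
with ≤ 4 heavy atoms, hash-collision checks on the same exhaustive set, and
ledger properties on 1,000 synthetic records. The exhaustive enumerator
refuses bounds above 5 heavy atoms, where completeness stops being
affordable.

## Known limitations

* No stereochemistry, charges, radicals, or elements beyond C/H/O/N; no 3D
  embedding or kinetic plausibility screening.
* Kekulization handles the standard one-double-bond-per-atom aromatic
  systems; exotic aromatic valence states are rejected rather than guessed.
* The full published census scale (hundreds of thousands of model reactions
  from a curated compound library) is out of scope here; the classifiers
  accept the published csv, but classifying ~177k atom-mapped reactions in
  one R process is a long-running batch job.
* Unique-reaction counts are convention-dependent, as discussed above; the
  package's convention is stated, tested, and cross-checked against the
  independent brute-force reference enumerator rather than tuned to match
  any particular published tally.
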