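# rxnspace

Reaction-space enumeration and transition-state dataset tooling for neutral
closed-shell C/H/O/N chemistry.

Machine-learning models for activation energies and transition states (TS)
need large, chemically diverse reaction datasets. Such datasets are built by
*graph enumeration*: represent each molecule by its bond-electron (BE)
matrix — off-diagonal bond orders, lone electrons on the diagonal —
and exhaustively apply an elementary reaction step (ERS) **bnfm** that
breaks *n* bond-order units and forms *m*. The production rule for
closed-shell organics is **b2f2**: for every pair of distinct bonds (A,B)
and (C,D), try both rearrangements {(A,C),(B,D)} and {(A,D),(B,C)}, keep the
valence-valid non-null products. To tame the redundancy of the resulting
space, each reaction is reduced to its **graphically-defined model
reaction**: the smallest reaction with the same number and type of bond
changes, obtained by truncating the parent at graph depth 1 from the
reactive atoms and capping severed single bonds with hydrogens so the
reaction centers keep their hybridization. Depth-1 model reactions are the
organizing unit of public TS datasets in the RGD1 layout (csv of kcal/mol
activation energies/enthalpies plus HDF5 of Hartree energies and Å
geometries, records keyed `MR_<X>_<Y>`).

`rxnspace` implements, for this chemistry:

* a BE-matrix molecular graph with atom-mapped SMILES I/O (explicit
  hydrogens, kekulization of aromatic input, strict closed-shell valence),
* exhaustive `enumerate_b2f2()` / `enumerate_ers()` with canonical,
  direction-invariant deduplication (`canonical_hash()`, `reaction_hash()`),
* `model_reaction()` truncation at configurable depth plus
  `saturation_curve()` to watch a molecule stream exhaust the model-reaction
  space,
* reaction-feature classifiers: bnfm signatures, mrnp molecularity,
  reactive-atom/bond-type censuses, identity-reaction detection, ΔE‡
  summaries and Bell–Evans–Polanyi fits,
* dataset I/O and QC: `read_rgd1_csv()`, `read_rgd1_hdf5()` (via a bundled
  python/h5py bridge), `recompute_energies()` (627.509474 kcal/mol per
  Hartree), `validate_records()` (anomalous barriers, duplicate TS
  conformers, ledger drift, geometry mismatches), XYZ export,
* seeded synthetic data: random valence-valid molecules, an exhaustive
  ≤5-heavy-atom enumerator, a naive brute-force ERS oracle, and
  self-consistent synthetic csv/HDF5 records with optional planted defects.

See `vignettes/reaction-space.Rmd` for the methods account.

## Worked example

γ-ketohydroperoxide (3-hydroperoxypropanal, `O=CCCOO`) is the classic
desk-scale enumeration seed:

```r
library(rxnspace)

khp <- parse_smiles("O=CCCOO")
khp
#> molgraph: 12 atoms (6 heavy), 1 fragment
#>   C(CCOO)=O

rxns <- enumerate_b2f2(khp)
length(rxns)
#> [1] 38
head(names(rxns), 4)
#> [1] "[H][H].C(=CC=O)OO>>C(CCOO)=O"  "[H][H].C(=CCOO)=O>>C(CCOO)=O"
#> [3] "[H][H].C(C1COO1)=O>>C(CCOO)=O" "[H][H].C(CC1OO1)=O>>C(CCOO)=O"
```

Every candidate pair of bonds and both rearrangements were tried; the 38
survivors are valence-valid, non-null, and deduplicated by the
direction-invariant reaction hash (the names above). The retro-peroxidation
channel reduces to a bimolecular model reaction:

```r
m <- model_reaction(rxns[["C(=O)OO.C=C>>C(CCOO)=O"]], depth = 1)
m
#> model_reaction (depth 1): C(CCOO)=O >> C(=O)OO.C=C
#>   12 atoms, of which 1 cap hydrogen
```

Classifying the whole set:

```r
f <- classify_reactions(rxns)
table(f$bnfm)
#> b2f2
#>   38
table(sprintf("%dr%dp", f$m, f$n))
#> 1r1p 1r2p
#>   19   19
reactive_atom_census(rxns)
#>   element count  fraction
#> 1       C    72 0.4736842
#> 2       H    33 0.2171053
#> 3       O    47 0.3092105
```

Synthetic dataset records are ledger-exact by construction and the
validator confirms it:

```r
d <- synthetic_dataset(5, seed = 42)
nrow(validate_records(d$records))
#> [1] 0
round(recompute_energies(d$records[[1]])$derived, 4)
#>     DE_F     DE_B     DG_F     DG_B       DH
#> 100.2639 107.2344 130.3348 128.2186   9.4307
```

The numbers read as: a 100.3 kcal/mol forward and 107.2 kcal/mol backward
electronic barrier, the corresponding free-energy barriers, and a mildly
endothermic (+9.4 kcal/mol) reaction enthalpy — all recomputed from the
stored Hartree fields and agreeing with the stored kcal/mol columns to
better than 1e-6.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/rxnspace.R enumerate --smiles "O=CCCOO" --break 2 --form 2 --out reactions.smi
Rscript inst/cli/rxnspace.R validate --csv RGD1CHNO_smiles.csv --report qc.json
```

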