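Package: rxnspace
Title: Reaction-Space Enumeration and Transition-State Dataset Tools for
    CHON Chemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for exploring the elementary-reaction space of neutral
    closed-shell molecules containing carbon, hydrogen, oxygen and nitrogen.
    Provides a bond-electron-matrix molecular graph with atom-mapped SMILES
    input/output, exhaustive break-n/form-m elementary-reaction-step
    enumeration (break two bonds, form two bonds by default),
    graphically-defined model-reaction truncation at a configurable graph
    depth with hydrogen capping, canonical direction-invariant reaction
    deduplication, reaction-feature classifiers (bond-change signatures,
    reactant/product molecularity, reactive-atom and bond-type censuses,
    identity-reaction detection, activation-energy summaries with
    Bell-Evans-Polanyi fits), and readers, writers and validators for the
    csv/HDF5 layout used by depth-1 model-reaction transition-state datasets
    such as RGD1, including energy-ledger recomputation and anomaly filters.
    A seeded synthetic-data module generates valence-valid random molecules,
    exhaustive small-molecule sets and self-consistent synthetic dataset
    records for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: python3 with h5py (HDF5 reading/writing); OpenBabel
    (optional, cross-checks in the test suite)
Config/testthat/edition: 3
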