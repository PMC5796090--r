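Package: memtriage
Title: Structure, Conservation and Dynamics Based Triage of Membrane
    Protein Missense Variants
Version: 0.1.0
Authors@R: person("Maintainer", "memtriage", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Feature computation and classification pipeline for triaging
    missense variants in polytopic membrane enzymes, developed around the
    sterol reductase DHCR7 (deficient in Smith-Lemli-Opitz syndrome).
    Computes membrane-aware relative solvent accessibility (Shrake-Rupley
    sampling with a geometric membrane slab), per-position evolutionary
    conservation from a multiple sequence alignment, and a physicochemical
    property distance between amino-acid types; classifies unknown variants
    with k-nearest neighbours over those features. Post-processes molecular
    dynamics output: region-wise RMSF sums and a cumulative-RMSF
    pathogenicity discriminant, residue cross-correlation (DCCM) difference
    maps, and MM/PBSA binding free energy aggregation with the linear
    nonpolar SASA term. Ships a synthetic-data generator that emulates every
    input with known ground truth, plus variant-table curation utilities for
    ClinVar/ExAC-style tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
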