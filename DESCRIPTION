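Package: solvscreen
Title: Solvent-Contact Hydration Scoring and Solubility Screening of
    Designed Miniproteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a solvent-contact implicit-solvation model in
    which the hydration free energy of a protein is a sum of per-atom
    terms: each atom's atomic solvation parameter times its solvent-exposed
    volume, with burial computed from a Gaussian occupancy envelope over
    neighbouring atoms. Atomic parameter tables (S, Omax, V per atom type)
    are fitted to dipeptide hydration free-energy data with a real-coded
    genetic algorithm. Around the model the package provides the screening
    pipeline used in structure-based miniprotein design: PDB structure
    handling with point-mutation bookkeeping, rule-based protonation-state
    assignment from hydrogen-bonding geometry, a two-stage candidate screen
    (binding-score ranking then a hydration-energy solubility filter),
    sequence-composition solubility analytics, protein-protein interface
    contact enumeration, and generators for synthetic helix-bundle and
    dipeptide structures with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
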