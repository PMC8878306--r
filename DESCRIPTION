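Package: drsp
Title: Structure-Based Prediction of Drug-Resistance Mutations in Protein-Drug Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether a single amino acid variant (SAV) in a protein-drug
    complex confers drug resistance. Featurizes each variant from the complex
    structure (drug-residue interaction energies, weighted-contact-number
    microenvironment descriptors, B-factor, solvent accessibility, backbone
    hydrogen-bond energies, secondary structure) and from sequence conservation
    profiles (substitution-matrix scores, windowed Shannon entropy). Variants are
    routed by their minimum distance to the bound drug into binding-pocket
    (interior) and distal (exterior) strata; a genetic algorithm selects features
    per stratum using cross-validated support-vector-machine fitness, and the
    combined interior plus exterior radial-basis-kernel classifier predicts
    resistant versus non-resistant variants. Includes seeded synthetic generators
    for toy complexes, conservation profiles and planted-signal feature tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    e1071,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
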