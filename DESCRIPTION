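Package: surftopo
Title: Residue-Level Membrane-Protein Topology Evidence from Surface
    Biotinylation Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns cell-surface biotinylation mass-spectrometry search results
    into residue-level extracellular topology evidence for transmembrane
    proteins. Implements in-silico protease digestion (trypsin, chymotrypsin)
    with modified-lysine cleavage blocking, exact peptide-to-proteome mapping
    with modification-site localization, score and label-mass filtering,
    minimum-support site aggregation with control subtraction, condition-set
    comparison, validation against reference topology annotations, and export
    of extracellular constraints for topology predictors. A forward simulator
    of the partial surface pre-digestion and primary-amine labelling experiment
    provides ground-truth datasets so the whole pipeline is testable without
    real mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
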