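Package: tapms
Title: Bait-Control Filtering and Quantification for AP-MS Pulldown Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for tandem affinity purification mass
    spectrometry (AP-MS) screens that compare a bait pulldown against a
    mock control. Implements in-silico tryptic digestion with coordinate
    bookkeeping, weighted spectral counting normalised by the number of
    theoretically observable tryptic peptides, bait/control enrichment
    ratios, a three-stage contaminant exclusion cascade (low enrichment,
    known affinity-purification contaminants and their families, abundant
    tissue proteins and their paralogs), kinase annotation, MS1
    extracted-ion-chromatogram peak-area quantification with replicate
    t-tests, b/y fragment-ladder arithmetic with phospho neutral-loss
    site localisation, single-peptide spectrum quality control, a
    simplified target-decoy FDR, and a synthetic pulldown simulator so
    the whole workflow is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    pracma,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
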