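Package: matecalcium
Title: Ratiometric Calcium Imaging and Ethogram Analysis of C. elegans Male Mating
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantification pipeline for brain-wide calcium imaging of
    Caenorhabditis elegans males during mating with freely moving
    hermaphrodites. Extracts ratiometric (GCaMP/mNeptune) neural activity
    traces from tracked two-channel volumetric recordings, performs
    event-triggered response analysis with lagged cross-correlation against
    binarized behavioral motifs, screens recordings for spurious activation
    of the vulva-detecting circuit, and scores mating performance from
    behavioral ethograms. Ships a synthetic-data generator (semi-Markov
    ethograms, kernel-coupled neural traces, two-channel emissions with a
    shared multiplicative motion artifact, rendered volumes) with full
    ground truth, so the whole pipeline is testable without any recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    rhdf5
Config/testthat/edition: 3
RoxygenNote: 7.3.3
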