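Package: nterminomics
Title: Substrate Calling and Cleavage-Site Analytics for Mitochondrial
    N-Terminomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential N-terminomics analysis of quantified N-terminal
    peptide tables from wild-type versus peptidase-knockout mitochondria.
    Curates credible protein N-termini (localization, start-position and
    most-N-terminal rules), calls substrates of the intermediate cleaving
    peptidase ICP55 and the octapeptidyl aminopeptidase OCT1 from paired and
    single differential termini under N-end-rule stability criteria, detects
    sequential-cleavage ladders, builds iceLogo-style cleavage-site motif
    profiles with proportion-test significance and consensus strings, and
    computes targeting-presequence property statistics (length, net charge at
    a given pH, residue composition, cleavage-site prediction scoring). A
    seeded forward simulator of presequence processing cascades and noisy
    dimethyl-ratio observations provides ground truth for parameter-recovery
    testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
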