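Package: aftm
Title: Transmembrane Segment Annotation from Predicted Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curates transmembrane segment (TMS) annotations from predicted
    protein structural models and raw membrane-placement output. Implements
    recursive domain partitioning driven by predicted-aligned-error (PAE)
    matrices, geometric post-processing of membrane-embedded segments
    (re-entrant classification, same-orientation merging, missing-TMS
    recovery, full/domain combination), transfer of reference TMS annotations
    onto target proteins via alignment hits with single-linkage clustering and
    floored-median consensus, and multi-source annotation comparison
    statistics. Ships a seeded synthetic fixture generator (helical bundles,
    block PAE matrices, perturbed placements and annotation sets) so the whole
    pipeline is testable without external downloads, plus a command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
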