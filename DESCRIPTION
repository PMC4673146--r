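Package: crpcnet
Title: Kinome siRNA Screen Normalization, Prize-Collecting Steiner Forest
    Network Inference, and IHC Tissue-Microarray Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the computational chain used to nominate candidate
    kinases from an arrayed kinome-wide siRNA screen in androgen-deprived
    prostate cancer cells: robust per-plate Z-score normalization against
    non-targeting control siRNAs (median/MAD with the 1.4826 consistency
    factor), primary and confirmation hit calling, prize-collecting Steiner
    forest (PCSF) inference over a confidence-weighted protein interactome
    with screen Z-scores as node prizes, a randomization test for enrichment
    of a query node against size-matched random kinase sets, and aggregation
    plus single-linkage clustering (uncentered absolute correlation) of
    ordinal immunohistochemistry tissue-microarray scores. Ships synthetic
    data generators with planted ground truth so every stage is testable
    end to end, an exact brute-force PCSF oracle for small instances, and a
    seeded pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
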