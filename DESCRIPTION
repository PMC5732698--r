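Package: dragonet
Title: Differential Phospho-Signalling Pathway Analysis on Protein Networks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Calls regulated phosphosites from replicated isobaric-label
    (TMT) phosphopeptide quantitation tables, derives substrate and kinase
    seeds, expands them on a tissue-filtered human signalling network with
    an iterative connectivity-significance (DIAMOnD-style) module detector,
    performs hypergeometric pathway enrichment with Benjamini-Hochberg FDR
    control, and classifies pathways as condition-unique, shared, or
    differentially regulated between comparisons. Includes deterministic
    synthetic-data generators for every input so the whole protocol is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
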