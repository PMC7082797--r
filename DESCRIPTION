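Package: rflpkit
Title: In Silico PCR-RFLP Assay Design and Dichotomous Keys for Species
    Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and evaluating PCR restriction fragment
    length polymorphism (PCR-RFLP) assays for DNA-barcode species
    identification, motivated by the discrimination of Haemaphysalis ticks
    with mitochondrial 16S rRNA and COI markers. Locates degenerate IUPAC
    primer binding sites and extracts amplicons in silico, simulates
    restriction digestion into fragment-length patterns, models agarose gel
    visibility and band co-migration, groups band patterns per species,
    ranks candidate restriction enzymes by discriminatory power, and
    builds, serializes and applies dichotomous fragment-size identification
    keys, shipping a built-in key to the Haemaphysalis species of North
    America. A synthetic amplicon simulator with planted primer-binding
    regions and recognition sites provides ground-truth data for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
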