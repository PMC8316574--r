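Package: phosprio
Title: Prioritization of Functionally Important Phosphosites from
    Quantitative Phosphoproteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for prioritizing functionally important phosphorylation
    sites from stable-isotope (15N) quantitative phosphoproteomics. Provides
    a robust differential-phosphorylation caller for replicate isotope-ratio
    data (normalized-interquartile flexible filter with exact or corrected
    Wilcoxon rank-sum tests), a six-feature logistic-regression functional
    scorer with fence-based score normalization and top-fraction
    prioritization, residue conservation scoring on ortholog alignments and
    species phylogenies, kinase-substrate and pathway enrichment statistics
    (hypergeometric E-ratio tests), and a seeded synthetic-data generator so
    that every stage of the workflow can be exercised with known ground
    truth. Stages compose into a file-based pipeline with a deterministic
    run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
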