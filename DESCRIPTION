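Package: goosemir
Title: Small RNA-Seq miRNA Profiling for Two-Library Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of two-library small RNA sequencing
    experiments of the kind used to profile ovarian miRNAs in laying versus
    broody geese: adapter/junk read cleaning, collapsing to unique tags,
    priority-rule annotation, known-miRNA quantification, novel miRNA
    discovery by stem-loop hairpin folding with seven structural criteria,
    two-library differential expression with the Audic-Claverie exact count
    statistic, plant-style miRNA target prediction with mismatch and
    minimum-free-energy-ratio rules, and hypergeometric GO/KEGG term
    enrichment. Includes a fully seeded synthetic-data generator that plants
    known miRNAs, hairpin precursors and target sites with complete ground
    truth, so every stage of the pipeline can be verified against a ledger.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
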