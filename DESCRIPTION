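Package: rerrs
Title: Restriction Enzyme Reduced-Representation Sequencing Metagenome Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling microbial communities from restriction enzyme
    reduced-representation sequencing (RE-RRS, the GBS library design applied to
    metagenomes). Implements in-silico restriction digestion with fragment size
    selection, demultiplexing of inline-barcoded single-end reads, adapter and
    quality trimming with sample-level QC, a reference-free cut-site tag
    profiling pipeline with prevalence filtering, MEGAN-style
    lowest-common-ancestor taxonomic assignment from alignment hit tables,
    log10-proportion profile matrices with equal-weight principal component
    analysis, microbial relationship matrices, REML variance-component
    estimation (repeatability, phenotypic correlation with a trait,
    microbiability), a compression-efficiency sequencing-depth sensitivity
    analysis, and a synthetic community and read simulator so the whole system
    can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
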