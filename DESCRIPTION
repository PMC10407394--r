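Package: ighvclones
Title: Single-Cell IGHV Repertoire Annotation, Mutation Profiling and
    Clone Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for single-cell immunoglobulin
    heavy-chain (IGH) variable-region analysis: loading IMGT-style
    germline V/D/J references, assigning germline genes to rearranged
    sequences by local alignment, extracting the CDR3/junction,
    classifying productivity, counting somatic hypermutations against
    the assigned germline V gene, grouping cells into clones by shared
    V gene and near-identical CDR3 (complete linkage), flagging
    intraclonal diversity, and producing per-sample summary tables.
    Includes a seeded V(D)J recombination and somatic-hypermutation
    simulator that emits repertoires with full ground truth, so every
    stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
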