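Package: medipcpg
Title: Single-CpG Read Allocation and Differential Methylation for MeDIP-seq
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Allocates ambiguously mapped MeDIP-seq reads to individual CpG
    sites with two EM algorithms -- a single-contributor multinomial model and
    an at-least-one-contributor truncated-Bernoulli model -- and detects
    differentially methylated single CpG sites between two samples with an
    exact conditional test and Benjamini-Hochberg adjustment. Includes CpG
    site discovery from a reference sequence, region segmentation, coverage
    matrix construction from mapped reads (BED), MRE-seq site counting, and a
    generative simulator of the immunoprecipitation process for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    optparse,
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
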