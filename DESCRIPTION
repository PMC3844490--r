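Package: muHEM
Title: Rough-Hypercuboid Feature Selection for Labelled Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Selects differentially expressed markers (e.g. miRNAs) from a
    labelled expression matrix using rough-hypercuboid equivalence partition
    matrices. Provides the hypercuboid algebra (class value intervals,
    partition matrices, confusion vectors, lower and upper approximations),
    dependency (relevance) and significance measures, a greedy
    relevance-significance selector with a tunable weight parameter chosen by
    a coefficient-of-variation index, a B.632+ bootstrap evaluation harness
    around a pluggable classifier, a seeded synthetic-data generator, and
    TSV/GEO series-matrix readers with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
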