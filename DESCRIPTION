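Package: mirrormeth
Title: Simulation and Analysis of Mirror-Image MCIp Microarray Methylation
    Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and analyses methyl-CpG immunoprecipitation (MCIp)
    experiments for detecting active DNA demethylation in post-mitotic
    cell differentiation. Provides a seeded synthetic-genome and
    methylome generator with planted differentially methylated regions
    (DMRs), a salt-fractionation model that partitions sonicated
    fragments into unmethylated (CpG) and methylated (mCpG) pools, a
    dual reciprocal two-channel promoter-array simulator with the
    mirror-image subtracted log10-ratio DMR statistic, an in-silico
    EpiTYPER (MassCLEAVE) bisulfite mass-spectrometry validation
    workflow with per-CpG-unit quantification, and downstream reporting:
    demethylation-kinetics classification, Mann-Whitney association of
    expression change with local CpG/GC content, and ChIP-qPCR
    percent-input normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), knitr, rmarkdown, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
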