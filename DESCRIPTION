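Package: xescape
Title: Detection of Escape from X-Chromosome Inactivation from TSS-Level
    Expression, DNA Methylation and Allelic Binding Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for identifying transcription start sites (TSSs) that
    escape X-chromosome inactivation and for characterising their regulation.
    Provides a Random-Forest sex classifier over X-linked TSS expression with
    out-of-bag outlier detection and proximity embedding; covariate-adjusted
    per-TSS differential-transcription tests calling escapee TSSs; a
    DNA-methylation sex-similarity score from Tukey-bisquare robust regression
    of M on A; motif and ChIP-seq peak over-representation tests with
    GC/length- and expression-matched backgrounds; and a phased allelic
    ChIP-seq imbalance analysis over an IUPAC personalised genome with a
    simulated-read mapability filter. Synthetic-data generators emulate the
    statistical structure of each input so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
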