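Package: ldtnet
Title: Isoform-Specific Co-Expression Networks via a Large-Dimensional
    Trace Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers splicing-isoform-specific co-expression networks from
    exon-level RNA-Seq expression tables. Each isoform is represented as a
    corrected exon-by-sample expression matrix, where exons shared by
    several isoforms are rescaled by the relative abundance of the owning
    isoform in each sample. Pairwise dependence between isoforms is tested
    with a large-dimensional trace statistic whose asymptotic normal null
    remains valid when the number of exons is comparable to the number of
    samples. Networks inferred from matched normal and disease samples can
    be compared to obtain differential (lost/gained) co-expression edges.
    A Monte-Carlo simulation harness evaluates power, type-I error and
    F-score over configurable designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
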