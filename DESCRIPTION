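Package: stressmem
Title: Transcriptional Memory Classification Under Repeated Dehydration Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies genes by their transcriptional responses to repeated
    dehydration stress cycles (watered, first stress S1, third stress S3) into
    memory, non-memory and late-response categories using three significance
    criteria (FDR-adjusted q-value, absolute log2 fold change, and an
    expression-percentile floor). Includes readers and writers for cuffdiff-style
    differential-expression tables, BLAST tabular homology hits and GO
    annotation files; a best-e-value-window annotation-transfer algorithm with
    longest-common-substring description synthesis and top-10 GO term
    aggregation; functional-category count/percentage matrices with capped
    heatmap intensity scaling; cross-species memory-conservation comparison of
    homolog response classes; leaf relative-water-content and replicate-quality
    utilities; and a synthetic-data generator with planted ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
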