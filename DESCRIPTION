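Package: glycoatlas
Title: Quantitative MALDI-TOF N-Glycome Atlas Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for building and analysing quantitative N-glycome
    atlases from MALDI-TOF peak lists: monosaccharide-composition mass
    calculus with glycoblotting derivatization chemistry, GlycoMod-style
    composition assignment, internal-standard absolute quantitation with a
    minimum-detection filter, biosynthesis-based glycotyping summaries,
    Canberra/Ward profile clustering, and repeated stratified-holdout
    multi-class classification with per-class F1 reporting. Includes a
    synthetic atlas generator emulating organ/tissue class structure,
    replicate noise and detection dropout so every stage is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    rpart,
    nnet,
    randomForest,
    kernlab
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    pheatmap
Config/testthat/edition: 3
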