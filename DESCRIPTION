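Package: chromapick
Title: Representative Chromatin-Mark Selection and Combinatorial
    Promoter-Pattern Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selects a representative subset of chromatin modifications by
    sparse self-representation of genome-wide signal profiles, identifies
    recurrent combinatorial patterns of the selected marks at promoters by
    K-means clustering of concatenated profiles, and scans the genome in
    sliding windows on both strands for novel promoter-like loci whose
    per-mark profiles all correlate with an active-promoter pattern.
    Includes a fully specified synthetic-data generator with planted
    linear-subspace mark structure, promoter shape classes and hidden
    promoter loci, so every pipeline stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml,
    cluster,
    mclust
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
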