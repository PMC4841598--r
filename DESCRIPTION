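Package: ripenet
Title: Exact Poisson Differential Expression and Weighted Coexpression
    Networks for Two-Genotype Fruit-Ripening Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for replicate-free RNA-seq comparisons of a
    late-ripening citrus mutant against its wild type across fruit ripening
    stages.  Implements RPKM normalization, the exact Poisson test for
    differential expression between two count libraries, transcription-factor
    family assignment from DNA-binding-domain hits, unsigned weighted gene
    coexpression network construction with topological overlap, simplified
    tree-cut module detection with eigengene merging, permutation validation
    of modules, module-trait and module-TF correlation, hub-gene screening,
    Venn set partitioning, Eisen-style fold-change profile clustering,
    hypergeometric term enrichment, and a seeded synthetic-data generator
    that plants differential expression, coexpression modules, trait links
    and domain hits for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
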