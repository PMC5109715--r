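Package: tfregclass
Title: Classification of Transcription Factors into Chromatin-Opening
    Regulatory Classes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies human transcription factors into hypothetical
    regulatory-function classes (Pioneer, Settler, positive and negative
    Migrant) from binary feature vectors derived from structural and
    annotation properties (TFClass hierarchy, Pfam domains, DNA-binding
    domain counts, protein-protein interactions, post-translational
    modifications, zinc-finger content). Implements balanced one-vs-rest
    ensembles over random under-sampling splits, bootstrap cross-validation
    with forward best-first feature-set search and Wilcoxon comparison,
    Fisher exact enrichment and depletion statistics on TF properties,
    TF-TF interaction pairs and time-course gene sets, GC content and
    information content of binding-site motifs, and a synthetic-data
    generator with planted class-conditional structure for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    e1071,
    class
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
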