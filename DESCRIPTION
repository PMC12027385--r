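Package: cenet
Title: Extracellular-Vesicle-Informed Competing Endogenous RNA Networks
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds polarity-consistent competing endogenous RNA networks
    (ceNETs) from differential-expression tables of miRNA cargo in
    extracellular vesicles and matched tissue. Selects miRNAs dysregulated
    in the same direction in both compartments, expands them over
    CLIP-seq-supported miRNA-target interaction tables spanning mRNA,
    lncRNA and circRNA, filters interactions under the ceRNA-hypothesis
    polarity rule, exports Cytoscape-compatible networks (SIF, GraphML,
    TSV), and performs local hypergeometric over-representation analysis
    with Benjamini-Hochberg correction, strength filtering and
    similarity-based term grouping. Includes a parameterised synthetic-data
    generator with planted structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: NetworkInference, GeneRegulation, miRNA, GeneSetEnrichment,
    Software
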