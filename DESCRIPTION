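Package: GOcategorize
Title: Gene Categorization and Enrichment Analysis via Information-Content
    Semantic Similarity on the Gene Ontology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assigns genes to user-defined biological categories by a
    specialized information-content based semantic similarity over the Gene
    Ontology directed acyclic graph, and tests category enrichment with a
    degree-preserving randomization null model. Provides an OBO parser, GAF
    and TSV annotation readers, true-path count propagation and information
    content computation, category-label propagation and per-gene assignment,
    randomization z-score enrichment, multi-label accuracy and Matthews
    correlation evaluation, synthetic ontology and annotation generators, and
    a command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'ontology.R'
    'annotations.R'
    'ic.R'
    'semsim.R'
    'categorize.R'
    'enrichment.R'
    'evaluation.R'
    'fixtures.R'
    'cli.R'
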