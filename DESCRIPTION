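Package: ontoloop
Title: Iterative Discovery of Ontology Term Classes by Keywords and
    Co-Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semi-automated discovery of all ontology terms sharing a
    target property (for example lipid-relatedness in the Gene Ontology).
    Terms are represented by binary keyword features extracted from term
    names and definitions together with co-annotation scores derived from
    gene-product annotation profiles; a linear-kernel support vector
    machine ranks uncurated terms, and an iterative predict-curate loop
    amplifies each human curation decision through the is-a inheritance
    constraint of the ontology DAG. Includes OBO and GAF readers, strict
    transitive-closure queries, constraint checking and propagation,
    label mapping across ontology versions, curation-efficiency and
    recall/precision evaluation, rank-shift analysis, and a synthetic
    ontology/annotation generator so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    igraph,
    e1071,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
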