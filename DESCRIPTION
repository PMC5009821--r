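Package: goSimNet
Title: Gene Ontology Semantic Similarity and Functional Association
    Networks
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes gene functional similarity from Gene Ontology
    annotations using seven seed measures (Resnik, Schlicker, Wang,
    HRSS, simUI, simGIC, term overlap) and an integrative measure that
    ranks the seed measures, selects the concordant ones per gene pair,
    and combines them with weights learned by simulated annealing on
    Enzyme Commission grouped training genes. Parses OBO ontologies and
    GAF 2.x annotation files, applies true-path-rule propagation and
    information-content calculation, and builds thresholded gene
    functional-association networks exportable as edge lists, GraphML
    and Cytoscape JSON. Includes deterministic synthetic-fixture
    generators (toy ontology, random DAGs, EC-grouped corpora) so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    graphics,
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: GO, Annotation, Network, GraphAndNetwork, Software
RoxygenNote: 7.3.3
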