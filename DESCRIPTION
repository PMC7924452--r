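Package: repurpose
Title: Similarity-Fusion Drug Repurposing with FAIR Workflow Provenance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-disease associations by fusing five drug-drug and
    two disease-disease similarity measures (chemical fingerprints, shared
    side effects, target sequence alignment, Gene Ontology-style semantic
    similarity, protein-interaction network closeness, disease description
    cosine, phenotype-ontology semantic similarity) into ten features per
    candidate pair via a weighted geometric mean over known associations,
    scored with L2-regularised logistic regression under drug-wise and
    pair-wise 10-fold cross-validation with negative sampling. Ships a
    synthetic knowledge-base generator with planted cluster signal for
    desk-scale evaluation, and a unified workflow-provenance model
    (prospective plans, retrospective execution traces, version links)
    emitted as Turtle RDF together with a competency-question query suite
    and version diffing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    glmnet,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
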