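Package: semsum
Title: Disease Knowledge Summarization from Semantic Predications
Version: 0.1.0
Authors@R:
    person("semsum", "maintainers", email = "semsum@example.org", role = c("aut", "cre"))
Description: Summarizes disease-related knowledge from collections of
    subject-predicate-object semantic predications (SemRep fielded output
    or simplified triple tables). Scores (semantic type, predicate)
    categories for a seed disease topic by the product of per-predicate
    Kullback-Leibler divergence salience and type-predicate mutual
    information (the KM score), extracts ranked topic-associated entities,
    enumerates indirect (hidden) relations by bounded depth-first search
    over a bipartite entity/predicate graph with inverse-document-frequency
    filtering of generalist entities, and filters weak relations with a
    random walk with restart. Includes ranked-retrieval evaluation
    (precision, recall, F, P@N, R@N, average precision), a synthetic
    predication-corpus generator with planted ground truth, and a
    command-line pipeline front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
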