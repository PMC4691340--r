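Package: ppiscore
Title: Reliability Scoring for Physical Protein-Protein Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates physical protein-protein interaction records from
    heterogeneous sources (PSI-MITAB 2.5/2.7 and a compact PSI-MI XML 2.5
    dialect) into a deduplicated set of binary interactions, expanding
    co-purified complexes with the spoke model and filtering non-physical,
    cross-species and non-protein records. Each interaction receives three
    reliability scores: a method-based score built from detection-method,
    interaction-type and publication evidence in the style of the PSI-MI
    community MIScore heuristic; an annotation-based score combining
    interacting Pfam domain pairs, shared Gene Ontology terms and homologous
    interactions through naive-Bayes likelihood ratios; and their geometric
    mean as a combined confidence score. Includes gold-standard construction
    from experiment scale and cellular compartments, ROC/AUC evaluation, and
    a seeded synthetic-corpus generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
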