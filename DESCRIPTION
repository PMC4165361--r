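Package: phenosim
Title: Phenotypic Drug-Disease Similarity Networks from Side Effects and Symptoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Scores drug-disease pairs by weighted best-match semantic
    similarity between drug side-effect profiles and disease symptom
    profiles over a phenotype ontology, using a hyponym-count information
    content and frequency/co-occurrence term weights. Benchmarks the
    ranked pairs against molecular (protein-interaction shortest-path)
    and clinical (indication, contraindication, clinical-trial,
    adverse-reaction) relationships with lift curves, selects a network
    threshold by Pareto optimization, detects communities by multi-level
    modularity optimization, tests disease- and drug-class enrichment
    with Fisher's exact test and Benjamini-Hochberg correction, and
    proposes candidate contraindications. Includes a synthetic-data
    generator that emulates the ontology, annotation, interaction-network
    and clinical-label structure the analysis assumes, so the whole
    pipeline is testable without licensed vocabularies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    withr,
    igraph,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
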