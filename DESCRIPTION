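Package: constellatr
Title: Multi-Level Perturbation Proteomics Partitioning, PPI-Hub Enrichment
    and Latent Semantic Gene-Concept Interrogation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing stepwise ("constellation") perturbation
    proteomics and receptor interactome data. Provides significance filtering
    and multi-set Venn partitioning of per-level protein quantification
    tables; exact hypergeometric protein-protein-interaction hub enrichment
    with a hybrid score (overlap count times -log10 enrichment probability)
    and its per-level aggregation; comparative interactome overlap analysis
    judged against size-matched random null sets with empirical p-values;
    a latent-semantic-indexing engine (log-entropy weighted term-gene matrix,
    truncated SVD, cosine interrogation with explicit/implicit association
    thresholds); and disease-continuum construction with therapeutic
    interrogator percentile ranking. Seeded synthetic-data generators
    emulate the statistical structure of every input so the whole pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'io.R'
    'synthetic.R'
    'partition.R'
    'enrichment.R'
    'overlap.R'
    'lsi.R'
    'ranking.R'
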