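Package: toxcourse
Title: Toxic Course Knowledge Graphs and Qualitative Imbalance Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An embedded engine for ontology-based representation of
    drug-induced toxic courses, modelled on the ToXic Process Ontology
    (TXPO) style of knowledge organization. Provides a typed in-memory
    knowledge base of continuants and occurrents with is-a, part-whole,
    causal (has-result), localization (occurs-in) and role relations;
    Turtle and RDF/XML import/export with OBO-style CURIE/PURL mapping;
    materialization of toxic courses as causal graphs with parent-to-child
    process inheritance and term-substitution specialization; upstream and
    downstream route search with cross-course comparison; functional
    decomposition trees with bottom-up dysfunction propagation; merged
    general course maps with common-process detection and is-a cause
    generalization; and a qualitative five-level supply-demand imbalance
    evaluator distinguishing balanced, latent and imbalanced states.
    Ships deterministic fixtures encoding the published phospholipidosis,
    sphingomyelin disorder, Niemann-Pick type A, NASH, cholestasis and
    ground-glass-appearance course fragments, plus random knowledge-base
    generators for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
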