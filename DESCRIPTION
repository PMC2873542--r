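Package: goalkit
Title: Over-Representation Analysis of Gene Groups with Configurable
    Gene Ontology Search Strategies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Functional characterization of gene groups by
    over-representation analysis against a reference gene list. Tests
    Gene Ontology terms (with three distinct strategies for walking the
    GO directed acyclic graph: bounded backtracking from a gene's most
    specific terms, full upward propagation cut at a minimum depth from
    the root, and their combination), transcription-factor target sets
    supplied as binary gene-by-TF matrices, and pathway gene sets.
    Significance is assessed with the one-tailed hypergeometric test
    (equivalently, one-sided Fisher's exact test for over-representation)
    with Bonferroni, Holm step-down, or Benjamini-Hochberg correction.
    Includes parsers for OBO ontologies, GAF annotation files,
    tab-delimited TF matrices and pathway maps, a synthetic-fixture
    generator with planted enrichment for validation, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
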