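# Shared in-code fixtures and independent brute-force oracles.

obo_file <- function(stanza_lines, header = "format-version: 1.2") {
  path <- tempfile(fileext = ".obo")
  writeLines(c(header, "", stanza_lines), path)
  path
}

term_stanza <- function(id, name = id, ns = "biological_process",
                        is_a = character(0), part_of = character(0),
                        alt_id = character(0), obsolete = FALSE) {
  c("[Term]", paste0("id: ", id), paste0("name: ", name),
    paste0("namespace: ", ns),
    if (length(is_a)) paste0("is_a: ", is_a, " ! parent"),
    if (length(alt_id)) paste0("alt_id: ", alt_id),
    if (length(part_of)) paste0("relationship: part_of ", part_of),
    if (obsolete) "is_obsolete: true",
    "")
}

# linear chain: ROOT <- A <- B
chain_dag <- function() {
  parse_obo(obo_file(c(
    term_stanza("GO:0000001", "root"),
    term_stanza("GO:0000002", "A", is_a = "GO:0000001"),
    term_stanza("GO:0000003", "B", is_a = "GO:0000002"))))
}

# diamond: ROOT; A is_a ROOT; B is_a ROOT; C is_a A and is_a B
diamond_dag <- function() {
  parse_obo(obo_file(c(
    term_stanza("GO:0000001", "root"),
    term_stanza("GO:0000002", "A", is_a = "GO:0000001"),
    term_stanza("GO:0000003", "B", is_a = "GO:0000001"),
    term_stanza("GO:0000004", "C", is_a = c("GO:0000002", "GO:0000003")))))
}

gaf_row <- function(gene, term, qualifier = "involved_in", evidence = "IEA",
                    symbol = gene, aspect = "P") {
  paste("SYN", gene, symbol, qualifier, term, "SYN:ref", evidence, "",
        aspect, "", "", "gene", "taxon:0", "20260101", "SYN", "", "",
        sep = "\t")
}

gaf_file <- function(rows) {
  path <- tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.2", rows), path)
  path
}

annotation_set_from <- function(gene_to_terms) {
  path <- gaf_file(unlist(lapply(names(gene_to_terms), function(g)
    vapply(gene_to_terms[[g]], function(t) gaf_row(g, t), character(1)))))
  path
}

# --- independent oracles (no shared code with the implementation) ---

# all terms on some parental path of length <= k, by explicit path enumeration
oracle_ancestors_within <- function(dag, term, k) {
  found <- character(0)
  walk <- function(node, steps_left) {
    found <<- union(found, node)
    if (steps_left > 0)
      for (p in dag$parents[[node]]) walk(p, steps_left - 1)
  }
  walk(term, k)
  found
}

# shortest path length to a parentless term, by exhaustive path enumeration
oracle_min_depth <- function(dag, term) {
  best <- Inf
  walk <- function(node, len) {
    ps <- dag$parents[[node]]
    if (length(ps) == 0) best <<- min(best, len)
    else for (p in ps) walk(p, len + 1)
  }
  walk(term, 0)
  best
}

# term -> gene sets by looping over every (gene, direct term, ancestor) triple
oracle_strategy <- function(ann, dag, strategy, k = 0, L = 0) {
  n_terms <- length(dag$ids)
  sets <- list()
  for (g in names(ann$gene_to_terms)) {
    for (s in ann$gene_to_terms[[g]]) {
      reach <- switch(strategy,
        I = oracle_ancestors_within(dag, s, k),
        II = oracle_ancestors_within(dag, s, n_terms),
        III = oracle_ancestors_within(dag, s, k))
      for (t in reach) sets[[t]] <- union(sets[[t]], g)
    }
  }
  if (strategy %in% c("II", "III"))
    sets <- sets[vapply(names(sets), function(t)
      oracle_min_depth(dag, t) >= L, logical(1))]
  lapply(sets[order(names(sets))], sort)
}

# random layered fixture small enough for the path-enumeration oracles
small_random_fixture <- function(seed, n_layers = 5, terms_per_layer = 12,
                                 n_genes = 50) {
  spec <- fixture_spec(n_layers = n_layers, terms_per_layer = terms_per_layer,
                       n_genes = n_genes, annotations_per_gene = c(1, 2),
                       input_size = 10, seed = seed)
  dag <- make_dag(spec)
  ann <- make_annotations(dag, spec)
  list(spec = spec, dag = dag, ann = ann)
}

expect_same_sets <- function(got, want) {
  expect_setequal(names(got), names(want))
  for (t in names(want)) expect_setequal(got[[t]], want[[t]])
}
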