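# Synthetic ontologies, annotations and gene lists with planted enrichment.
# All generators are pure functions of (spec, seed): RNG state is scoped
# locally and restored on exit, so no global state leaks.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification for a synthetic fixture bundle
#'
#' Describes a layered random ontology, random gene annotations over it, and
#' an input gene list with a planted enriched term.  The defaults describe
#' the validation conditions used throughout the package's own tests: a
#' 4-layer ontology of 18 non-root terms, a 200-gene annotated universe with
#' 1-3 direct annotations per gene, and a 20-gene input list of which 80%
#' is drawn from the planted term's gene pool.
#'
#' @param n_layers Number of layers including the root layer (>= 1).
#' @param terms_per_layer Terms in each non-root layer.
#' @param parents_per_term Length-2 integer range: parents drawn per term
#'   from the layer above.
#' @param n_genes Size of the annotated gene universe.
#' @param annotations_per_gene Length-2 integer range of direct annotations
#'   per gene.
#' @param input_size Size of the generated input gene list.
#' @param planted_term Term id to plant enrichment at; `NULL` picks the
#'   deepest-layer term with the largest annotated gene pool.
#' @param planted_fraction Fraction of the input list drawn from the planted
#'   term's gene pool, in `[0, 1]`.
#' @param seed Integer seed; every generator derives its stream from it.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_layers = 4, terms_per_layer = 6,
                         parents_per_term = c(1, 2), n_genes = 200,
                         annotations_per_gene = c(1, 3), input_size = 20,
                         planted_term = NULL, planted_fraction = 0.8,
                         seed = 1) {
  stopifnot(n_layers >= 1, terms_per_layer >= 1, n_genes >= 1,
            length(parents_per_term) == 2, all(parents_per_term >= 1),
            parents_per_term[1] <= parents_per_term[2],
            length(annotations_per_gene) == 2, all(annotations_per_gene >= 1),
            annotations_per_gene[1] <= annotations_per_gene[2],
            input_size >= 1, planted_fraction >= 0, planted_fraction <= 1)
  structure(list(
    n_layers = as.integer(n_layers),
    terms_per_layer = as.integer(terms_per_layer),
    parents_per_term = as.integer(parents_per_term),
    n_genes = as.integer(n_genes),
    annotations_per_gene = as.integer(annotations_per_gene),
    input_size = as.integer(input_size),
    planted_term = planted_term,
    planted_fraction = planted_fraction,
    seed = as.integer(seed)
  ), class = "fixture_spec")
}

syn_id <- function(i) sprintf("SYN:%07d", i)

# uniform draw from an inclusive integer range; avoids the sample() scalar trap
sample_int_range <- function(range) {
  if (range[1] == range[2]) return(range[1])
  sample(seq(range[1], range[2]), 1)
}

#' Generate a layered random ontology DAG
#'
#' Builds a single-namespace ontology with one root; each term in layer
#' `i > 0` draws its `is_a` parents uniformly from layer `i - 1`, which
#' guarantees acyclicity and root reachability by construction.  The result
#' is produced by serializing the layered structure to OBO text and parsing
#' it with [parse_obo()], so generated DAGs always satisfy the parser's
#' validity checks.  Deterministic given `spec$seed`.
#'
#' @param spec A `fixture_spec`.
#' @return An `ontology_dag`.
#' @export
make_dag <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  lines <- with_seed(spec$seed, {
    out <- c("format-version: 1.2", "")
    root <- syn_id(1)
    out <- c(out, "[Term]", paste0("id: ", root),
             "name: synthetic root", "namespace: biological_process", "")
    counter <- 1L
    prev_layer <- root
    if (spec$n_layers > 1) for (layer in seq_len(spec$n_layers - 1)) {
      this_layer <- character(spec$terms_per_layer)
      for (t in seq_len(spec$terms_per_layer)) {
        counter <- counter + 1L
        id <- syn_id(counter)
        this_layer[t] <- id
        np <- min(sample_int_range(spec$parents_per_term), length(prev_layer))
        parents <- sample(prev_layer, np)
        out <- c(out, "[Term]", paste0("id: ", id),
                 paste0("name: synthetic term L", layer, ".", t),
                 "namespace: biological_process",
                 paste0("is_a: ", parents), "")
      }
      prev_layer <- this_layer
    }
    out
  })
  con <- textConnection(lines)
  on.exit(close(con), add = TRUE)
  parse_obo(con)
}

#' Generate random gene annotations over a synthetic DAG
#'
#' Annotates each of `spec$n_genes` synthetic genes (ids `G0001`, ...) to a
#' uniform random sample of non-root, non-obsolete terms; the number of
#' direct annotations per gene is uniform on `spec$annotations_per_gene`.
#' Deterministic given `spec$seed`.
#'
#' @param dag An `ontology_dag`.
#' @param spec A `fixture_spec`.
#' @return An `annotation_set` whose universe has `spec$n_genes` genes.
#' @export
make_annotations <- function(dag, spec) {
  stopifnot(inherits(dag, "ontology_dag"), inherits(spec, "fixture_spec"))
  candidates <- dag$ids[!dag$obsolete & !(dag$ids %in% dag$roots)]
  if (length(candidates) == 0L)
    stop("ontology has no non-root terms to annotate genes to")
  with_seed(spec$seed + 1L, {
    genes <- sprintf("G%04d", seq_len(spec$n_genes))
    gene_to_terms <- lapply(genes, function(g) {
      sz <- sample_int_range(spec$annotations_per_gene)
      sort(sample(candidates, min(sz, length(candidates))))
    })
    names(gene_to_terms) <- genes
    new_annotation_set(gene_to_terms)
  })
}

# Genes annotated at-or-below a term: any direct annotation whose full
# ancestor closure contains the term.
genes_at_or_below <- function(ann, dag, term) {
  term <- resolve_term(dag, term)
  hit <- vapply(ann$gene_to_terms, function(ts)
    any(vapply(ts, function(t) term %in% all_ancestors(dag, t), logical(1))),
    logical(1))
  names(ann$gene_to_terms)[hit]
}

# Default planted term: deepest layer, then largest at-or-below pool, ties
# broken by id, so the choice depends only on (dag, ann).
pick_planted_term <- function(ann, dag) {
  candidates <- dag$ids[!dag$obsolete & !(dag$ids %in% dag$roots)]
  if (length(candidates) == 0L) stop("no candidate terms to plant at")
  d <- dag$depth[candidates]
  deepest <- candidates[!is.na(d) & d == max(d, na.rm = TRUE)]
  pools <- vapply(deepest, function(t) length(genes_at_or_below(ann, dag, t)),
                  integer(1))
  deepest[order(-pools, deepest)][1]
}

#' Generate an input gene list with planted enrichment
#'
#' Draws `spec$input_size` genes: a fraction `spec$planted_fraction` (rounded
#' to a count) without replacement from the genes annotated at or below the
#' planted term, and the remainder uniformly from the rest of the universe.
#' With `planted_fraction = 0` this is a uniform null draw.  Deterministic
#' given `spec$seed`.
#'
#' @param ann An `annotation_set`.
#' @param dag The companion `ontology_dag`.
#' @param spec A `fixture_spec`; if `spec$planted_term` is `NULL` the
#'   deepest term with the largest annotated pool is used.
#' @return Character vector of gene ids, with attributes `planted_term` and
#'   `planted_pool`.
#' @export
make_input_list <- function(ann, dag, spec) {
  stopifnot(inherits(ann, "annotation_set"), inherits(dag, "ontology_dag"),
            inherits(spec, "fixture_spec"))
  planted <- if (is.null(spec$planted_term)) pick_planted_term(ann, dag)
             else resolve_term(dag, spec$planted_term)
  pool <- genes_at_or_below(ann, dag, planted)
  if (length(pool) == 0L) stop("planted term has an empty gene pool: ", planted)
  n_planted <- round(spec$planted_fraction * spec$input_size)
  n_rest <- spec$input_size - n_planted
  if (n_planted > length(pool))
    stop("planted pool too small: need ", n_planted, ", have ", length(pool))
  if (n_rest > length(ann$universe) - n_planted)
    stop("universe too small: need ", spec$input_size, " genes, have ",
         length(ann$universe))
  with_seed(spec$seed + 2L, {
    first <- if (n_planted > 0) sample(pool, n_planted) else character(0)
    # remainder is uniform over the untaken universe, so planted_fraction = 0
    # degenerates to a uniform null draw from the whole universe
    rest <- setdiff(ann$universe, first)
    picked <- c(first, if (n_rest > 0) sample(rest, n_rest))
    structure(sample(picked), planted_term = planted, planted_pool = pool)
  })
}

#' Write a complete synthetic input bundle to disk
#'
#' Emits, under `dir`: `ontology.obo`, `annotations.gaf`, `genes.txt` (the
#' planted input list), `reference.txt` (the annotated universe),
#' `tf_matrix.tsv` (a random binary gene-by-TF matrix) and `pathways.tsv`
#' (random pathway memberships) -- the same dialects the package's parsers
#' consume.  Deterministic given `spec$seed`.
#'
#' @param dir Output directory (created if missing).
#' @param spec A `fixture_spec`.
#' @param n_tfs Number of synthetic transcription factors.
#' @param n_pathways Number of synthetic pathways.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture_bundle <- function(dir, spec = fixture_spec(),
                                 n_tfs = 4, n_pathways = 3) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dag <- make_dag(spec)
  ann <- make_annotations(dag, spec)
  input <- make_input_list(ann, dag, spec)

  paths <- c(obo = file.path(dir, "ontology.obo"),
             gaf = file.path(dir, "annotations.gaf"),
             genes = file.path(dir, "genes.txt"),
             reference = file.path(dir, "reference.txt"),
             tf = file.path(dir, "tf_matrix.tsv"),
             pathways = file.path(dir, "pathways.tsv"))
  write_obo(dag, paths["obo"])
  write_gaf(ann, dag, paths["gaf"])
  writeLines(as.character(input), paths["genes"])
  writeLines(ann$universe, paths["reference"])

  with_seed(spec$seed + 3L, {
    tfs <- sprintf("TF%02d", seq_len(n_tfs))
    cells <- matrix(rbinom(length(ann$universe) * n_tfs, 1, 0.15),
                    nrow = length(ann$universe),
                    dimnames = list(ann$universe, tfs))
    m <- structure(list(genes = ann$universe, tfs = tfs, cells = cells),
                   class = "tf_matrix")
    write_tf_matrix(m, paths["tf"])

    rows <- character(0)
    for (p in seq_len(n_pathways)) {
      pid <- sprintf("path%03d", p)
      members <- sample(ann$universe, max(3, round(length(ann$universe) / 10)))
      rows <- c(rows, paste(pid, sort(members),
                            sprintf("synthetic pathway %d", p), sep = "\t"))
    }
    writeLines(rows, paths["pathways"])
  })
  invisible(paths)
}
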