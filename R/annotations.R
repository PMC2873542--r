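# Gene -> term annotations and the three GO-tree search strategies.

# Gene identifiers are compared case-insensitively after whitespace trimming;
# they are normalized to upper case at every entry point.
normalize_gene_ids <- function(x) toupper(trimws(x))

new_annotation_set <- function(gene_to_terms, symbols = NULL) {
  gene_to_terms <- gene_to_terms[order(names(gene_to_terms))]
  structure(list(
    gene_to_terms = gene_to_terms,
    universe = names(gene_to_terms),
    symbols = symbols
  ), class = "annotation_set")
}

#' Parse a GAF gene-annotation file
#'
#' Reads GAF 2.x tab-delimited annotation lines (comment lines start with
#' `!`) into a map from gene id to the set of directly annotated term ids --
#' the gene's most specific terms, which need not be topological leaves of
#' the ontology.
#'
#' Filtering rules: rows whose qualifier contains `NOT` are excluded; rows
#' whose term id is unknown to `dag` or obsolete are dropped with a warning;
#' rows with fewer than 15 columns are skipped with a warning; duplicate
#' (gene, term) pairs collapse to one.  Evidence codes listed in
#' `exclude_evidence` (e.g. `"IEA"`) are excluded; by default all are kept.
#'
#' @param path Path to a GAF file, or a connection.
#' @param dag The companion `ontology_dag`; term ids are resolved against it
#'   (alt ids mapped to primary ids).
#' @param exclude_evidence Character vector of evidence codes to drop.
#' @return An object of class `annotation_set`: list with `gene_to_terms`
#'   (gene id -> character vector of term ids), `universe` (all annotated
#'   gene ids) and `symbols` (gene id -> DB object symbol, for lookup).
#' @export
parse_gaf <- function(path, dag, exclude_evidence = character()) {
  stopifnot(inherits(dag, "ontology_dag"))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]

  genes <- character(0); terms <- character(0); syms <- character(0)
  n_short <- 0L; n_unknown <- 0L; n_obsolete <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 15L) { n_short <- n_short + 1L; next }
    qualifier <- strsplit(f[4], "|", fixed = TRUE)[[1]]
    if ("NOT" %in% toupper(qualifier)) next
    if (length(exclude_evidence) && f[7] %in% exclude_evidence) next
    gene <- normalize_gene_ids(f[2])
    if (!nzchar(gene)) { n_short <- n_short + 1L; next }
    term <- trimws(f[5])
    prim <- tryCatch(resolve_term(dag, term), error = function(e) NA_character_)
    if (is.na(prim)) { n_unknown <- n_unknown + 1L; next }
    if (dag$obsolete[[prim]]) { n_obsolete <- n_obsolete + 1L; next }
    genes <- c(genes, gene); terms <- c(terms, prim)
    syms <- c(syms, trimws(f[3]))
  }
  if (n_short > 0L)
    warning(n_short, " malformed GAF row(s) skipped")
  if (n_unknown > 0L)
    warning(n_unknown, " annotation(s) to unknown term ids dropped")
  if (n_obsolete > 0L)
    warning(n_obsolete, " annotation(s) to obsolete terms dropped")
  if (length(genes) == 0L)
    stop("no usable annotation rows in GAF input")

  keep <- !duplicated(paste(genes, terms))
  gene_to_terms <- lapply(split(terms[keep], genes[keep]), function(x) sort(unique(x)))
  symbols <- syms[!duplicated(genes)]
  names(symbols) <- genes[!duplicated(genes)]
  new_annotation_set(gene_to_terms, symbols = symbols)
}

#' Serialize an annotation set to GAF 2.2
#'
#' Writes one minimal 17-column GAF row per (gene, direct term) pair, using
#' the aspect letter implied by each term's namespace.  Round-trips through
#' [parse_gaf()] losslessly.
#'
#' @param ann An `annotation_set`.
#' @param dag The companion `ontology_dag` (for namespaces).
#' @param path Output file path.
#' @param db Value for the DB column (default `"SYN"`).
#' @return `path`, invisibly.
#' @export
write_gaf <- function(ann, dag, path, db = "SYN") {
  stopifnot(inherits(ann, "annotation_set"), inherits(dag, "ontology_dag"))
  aspect_of <- c(biological_process = "P", molecular_function = "F",
                 cellular_component = "C")
  rows <- c("!gaf-version: 2.2")
  for (g in ann$universe) {
    sym <- if (!is.null(ann$symbols) && g %in% names(ann$symbols))
      ann$symbols[[g]] else g
    for (t in sort(ann$gene_to_terms[[g]])) {
      ns <- dag$namespace[[t]]
      asp <- if (ns %in% names(aspect_of)) aspect_of[[ns]] else "P"
      rows <- c(rows, paste(
        db, g, sym, "involved_in", t, paste0(db, ":ref"), "IEA", "",
        asp, "", "", "gene", paste0("taxon:0"), "20260101", db, "", "",
        sep = "\t"))
    }
  }
  writeLines(rows, path)
  invisible(path)
}

#' Per-term gene sets under the three GO-tree search strategies
#'
#' Turns per-gene direct annotations into the per-term gene sets that are
#' tested for over-representation.
#'
#' * **Strategy I** (max path length from leaf): a gene contributes to a term
#'   if the term lies within `k` parental steps of one of the gene's directly
#'   annotated ("most specific") terms.  `k = 0` tests the direct
#'   annotations only.
#' * **Strategy II** (min path length from root): annotations propagate fully
#'   upward, then terms whose minimum depth below the namespace root is less
#'   than `L` (the cut-off level) are discarded as too general.
#' * **Strategy III** (combined): Strategy I's bounded collection filtered by
#'   Strategy II's depth threshold, so the most specific terms are kept while
#'   terms more general than the cut level are discarded.
#'
#' @param ann An `annotation_set`.
#' @param dag The companion `ontology_dag`.
#' @param strategy `"I"`, `"II"` or `"III"`.
#' @param k Max parental steps from a direct annotation (strategies I, III).
#' @param L Minimum depth below the root (strategies II, III).
#' @param namespace Restrict emitted terms to one namespace (e.g.
#'   `"biological_process"`); `NULL` emits terms from every namespace.
#' @return Named list: term id -> sorted character vector of gene ids.
#'   Terms with empty gene sets are absent.
#' @export
term_gene_sets <- function(ann, dag, strategy = c("I", "II", "III"),
                           k = 0, L = 0, namespace = NULL) {
  stopifnot(inherits(ann, "annotation_set"), inherits(dag, "ontology_dag"))
  strategy <- match.arg(strategy)
  if (strategy %in% c("I", "III") && (!is.numeric(k) || k < 0))
    stop("k must be a non-negative integer")
  if (strategy %in% c("II", "III") && (!is.numeric(L) || L < 0))
    stop("L must be a non-negative integer")

  direct <- lapply(ann$gene_to_terms, function(ts)
    vapply(ts, resolve_term, character(1), dag = dag, USE.NAMES = FALSE))
  uniq_terms <- unique(unlist(direct, use.names = FALSE))

  reach <- switch(strategy,
    I   = lapply(uniq_terms, function(t) ancestors_within(dag, t, k)),
    II  = lapply(uniq_terms, function(t) all_ancestors(dag, t)),
    III = lapply(uniq_terms, function(t) ancestors_within(dag, t, k)))
  names(reach) <- uniq_terms

  gene_col <- character(0); term_col <- character(0)
  for (g in names(direct)) {
    ts <- unique(unlist(reach[direct[[g]]], use.names = FALSE))
    gene_col <- c(gene_col, rep(g, length(ts)))
    term_col <- c(term_col, ts)
  }

  keep <- !dag$obsolete[term_col]
  if (!is.null(namespace))
    keep <- keep & dag$namespace[term_col] == namespace
  if (strategy %in% c("II", "III")) {
    d <- dag$depth[term_col]
    keep <- keep & !is.na(d) & d >= L
  }
  gene_col <- gene_col[keep]; term_col <- term_col[keep]
  if (length(term_col) == 0L) return(stats::setNames(list(), character(0)))

  sets <- lapply(split(gene_col, term_col), function(x) sort(unique(x)))
  sets[order(names(sets))]
}

#' Fraction of a term's background annotation recovered by an input list
#'
#' The number of genes in the intersection of the input list with a term's
#' gene set, divided by the total number of background genes annotated to
#' that term.  This is the per-term metric used to compare search
#' strategies.
#'
#' @param term_genes Genes the term carries under the strategy in use.
#' @param input_genes The input gene list.
#' @param background_term_genes All background genes annotated to the term;
#'   must be nonempty.
#' @return A fraction in `[0, 1]`.
#' @export
percent_genes_in_term <- function(term_genes, input_genes, background_term_genes) {
  background_term_genes <- unique(background_term_genes)
  if (length(background_term_genes) == 0L)
    stop("background term gene set is empty")
  length(intersect(unique(term_genes), unique(input_genes))) /
    length(background_term_genes)
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", length(x$universe), "genes,",
      sum(lengths(x$gene_to_terms)), "direct (gene, term) annotations\n")
  invisible(x)
}
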