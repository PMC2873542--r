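# End-to-end analysis runs: configuration, gene-list reading, CSV outputs
# and the JSON run report.  The command-line front end in exec/goalkit is a
# thin wrapper over run_analysis().

#' Read a gene list from a text file
#'
#' Accepts one id per line or ids separated by whitespace, commas or
#' semicolons; lines starting with `#` are comments.  Ids are trimmed,
#' upper-cased (gene matching is case-insensitive throughout) and
#' de-duplicated with input order preserved.
#'
#' @param path Path to the gene-list file, or a connection.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[!startsWith(trimws(lines), "#")]
  toks <- unlist(strsplit(lines, "[\\s,;]+", perl = TRUE), use.names = FALSE)
  toks <- normalize_gene_ids(toks)
  toks <- toks[nzchar(toks)]
  toks <- toks[!duplicated(toks)]
  if (length(toks) == 0L) stop("gene list file contains no gene ids: ", path)
  toks
}

#' Configuration for an analysis run
#'
#' Bundles the inputs and parameters of one over-representation run.  At
#' least one analysis must be enabled: GO (requires `obo_path` and
#' `gaf_path`), TF (requires `tf_matrix_path`) or pathway (requires
#' `pathway_map_path`).
#'
#' Defaults: combined search strategy with `k = 0` (most specific terms
#' only) and `L = 3` (the cut level several GO tools default to),
#' Benjamini-Hochberg correction, `max_p = 0.05`, `min_genes = 2`.
#'
#' @param gene_list_path Input gene list file.
#' @param obo_path,gaf_path Ontology and annotation files for GO analysis.
#' @param reference_path Optional reference gene list; when omitted the
#'   reference defaults to the whole annotated universe (all genes in the
#'   GAF, or all genes named by the TF matrix / pathway map when no GAF is
#'   given).  A study-matched reference is preferable when available.
#' @param namespace GO namespace ("hierarchy") to analyse.
#' @param strategy GO-tree search strategy: `"I"`, `"II"` or `"III"`.
#' @param k Max path length from leaf (strategies I, III).
#' @param L Min path length from root (strategies II, III).
#' @param correction `"bh"`, `"holm"`, `"bonferroni"` or `"none"`.
#' @param max_p Maximum corrected p-value reported.
#' @param min_genes Minimum input genes per category.
#' @param tf_matrix_path Optional binary TF-target matrix (TSV).
#' @param pathway_map_path Optional pathway membership map (TSV).
#' @param output_dir Directory for result CSVs and the run report.
#' @param include_part_of Treat `part_of` as a parental edge (see
#'   [parse_obo()]).
#' @param exclude_evidence GAF evidence codes to drop (see [parse_gaf()]).
#' @return An object of class `run_config`.
#' @export
run_config <- function(gene_list_path, obo_path = NULL, gaf_path = NULL,
                       reference_path = NULL,
                       namespace = "biological_process",
                       strategy = c("III", "I", "II"), k = 0, L = 3,
                       correction = c("bh", "holm", "bonferroni", "none"),
                       max_p = 0.05, min_genes = 2,
                       tf_matrix_path = NULL, pathway_map_path = NULL,
                       output_dir = ".", include_part_of = TRUE,
                       exclude_evidence = character()) {
  strategy <- match.arg(strategy)
  correction <- match.arg(correction)
  if (xor(is.null(obo_path), is.null(gaf_path)))
    stop("GO analysis requires both obo_path and gaf_path")
  go_enabled <- !is.null(obo_path) && !is.null(gaf_path)
  if (!go_enabled && is.null(tf_matrix_path) && is.null(pathway_map_path))
    stop("no analysis enabled: provide obo+gaf, a TF matrix, or a pathway map")
  structure(list(
    gene_list_path = gene_list_path, obo_path = obo_path, gaf_path = gaf_path,
    reference_path = reference_path, namespace = namespace,
    strategy = strategy, k = k, L = L, correction = correction,
    max_p = max_p, min_genes = min_genes,
    tf_matrix_path = tf_matrix_path, pathway_map_path = pathway_map_path,
    output_dir = output_dir, include_part_of = include_part_of,
    exclude_evidence = exclude_evidence
  ), class = "run_config")
}

#' Run the configured analyses and write result files
#'
#' Executes every enabled analysis (GO terms under the configured search
#' strategy, TF target sets, pathways) against the shared input list and
#' reference, writing one CSV per analysis (`go_results.csv`,
#' `tf_results.csv`, `pathway_results.csv`) plus `run_report.json` recording,
#' per analysis, the reference size N, matched input size I, correction
#' multiplicity m, the parameters used, and any dropped genes.  Each
#' analysis kind is corrected independently.
#'
#' The run is fully deterministic: the same configuration produces
#' byte-identical CSVs.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with `results` (per-kind data frames), `files`
#'   (paths written) and `report` (the run-report list).
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  input_genes <- read_gene_list(config$gene_list_path)

  dag <- NULL; ann <- NULL
  if (!is.null(config$obo_path)) {
    dag <- parse_obo(config$obo_path, include_part_of = config$include_part_of)
    ann <- parse_gaf(config$gaf_path, dag,
                     exclude_evidence = config$exclude_evidence)
  }
  tfm <- if (!is.null(config$tf_matrix_path))
    parse_tf_matrix(config$tf_matrix_path) else NULL
  pwm <- if (!is.null(config$pathway_map_path))
    parse_pathway_map(config$pathway_map_path) else NULL

  if (!is.null(config$reference_path)) {
    reference <- read_gene_list(config$reference_path)
  } else {
    reference <- if (!is.null(ann)) ann$universe
      else unique(c(if (!is.null(tfm)) tfm$genes,
                    if (!is.null(pwm)) unlist(pwm$pathway_to_genes,
                                              use.names = FALSE)))
    warning("no reference list given; using all ", length(reference),
            " annotated genes as the reference universe (a study-matched ",
            "reference is preferable when available)")
  }

  results <- list(); files <- character(0); report_analyses <- list()
  run_one <- function(sets, kind, file, names_map = NULL) {
    res <- enrich(sets, input_genes, reference,
                  correction = config$correction, max_p = config$max_p,
                  min_genes = config$min_genes, kind = kind,
                  category_names = names_map)
    path <- file.path(config$output_dir, file)
    write_results_csv(res, path)
    results[[kind]] <<- res
    files[kind] <<- path
    report_analyses[[kind]] <<- list(
      N = if (nrow(res)) res$N[1] else length(reference),
      I = if (nrow(res)) res$I[1] else length(intersect(input_genes, reference)),
      m = attr(res, "m"),
      categories_reported = nrow(res),
      dropped_input_genes = as.list(attr(res, "dropped_input_genes")))
  }

  if (!is.null(dag)) {
    sets <- term_gene_sets(ann, dag, strategy = config$strategy,
                           k = config$k, L = config$L,
                           namespace = config$namespace)
    run_one(sets, "GO", "go_results.csv", names_map = dag$name)
  }
  if (!is.null(tfm)) run_one(tf_gene_sets(tfm), "TF", "tf_results.csv")
  if (!is.null(pwm)) run_one(pathway_gene_sets(pwm), "PATHWAY",
                             "pathway_results.csv",
                             names_map = pwm$pathway_names)

  report <- list(
    tool = "goalkit",
    version = as.character(utils::packageVersion("goalkit")),
    parameters = list(
      namespace = config$namespace, strategy = config$strategy,
      k = config$k, L = config$L, correction = config$correction,
      max_p = config$max_p, min_genes = config$min_genes,
      include_part_of = config$include_part_of,
      reference = if (is.null(config$reference_path)) "annotation universe"
                  else config$reference_path),
    analyses = report_analyses)
  report_path <- file.path(config$output_dir, "run_report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  files["report"] <- report_path

  invisible(list(results = results, files = files, report = report))
}
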