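# TF-target matrices and pathway membership maps, exposed as
# category -> gene-set maps for the enrichment engine.

#' Parse a binary TF-gene association matrix
#'
#' Reads a tab-delimited matrix in which rows correspond to genes and columns
#' to transcription factors, every cell is 0 or 1, and 1 marks a known
#' interaction between a TF and its target gene.  The first row holds the TF
#' names and the first column the gene ids; a corner cell above the gene
#' column is recognized when it is empty or labelled `gene`/`id` (in any
#' case), and may be omitted.  Orientation is fixed as genes x TFs; the
#' parser fails loudly rather than guessing a transposed layout.
#'
#' @param path Path to the TSV file, or a connection.
#' @return An object of class `tf_matrix`: list with `genes`, `tfs` and the
#'   integer 0/1 matrix `cells` (dimnames genes x TFs).
#' @export
parse_tf_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("TF matrix needs a header row and at least one gene row")
  rows <- strsplit(lines, "\t", fixed = TRUE)

  header <- trimws(rows[[1]])
  # corner cell above the gene-id column is optional; recognize it by label
  has_corner <- !nzchar(header[1]) ||
    tolower(header[1]) %in% c("gene", "genes", "id", "gene_id", "geneid")
  tfs <- if (has_corner) header[-1] else header
  body_width <- length(tfs) + 1L
  if (anyDuplicated(tfs)) stop("duplicate TF column name: ", tfs[duplicated(tfs)][1])
  if (any(!nzchar(tfs))) stop("empty TF column name in header")

  body <- rows[-1]
  genes <- character(length(body))
  cells <- matrix(NA_integer_, nrow = length(body), ncol = length(tfs))
  for (i in seq_along(body)) {
    f <- body[[i]]
    if (length(f) != body_width)
      stop("ragged TF matrix row ", i + 1L, ": expected ", body_width,
           " fields, got ", length(f))
    genes[i] <- normalize_gene_ids(f[1])
    vals <- trimws(f[-1])
    bad <- which(!vals %in% c("0", "1"))
    if (length(bad))
      stop("non-binary cell at gene row '", f[1], "', TF column '",
           tfs[bad[1]], "': '", vals[bad[1]], "'")
    cells[i, ] <- as.integer(vals)
  }
  if (anyDuplicated(genes))
    stop("duplicate gene row: ", genes[duplicated(genes)][1])
  dimnames(cells) <- list(genes, tfs)
  structure(list(genes = genes, tfs = tfs, cells = cells),
            class = "tf_matrix")
}

#' Gene target sets per transcription factor
#'
#' @param m A `tf_matrix`.
#' @return Named list: TF -> character vector of target genes (cells equal
#'   to 1).  TFs with no targets map to empty vectors; the enrichment engine
#'   drops such categories downstream.
#' @export
tf_gene_sets <- function(m) {
  stopifnot(inherits(m, "tf_matrix"))
  sets <- lapply(m$tfs, function(tf) sort(m$genes[m$cells[, tf] == 1L]))
  stats::setNames(sets, m$tfs)
}

#' Serialize a TF matrix to TSV
#'
#' @param m A `tf_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tf_matrix <- function(m, path) {
  stopifnot(inherits(m, "tf_matrix"))
  out <- c(paste(c("gene", m$tfs), collapse = "\t"),
           vapply(seq_along(m$genes), function(i)
             paste(c(m$genes[i], m$cells[i, ]), collapse = "\t"),
             character(1)))
  writeLines(out, path)
  invisible(path)
}

#' Parse a pathway-gene membership map
#'
#' Reads tab-delimited rows `pathway_id <TAB> gene_id [<TAB> pathway_name]`
#' and aggregates them into per-pathway gene sets.  Duplicate
#' (pathway, gene) rows collapse to one; when a pathway carries conflicting
#' labels the first occurrence wins with a warning.  Rows with fewer than
#' two fields are skipped with a warning.  Pathway ids pass through verbatim
#' (e.g. KEGG-style `sce03010`).
#'
#' @param path Path to the TSV file, or a connection.
#' @return An object of class `pathway_map`: list with `pathway_to_genes`
#'   (pathway id -> gene set) and `pathway_names` (pathway id -> label).
#' @export
parse_pathway_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  rows <- strsplit(lines, "\t", fixed = TRUE)

  short <- lengths(rows) < 2L
  if (any(short))
    warning(sum(short), " pathway row(s) with fewer than 2 fields skipped")
  rows <- rows[!short]
  if (length(rows) == 0L) stop("no usable rows in pathway map input")

  pw <- vapply(rows, function(f) trimws(f[1]), character(1))
  gene <- vapply(rows, function(f) normalize_gene_ids(f[2]), character(1))
  label <- vapply(rows, function(f)
    if (length(f) >= 3 && nzchar(trimws(f[3]))) trimws(f[3]) else NA_character_,
    character(1))

  keep <- nzchar(pw) & nzchar(gene)
  pw <- pw[keep]; gene <- gene[keep]; label <- label[keep]
  if (length(pw) == 0L) stop("no usable rows in pathway map input")

  sets <- lapply(split(gene, pw), function(x) sort(unique(x)))
  names_out <- character(0)
  for (p in unique(pw)) {
    labs <- label[pw == p & !is.na(label)]
    if (length(unique(labs)) > 1L)
      warning("conflicting labels for pathway ", p, "; keeping the first")
    names_out[p] <- if (length(labs)) labs[1] else p
  }
  structure(list(pathway_to_genes = sets[order(names(sets))],
                 pathway_names = names_out[order(names(names_out))]),
            class = "pathway_map")
}

#' Gene sets per pathway
#'
#' @param pm A `pathway_map`.
#' @return Named list: pathway id -> character vector of member genes.
#' @export
pathway_gene_sets <- function(pm) {
  stopifnot(inherits(pm, "pathway_map"))
  pm$pathway_to_genes
}
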