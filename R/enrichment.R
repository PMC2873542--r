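# Over-representation testing: contingency counts, one-tailed hypergeometric
# p-values, multiple-testing corrections, result filtering.

#' Contingency counts for one category
#'
#' Builds the quadruple (n, K, I, N) that parameterizes the one-tailed
#' hypergeometric test for one category: `n` input genes in the category,
#' `K` reference genes in the category, `I` input genes present in the
#' reference, `N` unique reference genes.  Input genes absent from the
#' reference are dropped with a warning before counting; category genes are
#' intersected with the reference.
#'
#' @param category_genes Genes annotated to the category.
#' @param input_genes The input gene list.
#' @param reference_genes The reference (background) gene list; nonempty.
#' @return An object of class `contingency_counts`: list with integer fields
#'   `n`, `K`, `I`, `N` and `members` (the sorted intersection genes).
#' @export
make_counts <- function(category_genes, input_genes, reference_genes) {
  reference_genes <- unique(reference_genes)
  if (length(reference_genes) == 0L) stop("reference gene list is empty")
  input_genes <- unique(input_genes)
  dropped <- setdiff(input_genes, reference_genes)
  if (length(dropped))
    warning(length(dropped), " input gene(s) absent from the reference dropped: ",
            paste(utils::head(sort(dropped), 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  input_ref <- intersect(input_genes, reference_genes)
  if (length(input_ref) == 0L) stop("no input genes found in reference")
  cat_ref <- intersect(unique(category_genes), reference_genes)
  members <- sort(intersect(cat_ref, input_ref))
  structure(list(
    n = length(members), K = length(cat_ref),
    I = length(input_ref), N = length(reference_genes),
    members = members
  ), class = "contingency_counts")
}

validate_counts <- function(n, K, I, N) {
  ok <- is.finite(n) & is.finite(K) & is.finite(I) & is.finite(N) &
    n >= 0 & K >= 0 & I >= 0 & N >= 1 &
    n <= pmin(K, I) & K <= N & I <= N &
    n == round(n) & K == round(K) & I == round(I) & N == round(N)
  if (!all(ok)) stop("invalid contingency counts (need 0 <= n <= min(K, I), K <= N, I <= N)")
  invisible(TRUE)
}

# Vectorized upper-tail P(X >= n), X ~ Hypergeometric(N, K, I), computed in
# log space via lchoose for numerical safety and clamped to [0, 1].
hyper_tail <- function(n, K, I, N) {
  validate_counts(n, K, I, N)
  mapply(function(n, K, I, N) {
    j <- n:min(K, I)
    p <- sum(exp(lchoose(K, j) + lchoose(N - K, I - j) - lchoose(N, I)))
    min(max(p, 0), 1)
  }, n, K, I, N)
}

#' One-tailed hypergeometric p-value for over-representation
#'
#' The probability of drawing at least `n` category genes when `I` genes are
#' sampled without replacement from a reference of `N` genes of which `K`
#' belong to the category:
#' \deqn{P(X \ge n) = \sum_{j=n}^{\min(K, I)}
#'   \binom{K}{j} \binom{N-K}{I-j} \big/ \binom{N}{I}.}
#' This equals the one-sided Fisher's exact test for over-representation on
#' the corresponding 2x2 table.  Terms are accumulated in log space.
#'
#' @param counts A `contingency_counts` object (or a list with fields
#'   `n`, `K`, `I`, `N`).
#' @return A probability in `[0, 1]`.
#' @seealso [fisher_oracle()] for an independent test-scale enumeration.
#' @export
hypergeom_pvalue <- function(counts) {
  hyper_tail(counts$n, counts$K, counts$I, counts$N)
}

#' Brute-force enumeration oracle for the hypergeometric tail
#'
#' Independently recomputes the upper-tail probability by explicit
#' combination counting over the whole support (no code shared with
#' [hypergeom_pvalue()]).  Intended for verification at test scale only;
#' refuses `N > 25`.
#'
#' @inheritParams hypergeom_pvalue
#' @return A probability in `[0, 1]`.
#' @export
fisher_oracle <- function(counts) {
  n <- counts$n; K <- counts$K; I <- counts$I; N <- counts$N
  if (N > 25) stop("fisher_oracle is test-scale only (N <= 25)")
  validate_counts(n, K, I, N)
  comb <- function(a, b) {
    if (b < 0 || b > a) return(0)
    r <- 1
    for (i in seq_len(b)) r <- r * (a - b + i) / i
    r
  }
  total <- comb(N, I)
  acc <- 0
  for (j in seq(n, min(K, I))) acc <- acc + comb(K, j) * comb(N - K, I - j)
  acc / total
}

check_pvec <- function(p) {
  if (length(p) < 1L) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  invisible(TRUE)
}

#' Multiple-testing corrections
#'
#' `correct_bonferroni()` multiplies each p-value by the number of tests and
#' caps at 1.  `correct_holm()` is the Bonferroni step-down procedure, and
#' `correct_bh()` the Benjamini-Hochberg step-up false-discovery-rate
#' procedure; both are computed by [stats::p.adjust()].  In order of
#' stringency: Bonferroni >= Holm >= Benjamini-Hochberg >= raw, elementwise.
#'
#' @param p Numeric vector of p-values in `[0, 1]`, length >= 1.
#' @return Adjusted p-values in the input order.
#' @name corrections
NULL

#' @rdname corrections
#' @export
correct_bonferroni <- function(p) {
  check_pvec(p)
  stats::p.adjust(p, method = "bonferroni")
}

#' @rdname corrections
#' @export
correct_holm <- function(p) {
  check_pvec(p)
  stats::p.adjust(p, method = "holm")
}

#' @rdname corrections
#' @export
correct_bh <- function(p) {
  check_pvec(p)
  stats::p.adjust(p, method = "BH")
}

apply_correction <- function(p, method) {
  switch(method,
         bonferroni = correct_bonferroni(p),
         holm = correct_holm(p),
         bh = correct_bh(p),
         none = { check_pvec(p); p },
         stop("unknown correction: ", method))
}

#' Over-representation analysis of a category map against a gene list
#'
#' For every category (GO term, transcription-factor target set, or pathway)
#' builds the contingency counts against the input list and reference
#' universe, computes the one-tailed hypergeometric p-value, applies the
#' selected multiple-testing correction across all tested categories of the
#' run, and returns the significant categories.
#'
#' Categories with fewer than `min_genes` input genes, and categories with no
#' reference genes at all, are removed *before* correction, so the correction
#' multiplicity `m` counts only the categories actually tested; `m` is
#' recorded in the result attributes.  Results are sorted by corrected
#' p-value, then raw p-value, then category id.
#'
#' @param category_gene_sets Named list: category id -> character vector of
#'   genes (e.g. the output of [term_gene_sets()] or [tf_gene_sets()]).
#' @param input_genes The input gene list.
#' @param reference_genes The reference gene list.
#' @param correction One of `"bh"`, `"holm"`, `"bonferroni"`, `"none"`.
#' @param max_p Keep categories with corrected p-value <= `max_p`.
#' @param min_genes Minimum number of input genes in a category for it to be
#'   tested.
#' @param kind Category kind label for the output: `"GO"`, `"TF"` or
#'   `"PATHWAY"`.
#' @param category_names Optional named character vector of human-readable
#'   labels, indexed by category id.
#' @return A `data.frame` with columns `category_id`, `category_name`,
#'   `kind`, `n`, `K`, `I`, `N`, `p_raw`, `p_corrected`,
#'   `correction_method`, `genes` (semicolon-joined intersection genes),
#'   and attributes `m` (correction multiplicity), `correction` and
#'   `dropped_input_genes`.
#' @export
enrich <- function(category_gene_sets, input_genes, reference_genes,
                   correction = c("bh", "holm", "bonferroni", "none"),
                   max_p = 1, min_genes = 0, kind = "GO",
                   category_names = NULL) {
  correction <- match.arg(correction)
  if (!is.numeric(max_p) || max_p <= 0 || max_p > 1)
    stop("max_p must be in (0, 1]")
  if (!is.numeric(min_genes) || min_genes < 0)
    stop("min_genes must be a non-negative integer")

  empty <- data.frame(
    category_id = character(0), category_name = character(0),
    kind = character(0), n = integer(0), K = integer(0), I = integer(0),
    N = integer(0), p_raw = numeric(0), p_corrected = numeric(0),
    correction_method = character(0), genes = character(0),
    stringsAsFactors = FALSE)
  attr(empty, "m") <- 0L
  attr(empty, "correction") <- correction

  if (length(category_gene_sets) == 0L) {
    warning("empty category map: nothing to test")
    return(empty)
  }
  if (is.null(names(category_gene_sets)) || any(!nzchar(names(category_gene_sets))))
    stop("category_gene_sets must be a named list")

  reference_genes <- unique(reference_genes)
  if (length(reference_genes) == 0L) stop("reference gene list is empty")
  input_genes <- unique(input_genes)
  dropped <- setdiff(input_genes, reference_genes)
  if (length(dropped))
    warning(length(dropped), " input gene(s) absent from the reference dropped")
  input_ref <- intersect(input_genes, reference_genes)
  if (length(input_ref) == 0L) stop("no input genes found in reference")
  I <- length(input_ref); N <- length(reference_genes)

  ids <- names(category_gene_sets)
  cat_ref <- lapply(category_gene_sets, function(g) intersect(unique(g), reference_genes))
  members <- lapply(cat_ref, function(g) sort(intersect(g, input_ref)))
  K <- lengths(cat_ref)
  n <- lengths(members)

  tested <- which(n >= min_genes & K >= 1L)
  attr(empty, "dropped_input_genes") <- dropped
  if (length(tested) == 0L) return(empty)

  p_raw <- hyper_tail(n[tested], K[tested], rep(I, length(tested)),
                      rep(N, length(tested)))
  p_corr <- apply_correction(p_raw, correction)
  m <- length(tested)

  res <- data.frame(
    category_id = ids[tested],
    category_name = if (is.null(category_names)) ids[tested] else {
      nm <- unname(category_names[ids[tested]])
      ifelse(is.na(nm), ids[tested], nm)
    },
    kind = kind,
    n = as.integer(n[tested]), K = as.integer(K[tested]),
    I = as.integer(I), N = as.integer(N),
    p_raw = p_raw, p_corrected = p_corr,
    correction_method = correction,
    genes = vapply(members[tested], paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE, row.names = NULL)

  res <- res[res$p_corrected <= max_p, , drop = FALSE]
  res <- res[order(res$p_corrected, res$p_raw, res$category_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "m") <- m
  attr(res, "correction") <- correction
  attr(res, "dropped_input_genes") <- dropped
  res
}

#' Write enrichment results as CSV
#'
#' @param results A result `data.frame` from [enrich()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path) {
  cols <- c("category_id", "category_name", "kind", "n", "K", "I", "N",
            "p_raw", "p_corrected", "correction_method", "genes")
  stopifnot(all(cols %in% names(results)))
  utils::write.csv(results[, cols], path, row.names = FALSE)
  invisible(path)
}
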