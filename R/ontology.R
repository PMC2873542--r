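# Ontology DAG: parsing, validation and upward-traversal primitives.

#' Parse an OBO 1.2 ontology file into a term DAG
#'
#' Reads `[Term]` stanzas from an OBO flat file (the dialect used by Gene
#' Ontology releases) and builds a directed acyclic graph of terms.
#' Traversal ("parental") edges are taken from `is_a` lines always, and from
#' `relationship: part_of` lines when `include_part_of = TRUE`.  `[Typedef]`
#' and other stanzas are skipped, as are unrecognized tags within a stanza.
#'
#' Obsolete terms are retained in the term table (so annotations pointing at
#' them can be recognized and dropped with a warning) but contribute no
#' traversal edges.  `alt_id` accessions resolve transparently to their
#' primary id in every lookup.
#'
#' Each namespace must contain exactly one root: a non-obsolete term with no
#' traversal parents.  Depth of every term below its namespace root (shortest
#' parent-edge path) is precomputed at parse time.
#'
#' @param path Path to an OBO file, or a connection.
#' @param include_part_of Treat `part_of` relationships as parental edges in
#'   addition to `is_a` (default `TRUE`, matching common GO practice).
#' @return An object of class `ontology_dag`: a list with elements `ids`,
#'   `name`, `namespace`, `obsolete`, `parents` (traversal parents),
#'   `parent_edges` (relation-typed edges, kept for serialization), `alt_ids`
#'   (alt accession -> primary id), `roots` (namespace -> root id) and
#'   `depth` (minimum distance from the namespace root).
#' @seealso [ancestors_within()], [all_ancestors()], [min_depth()],
#'   [write_obo()]
#' @export
#' @examples
#' obo <- c("format-version: 1.2", "",
#'          "[Term]", "id: GO:0000001", "name: root",
#'          "namespace: biological_process", "",
#'          "[Term]", "id: GO:0000002", "name: child",
#'          "namespace: biological_process", "is_a: GO:0000001 ! root")
#' tf <- tempfile(fileext = ".obo"); writeLines(obo, tf)
#' dag <- parse_obo(tf)
#' all_ancestors(dag, "GO:0000002")
parse_obo <- function(path, include_part_of = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)

  # split into stanzas: a stanza starts at a line like "[Term]" / "[Typedef]"
  stanza_starts <- grep("^\\[[^]]+\\]\\s*$", lines)
  if (length(stanza_starts) == 0L)
    stop("no [Term] stanzas found in OBO input")

  terms <- list()
  default_ns <- NA_character_
  hdr <- if (stanza_starts[1] > 1L) lines[seq_len(stanza_starts[1] - 1L)] else character(0)
  dns <- grep("^default-namespace:", hdr, value = TRUE)
  if (length(dns)) default_ns <- trimws(sub("^default-namespace:", "", dns[1]))

  bounds <- c(stanza_starts, length(lines) + 1L)
  for (s in seq_along(stanza_starts)) {
    head_line <- trimws(lines[stanza_starts[s]])
    if (head_line != "[Term]") next
    body <- if (stanza_starts[s] + 1L > bounds[s + 1L] - 1L) character(0)
            else lines[(stanza_starts[s] + 1L):(bounds[s + 1L] - 1L)]
    body <- body[nzchar(trimws(body))]

    tag_of <- sub("^([A-Za-z_-]+):.*$", "\\1", body)
    val_of <- trimws(sub("^[A-Za-z_-]+:", "", body))
    get1 <- function(tag) {
      v <- val_of[tag_of == tag]
      if (length(v)) v[1] else NA_character_
    }
    # id-valued tags may carry a "! comment"; keep the first token only
    first_tok <- function(x) sub("\\s.*$", "", x)

    id <- first_tok(get1("id"))
    if (is.na(id) || !nzchar(id)) stop("OBO [Term] stanza without an id")
    if (!is.null(terms[[id]])) stop("duplicate term id in OBO file: ", id)

    isa <- first_tok(val_of[tag_of == "is_a"])
    rel_raw <- val_of[tag_of == "relationship"]
    rel_type <- sub("\\s.*$", "", rel_raw)
    rel_target <- vapply(strsplit(rel_raw, "\\s+"), function(x)
      if (length(x) >= 2) x[2] else NA_character_, character(1))
    part_of <- rel_target[rel_type == "part_of" & !is.na(rel_target)]

    obs <- identical(tolower(get1("is_obsolete")), "true")
    ns <- get1("namespace")
    if (is.na(ns)) ns <- if (!is.na(default_ns)) default_ns else "default"

    terms[[id]] <- list(
      id = id,
      name = if (is.na(get1("name"))) id else get1("name"),
      namespace = ns,
      is_a = unique(isa),
      part_of = unique(part_of),
      alt_ids = unique(first_tok(val_of[tag_of == "alt_id"])),
      obsolete = obs
    )
  }
  if (length(terms) == 0L) stop("no [Term] stanzas found in OBO input")

  ids <- names(terms)
  nm <- vapply(terms, `[[`, character(1), "name")
  ns <- vapply(terms, `[[`, character(1), "namespace")
  obsolete <- vapply(terms, `[[`, logical(1), "obsolete")

  # alt-id map; aliases must not collide with primary ids or each other
  alt_pairs <- lapply(terms, `[[`, "alt_ids")
  alt_ids <- unlist(alt_pairs, use.names = FALSE)
  if (length(alt_ids)) {
    alt_primary <- rep(ids, lengths(alt_pairs))
    if (anyDuplicated(alt_ids))
      stop("duplicate alt_id in OBO file: ",
           alt_ids[duplicated(alt_ids)][1])
    clash <- intersect(alt_ids, ids)
    if (length(clash))
      stop("alt_id collides with a primary term id: ", clash[1])
    alt_map <- stats::setNames(alt_primary, alt_ids)
  } else {
    alt_map <- stats::setNames(character(0), character(0))
  }

  # typed parent edges (kept even for obsolete terms, for serialization)
  parent_edges <- lapply(terms, function(t) {
    e <- c(stats::setNames(t$is_a, rep("is_a", length(t$is_a))),
           stats::setNames(t$part_of, rep("part_of", length(t$part_of))))
    e[!is.na(e)]
  })

  # traversal parents: is_a always, part_of if configured; none for obsolete
  parents <- lapply(seq_along(ids), function(i) {
    if (obsolete[i]) return(character(0))
    e <- parent_edges[[i]]
    keep <- names(e) == "is_a" | (include_part_of & names(e) == "part_of")
    unique(unname(e[keep]))
  })
  names(parents) <- ids

  all_parents <- unique(unlist(parents, use.names = FALSE))
  unknown <- setdiff(all_parents, ids)
  if (length(unknown))
    stop("parent reference to unknown term id: ", unknown[1])

  # edges into obsolete terms cannot be traversed; drop them with a warning
  obs_ids <- ids[obsolete]
  if (length(obs_ids)) {
    hit <- vapply(parents, function(p) any(p %in% obs_ids), logical(1))
    if (any(hit)) {
      warning("dropping parent edge(s) pointing at obsolete term(s) from: ",
              paste(ids[hit], collapse = ", "))
      parents[hit] <- lapply(parents[hit], setdiff, y = obs_ids)
    }
  }

  check_acyclic(parents, ids[!obsolete])

  # one root (parentless, non-obsolete) per namespace
  roots <- character(0)
  for (nspace in unique(ns[!obsolete])) {
    members <- ids[!obsolete & ns == nspace]
    rootless <- members[lengths(parents[members]) == 0L]
    if (length(rootless) == 0L)
      stop("namespace '", nspace, "' has no root term")
    if (length(rootless) > 1L)
      stop("namespace '", nspace, "' has multiple parentless terms: ",
           paste(rootless, collapse = ", "))
    roots[nspace] <- rootless
  }

  dag <- structure(list(
    ids = ids, name = nm, namespace = ns, obsolete = obsolete,
    parents = parents, parent_edges = parent_edges, alt_ids = alt_map,
    roots = roots, depth = NULL
  ), class = "ontology_dag")
  dag$depth <- compute_depths(dag)
  dag
}

# Kahn's algorithm over the traversal edges; errors naming a cycle member.
check_acyclic <- function(parents, active_ids) {
  indeg <- stats::setNames(integer(length(active_ids)), active_ids)
  for (id in active_ids) {
    p <- intersect(parents[[id]], active_ids)
    indeg[p] <- indeg[p] + 1L   # child -> parent edge direction
  }
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (p in intersect(parents[[v]], active_ids)) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (seen < length(active_ids)) {
    member <- names(indeg)[indeg > 0L][1]
    stop("cycle detected in ontology parental edges involving term: ", member)
  }
  invisible(TRUE)
}

# BFS down from each namespace root; shortest parent-path distance per term.
compute_depths <- function(dag) {
  depth <- stats::setNames(rep(NA_integer_, length(dag$ids)), dag$ids)
  children <- stats::setNames(vector("list", length(dag$ids)), dag$ids)
  for (id in dag$ids)
    for (p in dag$parents[[id]]) children[[p]] <- c(children[[p]], id)
  for (root in dag$roots) {
    depth[root] <- 0L
    frontier <- root
    d <- 0L
    while (length(frontier)) {
      d <- d + 1L
      nxt <- unique(unlist(children[frontier], use.names = FALSE))
      nxt <- nxt[is.na(depth[nxt])]
      depth[nxt] <- d
      frontier <- nxt
    }
  }
  depth
}

# Resolve a term accession (possibly an alt_id) to its primary id.
resolve_term <- function(dag, term) {
  if (term %in% dag$ids) return(term)
  if (term %in% names(dag$alt_ids)) return(unname(dag$alt_ids[[term]]))
  stop("unknown term id: ", term)
}

#' Ancestors reachable within k parental steps
#'
#' Returns the term itself plus every term reachable by following 1..`k`
#' parent edges, taking the union over all parental paths.  With `k = 0` the
#' result is the term alone (the most specific term by itself).
#'
#' @param dag An `ontology_dag`.
#' @param term A term id (alt ids are resolved).
#' @param k Maximum number of parental steps, a non-negative integer.
#' @return Character vector of term ids (unordered set semantics).
#' @export
ancestors_within <- function(dag, term, k) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0)
    stop("k must be a single non-negative integer")
  term <- resolve_term(dag, term)
  if (dag$obsolete[[term]]) stop("term is obsolete: ", term)
  out <- term
  frontier <- term
  step <- 0L
  while (step < k && length(frontier)) {
    frontier <- setdiff(unique(unlist(dag$parents[frontier], use.names = FALSE)), out)
    out <- c(out, frontier)
    step <- step + 1L
  }
  out
}

#' All ancestors of a term (full upward closure)
#'
#' Every term on any parental path from `term` to its namespace root,
#' including `term` itself.
#'
#' @inheritParams ancestors_within
#' @return Character vector of term ids.
#' @export
all_ancestors <- function(dag, term) {
  stopifnot(inherits(dag, "ontology_dag"))
  term <- resolve_term(dag, term)
  out <- term
  frontier <- term
  while (length(frontier)) {
    frontier <- setdiff(unique(unlist(dag$parents[frontier], use.names = FALSE)), out)
    out <- c(out, frontier)
  }
  out
}

#' Minimum depth of a term below its namespace root
#'
#' Length of the shortest parent-edge path from the term to the root of its
#' namespace; the root itself has depth 0.  Depths are computed once at parse
#' time, so repeated calls are cheap and always agree.
#'
#' @inheritParams ancestors_within
#' @return A non-negative integer.
#' @export
min_depth <- function(dag, term) {
  stopifnot(inherits(dag, "ontology_dag"))
  term <- resolve_term(dag, term)
  if (dag$obsolete[[term]]) stop("term is obsolete: ", term)
  d <- dag$depth[[term]]
  if (is.na(d)) stop("term does not reach its namespace root: ", term)
  as.integer(d)
}

#' Serialize an ontology DAG back to OBO
#'
#' Writes the term table and typed parent edges as OBO 1.2 `[Term]` stanzas.
#' `parse_obo(write_obo(dag))` reproduces the same term and edge set.
#'
#' @param dag An `ontology_dag`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "ontology_dag"))
  tag_lines <- function(prefix, vals) {
    vals <- sort(as.character(unname(vals)))
    if (length(vals)) paste0(prefix, vals) else character(0)
  }
  out <- c("format-version: 1.2", "")
  for (id in sort(dag$ids)) {
    stanza <- c("[Term]",
                paste0("id: ", id),
                paste0("name: ", dag$name[[id]]),
                paste0("namespace: ", dag$namespace[[id]]))
    alts <- names(dag$alt_ids)[dag$alt_ids == id]
    stanza <- c(stanza, tag_lines("alt_id: ", alts))
    e <- dag$parent_edges[[id]]
    stanza <- c(stanza,
                tag_lines("is_a: ", e[names(e) == "is_a"]),
                tag_lines("relationship: part_of ", e[names(e) == "part_of"]))
    if (dag$obsolete[[id]]) stanza <- c(stanza, "is_obsolete: true")
    out <- c(out, stanza, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("ontology_dag:", length(x$ids), "terms (",
      sum(x$obsolete), "obsolete ) in",
      length(x$roots), "namespace(s)\n")
  for (ns in names(x$roots))
    cat("  ", ns, ": root ", x$roots[[ns]],
        ", max depth ", max(x$depth[x$namespace == ns & !x$obsolete], na.rm = TRUE),
        "\n", sep = "")
  invisible(x)
}
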