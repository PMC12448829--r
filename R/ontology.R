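#' GO ontology handling: parsing, term selection and the function graph
#'
#' The GO hierarchy is modeled as a rooted DAG over terms with directed
#' child -> parent edges labeled `is_a` or `part_of`.  The adjacency
#' convention used throughout the package: `A[i, i'] = 1` means a directed
#' edge from term `i` (the more specific child) to term `i'` (its parent);
#' the row index is the edge source.
#'
#' @name ontology
NULL

#' Construct an ontology graph
#'
#' @param terms character vector of term IDs
#' @param edges data.frame with columns child, parent, relation
#'   (relation in `is_a`, `part_of`)
#' @param names optional human-readable term names
#' @return object of class `ontology_graph` with fields `terms`, `edges`,
#'   `names` and a cached igraph in `graph`
#' @export
ontology_graph <- function(terms, edges, names = NULL) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) stop_data("duplicate term IDs")
  unknown <- setdiff(c(edges$child, edges$parent), terms)
  if (length(unknown))
    stop_data("edge references unknown term(s): ",
              paste(unknown, collapse = ", "))
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")], directed = TRUE,
    vertices = data.frame(name = terms))
  if (!igraph::is_dag(g)) stop_data("ontology graph contains a cycle")
  structure(list(terms = terms, edges = edges, names = names, graph = g),
            class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("ontology_graph:", length(x$terms), "terms,", nrow(x$edges),
      "edges (", sum(x$edges$relation == "is_a"), "is_a /",
      sum(x$edges$relation == "part_of"), "part_of )\n")
  invisible(x)
}

# terms with no incoming child->parent edge pointing at them from below,
# i.e. no children
ontology_leaves <- function(ontology) {
  setdiff(ontology$terms, unique(ontology$edges$parent))
}

# named list term -> all ancestors following child->parent edges,
# including the term itself
ontology_ancestors <- function(ontology) {
  g <- ontology$graph
  res <- lapply(ontology$terms, function(term)
    names(igraph::subcomponent(g, term, mode = "out")))
  names(res) <- ontology$terms
  res
}

#' Parse a minimal OBO file
#'
#' Supports `[Term]` stanzas with `id`, `name`, `is_a`, `relationship:
#' part_of` and `is_obsolete` tags.  Obsolete terms are excluded along with
#' any edge touching them; relations other than is_a/part_of are dropped.
#' A cycle or a reference to a term absent from the file is a format error.
#'
#' @param path OBO file
#' @return an `ontology_graph`
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) stop_data("OBO file not found: ", path)
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  if (!length(starts)) stop_data("no [Term] stanzas in ", path)
  bounds <- c(starts, length(lines) + 1L)
  terms <- character(0); nm <- character(0); obsolete <- logical(0)
  child <- character(0); parent <- character(0); relation <- character(0)
  for (i in seq_along(starts)) {
    stanza <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    stanza <- stanza[nzchar(stanza) & !startsWith(stanza, "[")]
    getval <- function(tag) {
      hit <- stanza[startsWith(stanza, paste0(tag, ":"))]
      sub("\\s*!.*$", "", trimws(sub(paste0("^", tag, ":"), "", hit)))
    }
    id <- getval("id")
    if (!length(id)) stop_data("OBO stanza without id")
    terms <- c(terms, id[1])
    nmv <- getval("name"); nm <- c(nm, if (length(nmv)) nmv[1] else id[1])
    obsolete <- c(obsolete, any(getval("is_obsolete") == "true"))
    for (p in getval("is_a")) {
      child <- c(child, id[1]); parent <- c(parent, p)
      relation <- c(relation, "is_a")
    }
    rel <- getval("relationship")
    for (r in rel) {
      parts <- strsplit(trimws(r), "\\s+")[[1]]
      if (length(parts) >= 2 && parts[1] == "part_of") {
        child <- c(child, id[1]); parent <- c(parent, parts[2])
        relation <- c(relation, "part_of")
      }
    }
  }
  unknown <- setdiff(parent, terms)
  if (length(unknown))
    stop_data("OBO references undefined term(s): ",
              paste(unknown, collapse = ", "))
  keep_terms <- terms[!obsolete]
  keep <- child %in% keep_terms & parent %in% keep_terms
  ontology_graph(keep_terms,
                 data.frame(child = child[keep], parent = parent[keep],
                            relation = relation[keep],
                            stringsAsFactors = FALSE),
                 names = nm[!obsolete])
}

#' Write a minimal OBO file
#'
#' @param ontology an `ontology_graph`
#' @param path output file
#' @export
write_obo <- function(ontology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_along(ontology$terms)) {
    id <- ontology$terms[i]
    writeLines(c("", "[Term]", paste0("id: ", id),
                 paste0("name: ", if (is.null(ontology$names)) id
                        else ontology$names[i])), con)
    e <- ontology$edges[ontology$edges$child == id, , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      if (e$relation[j] == "is_a")
        writeLines(paste0("is_a: ", e$parent[j]), con)
      else
        writeLines(paste0("relationship: part_of ", e$parent[j]), con)
    }
  }
  invisible(path)
}

#' Select GO terms by annotation frequency
#'
#' Ranks terms by the number of annotated proteins (descending), breaking
#' ties by lexicographic term ID, and keeps the top `max_terms`.  This is
#' the usual frequency-based pruning that keeps model size tractable while
#' covering most annotations.
#'
#' @param annotations data.frame(protein_id, go_id)
#' @param ontology an `ontology_graph`
#' @param max_terms maximum number of terms retained
#' @return list with `selected` (ordered term IDs) and `counts`
#' @export
select_terms <- function(annotations, ontology, max_terms) {
  if (nrow(annotations) == 0) {
    warning("empty annotation table: empty term selection")
    return(list(selected = character(0), counts = integer(0)))
  }
  unknown <- setdiff(unique(annotations$go_id), ontology$terms)
  if (length(unknown))
    stop_data("annotations reference unknown term(s): ",
              paste(unknown, collapse = ", "))
  counts <- table(annotations$go_id)
  counts <- counts[order(-as.integer(counts), names(counts))]
  sel <- names(counts)[seq_len(min(max_terms, length(counts)))]
  list(selected = sel,
       counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Build the function-graph adjacency over selected terms
#'
#' Restricts the ontology to the selected terms.  Edges passing through an
#' unselected intermediate term are NOT transitively closed: the prior
#' encodes only directly observed hierarchy, and the learned function
#' attention is free to recover any missing links.
#'
#' @param ontology an `ontology_graph`
#' @param selection result of [select_terms()] or a character vector
#' @return binary N_F x N_F matrix, rows = children (edge sources)
#' @export
build_function_adjacency <- function(ontology, selection) {
  sel <- if (is.list(selection)) selection$selected else selection
  if (length(setdiff(sel, ontology$terms)))
    stop_data("selection contains terms absent from the ontology")
  a <- matrix(0, length(sel), length(sel), dimnames = list(sel, sel))
  e <- ontology$edges
  keep <- e$child %in% sel & e$parent %in% sel
  if (any(keep)) a[cbind(e$child[keep], e$parent[keep])] <- 1
  a
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' @param labels binary protein x term matrix (colnames = term IDs)
#' @param ontology an `ontology_graph` covering the columns
#' @return binary matrix of the same shape, ancestor-closed
#' @export
propagate_annotations <- function(labels, ontology) {
  anc <- ontology_ancestors(ontology)
  out <- labels
  for (term in colnames(labels)) {
    up <- intersect(anc[[term]], colnames(labels))
    pos <- labels[, term] == 1
    if (any(pos)) out[pos, up] <- 1L
  }
  out
}
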