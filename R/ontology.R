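# Tissue ontology: OBO parsing, name resolution, major-tissue back-mapping.
#
# Tissue vocabularies (e.g. the Brenda Tissue Ontology) are directed acyclic
# graphs over is-a relations. Datasets report tissues at different
# granularities (whole brain vs. individual brain sub-regions), so analyses
# are anchored on a fixed set of mutually non-ancestral "major" tissue terms
# to which any finer term is back-mapped through its ancestors.

#' Parse an OBO-format tissue ontology
#'
#' Reads the subset of OBO 1.2 needed for tissue mapping: \code{[Term]}
#' stanzas with \code{id}, \code{name}, \code{synonym}, \code{is_a} and
#' \code{is_obsolete} lines. Obsolete terms (and their edges) are dropped.
#' Only is-a relationships are retained; other relationship types are
#' ignored.
#'
#' @param x Path to an OBO file, or a character vector of OBO lines.
#' @return An object of class \code{ontology_dag} with elements
#'   \code{terms} (data.frame: \code{id}, \code{name}),
#'   \code{synonyms} (data.frame: \code{id}, \code{synonym}) and
#'   \code{edges} (data.frame: \code{child}, \code{parent}).
#' @examples
#' obo <- c("[Term]", "id: T:1", "name: root",
#'          "[Term]", "id: T:2", "name: leaf", "is_a: T:1")
#' dag <- parse_obo(obo)
#' @export
parse_obo <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE) else x
  lines <- trimws(lines)

  in_term <- FALSE
  cur <- NULL
  stanzas <- list()
  flush <- function(cur) if (!is.null(cur)) stanzas[[length(stanzas) + 1L]] <<- cur

  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "" || startsWith(ln, "!")) next
    if (startsWith(ln, "[")) {
      flush(cur)
      cur <- NULL
      in_term <- identical(ln, "[Term]")
      if (in_term) cur <- list(line = i, id = NA_character_, name = NA_character_,
                               synonyms = character(), parents = character(),
                               obsolete = FALSE)
      next
    }
    if (!in_term) next
    sep <- regexpr(":", ln, fixed = TRUE)
    if (sep < 0L) stop("malformed OBO stanza line ", i, ": ", ln)
    key <- substr(ln, 1L, sep - 1L)
    val <- trimws(substr(ln, sep + 1L, nchar(ln)))
    if (key == "id") {
      cur$id <- val
    } else if (key == "name") {
      cur$name <- val
    } else if (key == "synonym") {
      # synonym: "label" SCOPE [xrefs] -- keep the quoted label
      m <- regmatches(val, regexpr('"[^"]*"', val))
      if (length(m)) cur$synonyms <- c(cur$synonyms, substr(m, 2L, nchar(m) - 1L))
    } else if (key == "is_a") {
      # strip trailing "! comment"
      cur$parents <- c(cur$parents, trimws(sub("!.*$", "", val)))
    } else if (key == "is_obsolete") {
      cur$obsolete <- identical(tolower(val), "true")
    }
  }
  flush(cur)

  stanzas <- Filter(function(s) !s$obsolete, stanzas)
  for (s in stanzas) {
    if (is.na(s$id) || is.na(s$name) || !nzchar(s$name))
      stop("malformed OBO stanza starting at line ", s$line,
           ": missing id or name")
  }
  ids <- vapply(stanzas, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate term id: ", ids[duplicated(ids)][1L])

  terms <- data.frame(
    id = ids,
    name = vapply(stanzas, `[[`, character(1), "name"),
    stringsAsFactors = FALSE
  )
  synonyms <- do.call(rbind, lapply(stanzas, function(s) {
    if (!length(s$synonyms)) return(NULL)
    data.frame(id = s$id, synonym = s$synonyms, stringsAsFactors = FALSE)
  }))
  if (is.null(synonyms))
    synonyms <- data.frame(id = character(), synonym = character(),
                           stringsAsFactors = FALSE)
  edges <- do.call(rbind, lapply(stanzas, function(s) {
    if (!length(s$parents)) return(NULL)
    data.frame(child = s$id, parent = s$parents, stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(child = character(), parent = character(),
                        stringsAsFactors = FALSE)
  # edges referencing obsolete/unknown terms are dropped with the term
  edges <- edges[edges$parent %in% ids & edges$child %in% ids, , drop = FALSE]

  dag <- structure(list(terms = terms, synonyms = synonyms, edges = edges),
                   class = "ontology_dag")
  g <- dag_graph(dag)
  if (!igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    member <- igraph::tail_of(g, cyc[1])$name
    stop("is_a relations contain a cycle involving term ", member)
  }
  dag
}

# igraph representation, edges pointing child -> parent
dag_graph <- function(dag) {
  igraph::graph_from_data_frame(dag$edges, directed = TRUE,
                                vertices = dag$terms$id)
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("Tissue ontology DAG: ", nrow(x$terms), " terms, ",
      nrow(x$edges), " is-a edges, ", nrow(x$synonyms), " synonyms\n",
      sep = "")
  invisible(x)
}

#' Ambiguous tissue names never resolved to a term
#'
#' Free-text tissue labels that name more than one tissue (or none) cannot be
#' mapped to a single ontology term and are skipped during name resolution.
#' @return Character vector of blacklisted labels (lower case).
#' @export
ambiguous_tissue_names <- function() {
  c("retina and testis", "uncharacterized tissue")
}

#' Resolve a free-text tissue name to an ontology term
#'
#' Case-insensitive exact matching against canonical term names first, then
#' against synonyms. Labels on the ambiguous-name blacklist, and labels with
#' no match, return \code{NA}: absence is a value, not an error. No fuzzy
#' matching is attempted, since approximate matches would invent
#' gene-tissue associations.
#'
#' @param name Free-text tissue label (scalar or vector).
#' @param dag An \code{ontology_dag}.
#' @param blacklist Labels treated as unresolvable;
#'   default \code{ambiguous_tissue_names()}.
#' @return Term id(s), \code{NA} where unmatched.
#' @export
match_tissue_name <- function(name, dag, blacklist = ambiguous_tissue_names()) {
  stopifnot(is.character(name), all(nzchar(name) | is.na(name)))
  key <- tolower(trimws(name))
  by_name <- dag$terms$id[match(key, tolower(dag$terms$name))]
  by_syn <- dag$synonyms$id[match(key, tolower(dag$synonyms$synonym))]
  out <- ifelse(is.na(by_name), by_syn, by_name)
  out[key %in% tolower(blacklist)] <- NA_character_
  out
}

#' Ancestors of a term
#'
#' Transitive closure over is-a edges, excluding the term itself.
#'
#' @param term A term id present in \code{dag}.
#' @param dag An \code{ontology_dag}.
#' @return Character vector of ancestor term ids (possibly empty).
#' @export
term_ancestors <- function(term, dag) {
  if (!term %in% dag$terms$id) stop("unknown term: ", term)
  g <- dag_graph(dag)
  anc <- igraph::subcomponent(g, term, mode = "out")$name
  setdiff(anc, term)
}

#' Back-map a term to the major tissues
#'
#' Returns every major tissue equal to the term or among its ancestors. A
#' term inside a DAG (not a tree) can reach more than one major; all matches
#' are returned so that evidence propagates symmetrically across datasets.
#'
#' @param term A term id present in \code{dag}.
#' @param majors Character vector of major-tissue term ids.
#' @param dag An \code{ontology_dag}.
#' @return Character vector, a subset of \code{majors} (possibly empty).
#' @export
map_to_major <- function(term, majors, dag) {
  if (!term %in% dag$terms$id) stop("unknown term: ", term)
  intersect(majors, c(term, term_ancestors(term, dag)))
}

#' Check that a major-tissue set is non-overlapping
#'
#' A valid major set has no member that is an ancestor of another member, so
#' that back-mapped associations are never double counted along one lineage.
#'
#' @param majors Character vector of term ids, all present in \code{dag}.
#' @param dag An \code{ontology_dag}.
#' @return \code{TRUE} iff no ordered pair of majors is in an
#'   ancestor/descendant relation (vacuously true for fewer than two).
#' @export
assert_non_overlapping <- function(majors, dag) {
  missing <- setdiff(majors, dag$terms$id)
  if (length(missing)) stop("unknown major term: ", missing[1L])
  if (length(majors) < 2L) return(TRUE)
  for (m in majors) {
    if (length(intersect(term_ancestors(m, dag), majors))) return(FALSE)
  }
  TRUE
}

#' Map the tissue labels of a measurement table onto major tissues
#'
#' Resolves free-text labels to terms and back-maps each to the major set.
#' Labels already equal to a major id are kept as-is. Unresolvable labels
#' and labels with no major ancestor are dropped.
#'
#' @param tissue Character vector of tissue labels or term ids.
#' @param majors Character vector of major term ids.
#' @param dag An \code{ontology_dag}.
#' @return A list with one character vector of majors per input label.
#' @keywords internal
resolve_to_majors <- function(tissue, majors, dag) {
  terms <- ifelse(tissue %in% dag$terms$id, tissue, match_tissue_name(tissue, dag))
  g <- dag_graph(dag)
  uniq <- unique(terms[!is.na(terms)])
  reach <- lapply(uniq, function(tm)
    intersect(majors, igraph::subcomponent(g, tm, mode = "out")$name))
  names(reach) <- uniq
  lapply(terms, function(tm) if (is.na(tm)) character() else reach[[tm]])
}
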