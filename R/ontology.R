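# Ontology graph: parsing, validation, ancestor queries.

NAMESPACE_MAP <- c(
  biological_process = "BP",
  molecular_function = "MF",
  cellular_component = "CC",
  BP = "BP", MF = "MF", CC = "CC"
)

#' Construct an ontology graph
#'
#' An `fegfs_ontology` is a lightweight in-memory representation of an
#' ontology DAG: a set of term identifiers, each with a human-readable
#' name, a namespace (`BP`, `MF` or `CC`), and a set of parent terms
#' collected from `is_a` and `part_of` edges.  Obsolete terms are kept
#' aside (they carry no edges and are excluded from every query), and
#' alternative identifiers are mapped to their primary term.
#'
#' Validation enforces that the graph restricted to each namespace is
#' acyclic and that parent edges stay within one namespace; cycles are a
#' hard error.
#'
#' @param terms character vector of (non-obsolete) term identifiers.
#' @param name named character vector, term -> label.
#' @param namespace named character vector, term -> one of `"BP"`,
#'   `"MF"`, `"CC"`.
#' @param parents named list, term -> character vector of parent terms.
#' @param obsolete character vector of obsolete term identifiers.
#' @param alt_id named character vector mapping alternative ids to their
#'   primary term.
#' @return an object of class `fegfs_ontology`.
#' @export
ontology_graph <- function(terms, name, namespace, parents,
                           obsolete = character(), alt_id = character()) {
  terms <- as.character(terms)
  stopifnot(!anyDuplicated(terms))
  namespace <- namespace[terms]
  if (anyNA(namespace)) {
    stop("terms without a namespace: ",
         paste(terms[is.na(namespace)], collapse = ", "))
  }
  parents <- parents[terms]
  names(parents) <- terms
  parents <- lapply(parents, function(p) unique(as.character(p)))
  # drop edges to unknown or obsolete terms, warn once
  known <- terms
  dropped <- unique(unlist(lapply(parents, setdiff, y = known)))
  if (length(dropped)) {
    warning("dropping edges to ", length(dropped),
            " unknown or obsolete parent term(s): ",
            paste(utils::head(dropped, 5L), collapse = ", "))
    parents <- lapply(parents, intersect, y = known)
  }
  g <- structure(
    list(terms = terms, name = name[terms], namespace = namespace,
         parents = parents, obsolete = unique(as.character(obsolete)),
         alt_id = alt_id),
    class = "fegfs_ontology"
  )
  for (tm in terms) {
    bad <- g$parents[[tm]][namespace[g$parents[[tm]]] != namespace[[tm]]]
    if (length(bad)) {
      stop("cross-namespace parent edge: ", tm, " -> ",
           paste(bad, collapse = ", "))
    }
  }
  g$order <- topological_order(g)      # errors on cycles
  g$ancestors <- all_ancestors(g)
  nroot <- table(namespace[vapply(parents, length, 1L) == 0L])
  if (any(nroot > 1L)) {
    warning("namespace(s) with more than one root: ",
            paste(names(nroot)[nroot > 1L], collapse = ", "))
  }
  g
}

#' @export
print.fegfs_ontology <- function(x, ...) {
  cat("fegfs ontology:", length(x$terms), "terms (",
      paste(names(table(x$namespace)), table(x$namespace), collapse = ", "),
      "),", length(x$obsolete), "obsolete\n")
  invisible(x)
}

# Kahn's algorithm over parent edges; error names one cycle member.
topological_order <- function(graph) {
  terms <- graph$terms
  indeg <- vapply(graph$parents, length, 1L)
  child_of <- list()
  for (tm in terms) {
    for (p in graph$parents[[tm]]) child_of[[p]] <- c(child_of[[p]], tm)
  }
  queue <- terms[indeg == 0L]
  out <- character(0)
  indeg <- indeg  # term -> number of unprocessed parents
  while (length(queue)) {
    tm <- queue[[1L]]; queue <- queue[-1L]
    out <- c(out, tm)
    for (ch in child_of[[tm]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != length(terms)) {
    stop("ontology contains a cycle involving term(s): ",
         paste(utils::head(setdiff(terms, out), 5L), collapse = ", "))
  }
  out
}

# term -> character vector of all ancestors (excluding the term itself),
# computed once in topological order.
all_ancestors <- function(graph) {
  anc <- stats::setNames(vector("list", length(graph$terms)), graph$terms)
  for (tm in graph$order) {
    ps <- graph$parents[[tm]]
    anc[[tm]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }
  anc
}

#' Ancestors of a term
#'
#' @param graph an [ontology_graph()].
#' @param term a term identifier (alternative ids are resolved).
#' @param include_self include the term itself in the result?
#' @return character vector of ancestor term identifiers.
#' @export
ancestors <- function(graph, term, include_self = FALSE) {
  term <- resolve_term(graph, term)
  out <- graph$ancestors[[term]]
  if (include_self) out <- unique(c(term, out))
  out
}

resolve_term <- function(graph, term) {
  if (term %in% graph$terms) return(term)
  if (term %in% names(graph$alt_id)) return(unname(graph$alt_id[[term]]))
  stop("unknown term: ", term)
}

#' Parse an OBO 1.2/1.4 ontology file
#'
#' Reads `[Term]` stanzas: `is_a` and `relationship: part_of` lines become
#' parent edges, `alt_id` values are mapped to their primary term, and
#' terms flagged `is_obsolete: true` are set aside with no edges.  Other
#' relationship types (the regulates family and friends) are ignored, as
#' is standard in enrichment tooling.
#'
#' @param path path to an OBO file.
#' @return an [ontology_graph()].
#' @export
parse_obo <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  in_term <- FALSE
  cur <- NULL
  stanzas <- list()
  flush <- function(cur) {
    if (is.null(cur)) return(invisible())
    if (is.null(cur$id)) {
      stop("malformed [Term] stanza starting at line ", cur$line,
           ": missing id")
    }
    stanzas[[length(stanzas) + 1L]] <<- cur
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "") next
    if (startsWith(ln, "[")) {
      flush(cur); cur <- NULL
      in_term <- identical(ln, "[Term]")
      if (in_term) cur <- list(line = i, parents = character(),
                               alt = character(), obsolete = FALSE)
      next
    }
    if (!in_term) next
    sep <- regexpr(":", ln, fixed = TRUE)
    if (sep < 0L) stop("malformed line ", i, " in [Term] stanza: ", ln)
    key <- substr(ln, 1L, sep - 1L)
    val <- trimws(substr(ln, sep + 1L, nchar(ln)))
    val <- sub("\\s*!.*$", "", val)          # trailing comments
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$ns <- val
    else if (key == "alt_id") cur$alt <- c(cur$alt, val)
    else if (key == "is_a") cur$parents <- c(cur$parents, val)
    else if (key == "relationship") {
      parts <- strsplit(val, "\\s+")[[1L]]
      if (length(parts) >= 2L && parts[[1L]] == "part_of") {
        cur$parents <- c(cur$parents, parts[[2L]])
      }
    } else if (key == "is_obsolete") cur$obsolete <- identical(val, "true")
  }
  flush(cur)
  if (!length(stanzas)) stop("no [Term] stanzas found in ", path)

  obs <- vapply(stanzas, function(s) s$obsolete, TRUE)
  live <- stanzas[!obs]
  ids <- vapply(live, function(s) s$id, "")
  ns_raw <- vapply(live, function(s) s$ns %||% NA_character_, "")
  ns <- stats::setNames(unname(NAMESPACE_MAP[ns_raw]), ids)
  if (anyNA(ns)) {
    stop("term(s) with missing or unknown namespace: ",
         paste(ids[is.na(ns)], collapse = ", "))
  }
  nm <- stats::setNames(vapply(live, function(s) s$name %||% s$id, ""), ids)
  parents <- stats::setNames(lapply(live, function(s) s$parents), ids)
  alt <- unlist(lapply(live, function(s) {
    if (length(s$alt)) stats::setNames(rep(s$id, length(s$alt)), s$alt)
  }))
  obsolete <- vapply(stanzas[obs], function(s) s$id, character(1L))
  g <- ontology_graph(ids, nm, ns, parents,
                      obsolete = obsolete,
                      alt_id = if (is.null(alt)) character() else alt)
  message("parsed ", length(ids), " terms (", length(obsolete),
          " obsolete) from ", path)
  g
}

#' Write an ontology graph as a minimal OBO file
#'
#' Emits one `[Term]` stanza per term (deterministic order) so that
#' generated fixtures round-trip through [parse_obo()].
#'
#' @param graph an [ontology_graph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  inv <- c("biological_process", "molecular_function", "cellular_component")
  names(inv) <- c("BP", "MF", "CC")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (tm in sort(graph$terms)) {
    writeLines(c(
      "[Term]",
      paste0("id: ", tm),
      paste0("name: ", graph$name[[tm]]),
      paste0("namespace: ", inv[[graph$namespace[[tm]]]]),
      if (length(graph$parents[[tm]]))
        paste0("is_a: ", sort(graph$parents[[tm]])),
      ""
    ), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
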