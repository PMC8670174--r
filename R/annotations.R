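# Gene -> term annotations: readers, true-path propagation, term
# frequencies used by SimRel.

#' Construct an annotation map
#'
#' An `fegfs_annotations` object holds the gene/term membership in both
#' directions: `direct` as read from the annotation file, `propagated`
#' after closure under ancestry (the true-path rule), `term_genes` as the
#' inversion of the propagated map, and `frequency`, the per-namespace
#' relative frequency P(t) of each term (fraction of genes annotated in
#' the term's namespace that carry the term after propagation).  Only
#' `direct` is populated until [propagate()] is called.
#'
#' @param direct named list, gene -> character vector of term ids.
#' @return an object of class `fegfs_annotations`.
#' @export
annotation_map <- function(direct) {
  stopifnot(is.list(direct))
  direct <- lapply(direct, function(x) unique(as.character(x)))
  structure(list(direct = direct, propagated = NULL,
                 term_genes = NULL, frequency = NULL,
                 ns_genes = NULL),
            class = "fegfs_annotations")
}

#' @export
print.fegfs_annotations <- function(x, ...) {
  cat("fegfs annotations:", length(x$direct), "genes,",
      length(unique(unlist(x$direct, use.names = FALSE))), "direct terms",
      if (is.null(x$propagated)) "(not propagated)" else "(propagated)", "\n")
  invisible(x)
}

#' Read gene -> term annotations
#'
#' Two formats are supported: GAF 2.x (tab-separated, `!` comment lines;
#' the gene identifier is taken from column 3, DB Object Symbol, so that
#' it matches the symbols expression matrices usually carry, and rows
#' whose qualifier contains `NOT` are skipped) and a plain two-column TSV
#' of `gene<TAB>term`.  Identifiers are taken verbatim, case preserved.
#'
#' @param path annotation file path.
#' @param fmt `"gaf"`, `"tsv"`, or `"auto"` (GAF if any line has >= 15
#'   tab-separated fields).
#' @return an [annotation_map()] with only the direct mapping filled.
#' @export
parse_annotations <- function(path, fmt = c("auto", "gaf", "tsv")) {
  fmt <- match.arg(fmt)
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(trimws(lines))]
  if (!length(lines)) return(annotation_map(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (fmt == "auto") {
    fmt <- if (max(lengths(fields)) >= 15L) "gaf" else "tsv"
  }
  skipped <- 0L
  pairs <- if (fmt == "gaf") {
    lapply(fields, function(f) {
      if (length(f) < 5L || !nzchar(f[[5L]])) { skipped <<- skipped + 1L; return(NULL) }
      if (grepl("(^|\\|)NOT(\\||$)", f[[4L]])) return(NULL)
      c(f[[3L]], f[[5L]])
    })
  } else {
    lapply(fields, function(f) {
      if (length(f) < 2L || !nzchar(f[[2L]])) { skipped <<- skipped + 1L; return(NULL) }
      c(f[[1L]], f[[2L]])
    })
  }
  if (skipped) warning(skipped, " row(s) without a term column skipped")
  pairs <- pairs[!vapply(pairs, is.null, TRUE)]
  if (!length(pairs)) return(annotation_map(list()))
  gene <- vapply(pairs, `[[`, "", 1L)
  term <- vapply(pairs, `[[`, "", 2L)
  direct <- split(term, gene)
  message("read ", length(pairs), " annotation rows for ", length(direct),
          " genes from ", path, " (", fmt, ")")
  annotation_map(direct)
}

#' Propagate annotations up the ontology
#'
#' Applies the true-path rule: a gene annotated to a term is annotated to
#' all of its ancestors.  Fills `propagated`, its inversion `term_genes`,
#' and `frequency`: for a term t in namespace ns,
#' `frequency[t] = |term_genes[t]| / (genes annotated in ns)`, the P(t)
#' used by [simrel()].  Frequencies are computed from the supplied
#' annotation corpus (per namespace); an externally derived frequency
#' table can be supplied via `frequency_override`.
#'
#' Annotated terms absent from the graph are dropped with a warning;
#' alternative ids are resolved to their primary term.
#'
#' @param graph an [ontology_graph()].
#' @param annot an [annotation_map()].
#' @param frequency_override optional named numeric vector term -> P(t)
#'   replacing the corpus-derived frequencies for the named terms.
#' @return the annotation map with `propagated`, `term_genes`,
#'   `frequency` and `ns_genes` (per-namespace gene counts) filled.
#' @export
propagate <- function(graph, annot, frequency_override = NULL) {
  stopifnot(inherits(graph, "fegfs_ontology"),
            inherits(annot, "fegfs_annotations"))
  known <- c(graph$terms, names(graph$alt_id))
  used <- unique(unlist(annot$direct, use.names = FALSE))
  unknown <- setdiff(used, known)
  if (length(unknown)) {
    warning("dropping ", length(unknown),
            " annotated term(s) absent from the ontology: ",
            paste(utils::head(unknown, 5L), collapse = ", "))
  }
  anc_self <- lapply(stats::setNames(graph$terms, graph$terms),
                     function(tm) c(tm, graph$ancestors[[tm]]))
  prop <- lapply(annot$direct, function(tms) {
    tms <- vapply(setdiff(tms, unknown), resolve_term, "", graph = graph)
    unique(unlist(anc_self[tms], use.names = FALSE))
  })
  prop <- prop[lengths(prop) > 0L]
  # invert: term -> genes
  if (length(prop)) {
    gene_rep <- rep(names(prop), lengths(prop))
    term_vec <- unlist(prop, use.names = FALSE)
    term_genes <- lapply(split(gene_rep, term_vec), unique)
  } else term_genes <- list()
  # per-namespace gene universes
  ns_of <- graph$namespace
  ns_genes <- stats::setNames(integer(0), character(0))
  freq <- stats::setNames(numeric(length(term_genes)), names(term_genes))
  for (ns in unique(ns_of[names(term_genes)])) {
    tms <- names(term_genes)[ns_of[names(term_genes)] == ns]
    genes_ns <- unique(unlist(term_genes[tms], use.names = FALSE))
    ns_genes[[ns]] <- length(genes_ns)
    freq[tms] <- lengths(term_genes[tms]) / length(genes_ns)
  }
  if (!is.null(frequency_override)) {
    freq[names(frequency_override)] <- frequency_override
  }
  annot$propagated <- prop
  annot$term_genes <- term_genes
  annot$frequency <- freq
  annot$ns_genes <- ns_genes
  annot
}

#' Write annotations as a two-column TSV
#'
#' Writes the direct gene -> term pairs (deterministic order) in the
#' two-column format [parse_annotations()] reads back.
#'
#' @param annot an [annotation_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annot, path) {
  genes <- sort(names(annot$direct))
  lines <- unlist(lapply(genes, function(g) {
    paste(g, sort(annot$direct[[g]]), sep = "\t")
  }))
  writeLines(lines, path)
  invisible(path)
}
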