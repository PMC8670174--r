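# Per-namespace hypergeometric over-representation testing with BH-FDR.

#' Upper-tail hypergeometric p-value
#'
#' Probability of observing at least `k` annotated genes in a sample of
#' `n` input genes, when `M` of the `N` background genes carry the term:
#' `P(X >= k)` for `X ~ Hypergeometric(N, M, n)`.  The upper tail is the
#' standard over-representation statistic built on the hypergeometric
#' pmf.
#'
#' @param k observed overlap (can be a vector).
#' @param n number of input genes in the namespace.
#' @param M number of background genes carrying the term.
#' @param N number of background genes in the namespace.
#' @return p-value(s) in (0, 1].
#' @export
hypergeom_pvalue <- function(k, n, M, N) {
  stopifnot(length(n) == 1L, length(M) == 1L, length(N) == 1L)
  if (any(k < 0) || n < 0 || M < 0 || N < 0 || any(k > n) || n > N || M > N) {
    stop("require 0 <= k <= n <= N and 0 <= M <= N")
  }
  stats::phyper(k - 1, M, N - M, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, returned in the input order, clipped to
#' \[0, 1\] and monotone in the sorted p-values.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Gene Ontology over-representation analysis
#'
#' Tests the input gene list against every annotated term, independently
#' within each namespace (BP, MF, CC): the background `N` is the number
#' of corpus genes annotated in the namespace, `n` the input genes among
#' them, `M` the term's corpus gene count and `k` the input/term overlap.
#' p-values are the upper-tail hypergeometric probability and are
#' BH-adjusted within each namespace; terms with `q_value <= alpha` are
#' returned.
#'
#' @param genes character vector of input gene identifiers (duplicates
#'   are removed; matching is exact-string).
#' @param graph an [ontology_graph()].
#' @param annot a propagated [annotation_map()] (see [propagate()]).
#' @param alpha FDR threshold (default 0.05).
#' @param min_genes minimum overlap `k` for a term to be tested
#'   (default 2, suppressing singleton hits).
#' @return a data.frame with one row per significant term: `term`,
#'   `name`, `namespace`, `k`, `n`, `M`, `N`, `p_value`, `q_value`, and a
#'   list-column `genes` holding the input genes annotated to the term
#'   (the overlap, not the full corpus set).  Rows are ordered by
#'   namespace, then q-value, p-value and term id.
#' @export
enrich <- function(genes, graph, annot, alpha = 0.05, min_genes = 2L) {
  stopifnot(inherits(graph, "fegfs_ontology"),
            inherits(annot, "fegfs_annotations"))
  if (is.null(annot$term_genes)) {
    stop("annotations are not propagated; call propagate() first")
  }
  stopifnot(alpha > 0, alpha <= 1, min_genes >= 1)
  genes <- unique(as.character(genes))
  annotated <- genes[genes %in% names(annot$propagated)]
  if (!length(annotated)) {
    stop("none of the input genes carry an annotation; ",
         "check that gene identifiers match the annotation corpus")
  }
  ns_of <- graph$namespace
  res <- list()
  for (ns in sort(unique(ns_of[names(annot$term_genes)]))) {
    tms <- names(annot$term_genes)[ns_of[names(annot$term_genes)] == ns]
    corpus_ns <- unique(unlist(annot$term_genes[tms], use.names = FALSE))
    n <- sum(annotated %in% corpus_ns)
    if (n == 0L) next
    N <- length(corpus_ns)
    rows <- lapply(sort(tms), function(tm) {
      hit <- intersect(annotated, annot$term_genes[[tm]])
      k <- length(hit)
      if (k < min_genes) return(NULL)
      M <- length(annot$term_genes[[tm]])
      data.frame(term = tm, name = unname(graph$name[[tm]]), namespace = ns,
                 k = k, n = n, M = M, N = N,
                 p_value = hypergeom_pvalue(k, n, M, N),
                 genes = I(list(sort(hit))),
                 stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (!length(rows)) next
    df <- do.call(rbind, rows)
    df$q_value <- bh_fdr(df$p_value)
    res[[ns]] <- df[df$q_value <= alpha, , drop = FALSE]
  }
  if (!length(res)) {
    out <- data.frame(term = character(), name = character(),
                      namespace = character(), k = integer(), n = integer(),
                      M = integer(), N = integer(), p_value = numeric(),
                      genes = I(list()), q_value = numeric())
  } else {
    out <- do.call(rbind, res)
  }
  out <- out[order(out$namespace, out$q_value, out$p_value, out$term), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("term", "name", "namespace", "k", "n", "M", "N",
          "p_value", "q_value", "genes")]
}

#' Write an enrichment table as TSV
#'
#' @param enriched a data.frame from [enrich()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(enriched, path) {
  flat <- enriched
  flat$genes <- vapply(enriched$genes, paste, "", collapse = ",")
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
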