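# SimRel semantic similarity and REVIGO-style redundancy reduction of an
# enriched term list.

#' SimRel semantic similarity between two terms
#'
#' Lin similarity scaled by how informative the shared ancestry is:
#' with P(t) the relative annotation frequency of term t and MIA the
#' common ancestor of `g1` and `g2` with the smallest P (the most
#' informative ancestor),
#'
#' \deqn{sim(g_1,g_2) = \frac{2\,\log P(MIA)}{\log P(g_1)+\log P(g_2)}
#'   \times (1 - P(MIA))}
#'
#' The (1 - P(MIA)) factor down-weights pairs whose only shared ancestry
#' is very general; in particular the similarity is 0 whenever the MIA is
#' the namespace root (P = 1), and `simrel(t, t) = 1 - P(t)`.  The Lin
#' ratio is invariant to the logarithm base; natural logs are used.
#'
#' @param graph an [ontology_graph()].
#' @param annot a propagated [annotation_map()] (frequencies filled).
#' @param g1,g2 term identifiers in the same namespace with positive
#'   annotation frequency.
#' @return similarity in \[0, 1\].
#' @export
simrel <- function(graph, annot, g1, g2) {
  g1 <- resolve_term(graph, g1)
  g2 <- resolve_term(graph, g2)
  if (graph$namespace[[g1]] != graph$namespace[[g2]]) {
    stop("simrel is undefined across namespaces: ", g1, " (",
         graph$namespace[[g1]], ") vs ", g2, " (",
         graph$namespace[[g2]], ")")
  }
  freq <- annot$frequency
  p1 <- freq[[g1]]; p2 <- freq[[g2]]
  if (is.null(p1) || is.null(p2) || is.na(p1) || is.na(p2) ||
      p1 <= 0 || p2 <= 0) {
    stop("both terms must have positive annotation frequency")
  }
  common <- intersect(ancestors(graph, g1, include_self = TRUE),
                      ancestors(graph, g2, include_self = TRUE))
  common <- common[common %in% names(freq)]
  if (!length(common)) return(0)
  pc <- freq[common]
  # most informative ancestor; ties broken by lexicographically smallest id
  cand <- sort(common[pc == min(pc)])
  p_mia <- freq[[cand[[1L]]]]
  denom <- log(p1) + log(p2)
  if (denom == 0 || p_mia >= 1) return(0)
  2 * log(p_mia) / denom * (1 - p_mia)
}

# all pairwise SimRel values among terms (same namespace assumed)
simrel_matrix <- function(graph, annot, terms) {
  n <- length(terms)
  S <- matrix(0, n, n, dimnames = list(terms, terms))
  if (n < 2L) return(S)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      S[i, j] <- S[j, i] <- simrel(graph, annot, terms[[i]], terms[[j]])
    }
  }
  S
}

#' Collapse an enriched term list by semantic similarity
#'
#' REVIGO-style redundancy reduction: within each namespace, the
#' most-similar pair with SimRel at or above `cutoff` is repeatedly
#' collapsed to a single representative until no remaining pair reaches
#' the cutoff.  The representative of a pair is (i) the ancestor, if one
#' term is an ancestor of the other (the "father" term), otherwise
#' (ii) the term with the smaller p-value, ties broken by larger corpus
#' set `M`, then by lexicographically smaller term id.  With
#' `prefer_ancestor = FALSE` rule (i) is skipped and representatives are
#' chosen by p-value alone.
#'
#' Surviving terms keep their gene sets and statistics unchanged.
#'
#' @param terms a data.frame from [enrich()] (columns `term`,
#'   `namespace`, `p_value`, `M` required).
#' @param graph an [ontology_graph()].
#' @param annot a propagated [annotation_map()].
#' @param cutoff similarity threshold in \[0, 1\] (default 0.4).
#' @param prefer_ancestor prefer the ancestor as representative before
#'   comparing p-values? (default TRUE).
#' @return the surviving rows of `terms`, with an attribute `"mapping"`:
#'   a data.frame (`discarded`, `representative`, `similarity`) recording
#'   every collapse.
#' @export
reduce_terms <- function(terms, graph, annot, cutoff = 0.4,
                         prefer_ancestor = TRUE) {
  stopifnot(is.data.frame(terms), cutoff >= 0, cutoff <= 1)
  mapping <- data.frame(discarded = character(),
                        representative = character(),
                        similarity = numeric())
  if (nrow(terms) < 2L) {
    attr(terms, "mapping") <- mapping
    return(terms)
  }
  keep <- character(0)
  for (ns in sort(unique(terms$namespace))) {
    sub <- terms[terms$namespace == ns, , drop = FALSE]
    ids <- sort(sub$term)
    S <- simrel_matrix(graph, annot, ids)
    pval <- stats::setNames(sub$p_value, sub$term)
    Msz <- stats::setNames(sub$M, sub$term)
    alive <- ids
    while (length(alive) > 1L) {
      Ss <- S[alive, alive, drop = FALSE]
      diag(Ss) <- -Inf
      top <- max(Ss)
      if (top < cutoff) break
      # most similar pair; ids are sorted so which.max ties resolve
      # to the lexicographically first pair
      idx <- which(Ss == top, arr.ind = TRUE)
      idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
      idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
      a <- alive[[idx[1L, 1L]]]; b <- alive[[idx[1L, 2L]]]
      rep_term <- pick_representative(graph, a, b, pval, Msz,
                                      prefer_ancestor)
      drop_term <- if (rep_term == a) b else a
      mapping <- rbind(mapping, data.frame(
        discarded = drop_term, representative = rep_term,
        similarity = top))
      alive <- setdiff(alive, drop_term)
    }
    keep <- c(keep, alive)
  }
  out <- terms[terms$term %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mapping") <- mapping
  out
}

pick_representative <- function(graph, a, b, pval, Msz, prefer_ancestor) {
  if (prefer_ancestor) {
    if (a %in% ancestors(graph, b)) return(a)
    if (b %in% ancestors(graph, a)) return(b)
  }
  if (pval[[a]] != pval[[b]]) {
    return(if (pval[[a]] < pval[[b]]) a else b)
  }
  if (Msz[[a]] != Msz[[b]]) {
    return(if (Msz[[a]] > Msz[[b]]) a else b)
  }
  min(a, b)
}

#' Write the semantic-reduction report as TSV
#'
#' @param reduced output of [reduce_terms()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reduction_report <- function(reduced, path) {
  mapping <- attr(reduced, "mapping")
  if (is.null(mapping)) mapping <- data.frame(
    discarded = character(), representative = character(),
    similarity = numeric())
  utils::write.table(mapping, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
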