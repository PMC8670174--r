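# Gene repetitive-rate reduction: coverage filtering and threshold
# merging of functional gene sets.

#' Construct a functional gene set
#'
#' The unit on which per-set KPCA runs: a named gene set together with
#' the ontology terms it absorbed.  Merged sets get the id
#' `"merged:"` followed by the sorted member term ids.
#'
#' @param id set label.
#' @param genes character vector of gene identifiers (non-empty).
#' @param source_terms term ids whose input-gene sets this set unions
#'   (defaults to `id`).
#' @return a list of class `fegfs_gene_set`.
#' @export
functional_gene_set <- function(id, genes, source_terms = id) {
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("gene set ", id, " is empty")
  structure(list(id = id, genes = genes,
                 source_terms = sort(unique(as.character(source_terms)))),
            class = "fegfs_gene_set")
}

#' Turn an enrichment table into functional gene sets
#'
#' Each significant term's input-gene overlap (its `genes` list-column
#' entry) becomes one functional gene set.
#'
#' @param enriched a data.frame from [enrich()] / [reduce_terms()].
#' @return a list of [functional_gene_set()]s.
#' @export
gene_sets_from_enrichment <- function(enriched) {
  stopifnot(is.data.frame(enriched))
  lapply(seq_len(nrow(enriched)), function(i) {
    functional_gene_set(enriched$term[[i]], enriched$genes[[i]])
  })
}

#' Gene repetitive rate between two gene sets
#'
#' `|a intersect b| / min(|a|, |b|)`: the fraction of the smaller set
#' shared with the larger.  A rate of 1 means the smaller set is fully
#' covered.
#'
#' @param a,b non-empty character vectors of gene identifiers, or
#'   [functional_gene_set()]s.
#' @return rate in \[0, 1\].
#' @export
repetitive_rate <- function(a, b) {
  if (inherits(a, "fegfs_gene_set")) a <- a$genes
  if (inherits(b, "fegfs_gene_set")) b <- b$genes
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b)) stop("gene sets must be non-empty")
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Pairwise repetitive-rate matrix
#'
#' @param sets a list of [functional_gene_set()]s.
#' @return a symmetric matrix with unit diagonal, dimnames = set ids.
#' @export
rate_matrix <- function(sets) {
  stopifnot(length(sets) >= 1L)
  ids <- vapply(sets, `[[`, "", "id")
  n <- length(sets)
  R <- matrix(1, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        R[i, j] <- R[j, i] <- repetitive_rate(sets[[i]], sets[[j]])
      }
    }
  }
  R
}

#' Remove fully covered gene sets
#'
#' A set whose repetitive rate with some other set equals 1 is the
#' smaller of the pair (its genes all belong to the other); such sets
#' are removed and the larger sets retained.  Among identical sets of
#' equal size the lexicographically smallest id survives.
#'
#' @param sets a list of [functional_gene_set()]s.
#' @return the surviving sets, genes unchanged.
#' @export
remove_covered <- function(sets) {
  if (length(sets) < 2L) return(sets)
  sizes <- vapply(sets, function(s) length(s$genes), 1L)
  ids <- vapply(sets, `[[`, "", "id")
  covered <- vapply(seq_along(sets), function(i) {
    for (j in seq_along(sets)) {
      if (i == j) next
      inter <- length(intersect(sets[[i]]$genes, sets[[j]]$genes))
      if (inter < sizes[[i]]) next        # i not a subset of j
      if (sizes[[i]] < sizes[[j]]) return(TRUE)
      if (sizes[[i]] == sizes[[j]] && ids[[j]] < ids[[i]]) return(TRUE)
    }
    FALSE
  }, TRUE)
  sets[!covered]
}

merged_id <- function(a, b) {
  paste0("merged:", paste(sort(unique(c(a$source_terms, b$source_terms))),
                          collapse = "+"))
}

merge_pair <- function(a, b) {
  functional_gene_set(merged_id(a, b),
                      union(a$genes, b$genes),
                      c(a$source_terms, b$source_terms))
}

#' One pairwise merging pass at a repetitive-rate threshold
#'
#' Best-first pairwise matching: the pair of sets with the highest rate
#' at or above `threshold` (ties: larger union, then lexicographically
#' smaller pair of ids) is replaced by its union; each set takes part in
#' at most one merge per pass, so a newly merged set is not merged again
#' until the next round — this is what makes repeated screening rounds
#' meaningful (see [reduce_redundancy()]).
#'
#' @param sets a list of [functional_gene_set()]s.
#' @param threshold repetitive-rate threshold in (0, 1\] (default 0.8).
#' @return the sets after one matching pass (unmerged sets first, in
#'   input order, then merged sets in merge order).
#' @export
merge_round <- function(sets, threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1)
  if (length(sets) < 2L) return(sets)
  avail <- sets
  merged <- list()
  repeat {
    if (length(avail) < 2L) break
    R <- rate_matrix(avail)
    diag(R) <- -Inf
    top <- max(R)
    if (top < threshold) break
    idx <- which(R == top, arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    if (nrow(idx) > 1L) {
      uni <- apply(idx, 1L, function(p)
        length(union(avail[[p[[1L]]]]$genes, avail[[p[[2L]]]]$genes)))
      key <- apply(idx, 1L, function(p)
        paste(sort(c(avail[[p[[1L]]]]$id, avail[[p[[2L]]]]$id)),
              collapse = "\r"))
      idx <- idx[order(-uni, key), , drop = FALSE]
    }
    i <- idx[1L, 1L]; j <- idx[1L, 2L]
    merged[[length(merged) + 1L]] <- merge_pair(avail[[i]], avail[[j]])
    avail <- avail[-c(i, j)]
  }
  c(avail, merged)
}

#' Reduce gene-set redundancy by repeated screening
#'
#' Alternates [remove_covered()] and one [merge_round()] matching pass,
#' `rounds` times (default 2, two screenings).  With
#' `until_converged = TRUE` the screening is instead repeated until a
#' full round changes nothing, which guarantees that all final pairwise
#' rates are below `threshold`.  If the fixed number of rounds stops
#' short of convergence a warning reports the remaining maximum rate.
#'
#' The union of all genes over the sets is invariant: coverage removal
#' deletes only true subsets and merging takes unions.
#'
#' @param sets a list of [functional_gene_set()]s.
#' @param threshold repetitive-rate threshold in (0, 1\] (default 0.8).
#' @param rounds number of screening rounds (default 2).
#' @param until_converged iterate to the fixpoint instead of a fixed
#'   round count?
#' @return the final list of [functional_gene_set()]s.
#' @export
reduce_redundancy <- function(sets, threshold = 0.8, rounds = 2L,
                              until_converged = FALSE) {
  stopifnot(rounds >= 1L)
  state <- sets
  round_no <- 0L
  repeat {
    round_no <- round_no + 1L
    before <- sort(vapply(state, `[[`, "", "id"))
    state <- remove_covered(state)
    state <- merge_round(state, threshold)
    after <- sort(vapply(state, `[[`, "", "id"))
    if (until_converged) {
      if (identical(before, after)) break
    } else if (round_no >= rounds) break
  }
  if (length(state) > 1L) {
    R <- rate_matrix(state)
    diag(R) <- -Inf
    if (max(R) >= threshold) {
      warning("redundancy reduction stopped before convergence: ",
              "maximum remaining repetitive rate ",
              format(max(R), digits = 3),
              " >= ", threshold, "; increase rounds or use ",
              "until_converged = TRUE")
    }
  }
  state
}

#' Write functional gene sets in GMT format
#'
#' One line per set: id, description (the absorbed term ids), then the
#' genes, tab-separated.
#'
#' @param sets a list of [functional_gene_set()]s.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$id, paste(s$source_terms, collapse = ","), sort(s$genes)),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read functional gene sets from a GMT file
#'
#' @param path a GMT file written by [write_gmt()] (or any standard GMT).
#' @return a list of [functional_gene_set()]s.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line: ", ln)
    src <- strsplit(f[[2L]], ",", fixed = TRUE)[[1L]]
    if (!length(src) || !nzchar(src[[1L]])) src <- f[[1L]]
    functional_gene_set(f[[1L]], f[-(1:2)], src)
  })
}
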