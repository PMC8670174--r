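# Agglomerative clustering of the feature matrix and external
# evaluation metrics (ARI, NMI, homogeneity, completeness).

#' Agglomerative hierarchical clustering
#'
#' Bottom-up merging of cells under Euclidean distance in the feature
#' space until `k` clusters remain.  `linkage = "ward"` (the default)
#' uses Ward's minimum-variance criterion on Euclidean distances
#' (hclust's `"ward.D2"`); `"average"`, `"complete"` and `"single"` are
#' also available.
#'
#' @param features numeric matrix, cells x features (e.g. from
#'   [build_feature_matrix()]).
#' @param k number of clusters, `1 <= k <=` number of cells.
#' @param linkage linkage criterion.
#' @return a list of class `fegfs_clustering`: `labels` (named integer
#'   vector of cluster indices 1..k), `k`, `linkage`, and the `hclust`
#'   tree.
#' @export
agglomerative <- function(features, k,
                          linkage = c("ward", "average", "complete",
                                      "single")) {
  linkage <- match.arg(linkage)
  features <- as.matrix(features)
  n <- nrow(features)
  if (k < 1L || k > n) stop("k must be between 1 and the number of cells")
  method <- c(ward = "ward.D2", average = "average",
              complete = "complete", single = "single")[[linkage]]
  tree <- stats::hclust(stats::dist(features, method = "euclidean"),
                        method = method)
  labels <- stats::cutree(tree, k = k)
  names(labels) <- rownames(features)
  structure(list(labels = labels, k = k, linkage = linkage, tree = tree),
            class = "fegfs_clustering")
}

#' @export
print.fegfs_clustering <- function(x, ...) {
  cat("fegfs clustering:", length(x$labels), "cells in", x$k,
      "clusters (", x$linkage, "linkage )\n")
  invisible(x)
}

check_labels <- function(truth, pred) {
  if (inherits(truth, "fegfs_clustering")) truth <- truth$labels
  if (inherits(pred, "fegfs_clustering")) pred <- pred$labels
  if (length(truth) != length(pred)) {
    stop("label vectors have different lengths (", length(truth), " vs ",
         length(pred), ")")
  }
  if (length(truth) < 2L) stop("need at least 2 samples")
  list(truth = as.character(truth), pred = as.character(pred))
}

#' Adjusted Rand index
#'
#' Hubert-Arabie chance-corrected Rand index between two partitions:
#' the Rand index (fraction of sample pairs on which the partitions
#' agree — placed together in both or apart in both) is rescaled by its
#' expectation under random partitions with the same cluster sizes, so
#' that identical partitions score 1 and random agreement scores ~0.
#'
#' @param truth,pred label vectors of equal length (>= 2).
#' @return the ARI, in \[-1, 1\].
#' @export
ari <- function(truth, pred) {
  lb <- check_labels(truth, pred)
  tab <- table(lb$truth, lb$pred)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  tot <- choose(n, 2)
  expected <- sum_a * sum_b / tot
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) {
    # degenerate: both partitions all-singletons or all-one-cluster
    return(if (sum_ij == max_idx) 1 else 0)
  }
  (sum_ij - expected) / (max_idx - expected)
}

#' Normalized mutual information
#'
#' `2 I(F, G) / (H(F) + H(G))` with `I` the mutual information and `H`
#' the partition entropies from the contingency table (natural logs; the
#' ratio is base-invariant).  Two identical trivial partitions (both a
#' single cluster) are defined to agree perfectly (NMI 1); if exactly
#' one partition is trivial the mutual information, and hence the NMI,
#' is 0.
#'
#' @param truth,pred label vectors of equal length (>= 2).
#' @return the NMI, in \[0, 1\].
#' @export
nmi <- function(truth, pred) {
  lb <- check_labels(truth, pred)
  tab <- table(lb$truth, lb$pred)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij)
  p_j <- colSums(pij)
  hf <- -sum(ifelse(pi_ > 0, pi_ * log(pi_), 0))
  hg <- -sum(ifelse(p_j > 0, p_j * log(p_j), 0))
  if (hf + hg == 0) return(1)
  outer_p <- outer(pi_, p_j)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer_p[nz]))
  mi <- max(mi, 0)
  2 * mi / (hf + hg)
}

#' Homogeneity and completeness scores
#'
#' Each predicted cluster is matched to a reference class; with
#' `matching = "majority"` (default) the majority class, ties going to
#' the smallest class index, with `matching = "optimal"` the one-to-one
#' assignment maximising the total number of correctly placed cells
#' (exact assignment search; feasible for <= 10 clusters).  Writing
#' N(F_i, G_i) for the cells of cluster i that belong to its matched
#' class, N(G_i) for the cluster size and N(F_i) for the matched class
#' size, homogeneity averages N(F_i, G_i)/N(G_i) and completeness
#' averages N(F_i, G_i)/N(F_i) over the k predicted clusters.
#'
#' @param truth,pred label vectors of equal length (>= 2).
#' @param matching cluster-to-class correspondence rule.
#' @return named numeric vector `c(hom = , com = )`, each in \[0, 1\].
#' @export
hom_com <- function(truth, pred, matching = c("majority", "optimal")) {
  matching <- match.arg(matching)
  lb <- check_labels(truth, pred)
  tab <- table(lb$truth, lb$pred)   # classes x clusters
  k <- ncol(tab)
  class_sizes <- rowSums(tab)
  cluster_sizes <- colSums(tab)
  match_idx <- if (matching == "majority") {
    apply(tab, 2L, which.max)       # ties -> smallest class index
  } else {
    optimal_assignment(tab)
  }
  correct <- vapply(seq_len(k), function(j) tab[match_idx[[j]], j], 1)
  hom <- mean(correct / cluster_sizes)
  com <- mean(correct / class_sizes[match_idx])
  c(hom = hom, com = com)
}

# Exact one-to-one assignment of clusters to classes maximising the
# total matched count; branch-and-bound over permutations.  When there
# are more clusters than classes the surplus clusters fall back to
# their majority class.
optimal_assignment <- function(tab) {
  k <- ncol(tab)
  ncl <- nrow(tab)
  if (k > 10L) {
    stop("optimal matching supports at most 10 predicted clusters; ",
         "use matching = \"majority\"")
  }
  best <- list(score = -1, idx = NULL)
  recurse <- function(j, used, idx, score) {
    if (j > k) {
      if (score > best$score) best <<- list(score = score, idx = idx)
      return(invisible())
    }
    choices <- if (length(used) < ncl) setdiff(seq_len(ncl), used) else
      seq_len(ncl)  # more clusters than classes: reuse allowed for surplus
    for (i in choices) {
      recurse(j + 1L, c(used, i), c(idx, i), score + tab[i, j])
    }
  }
  recurse(1L, integer(0), integer(0), 0)
  best$idx
}

#' Evaluate a clustering against reference labels
#'
#' @param truth,pred label vectors of equal length (>= 2); `pred` may be
#'   an [agglomerative()] result.
#' @param matching correspondence rule for [hom_com()].
#' @return a one-row data.frame with columns `ari`, `nmi`, `hom`, `com`.
#' @export
evaluate_clustering <- function(truth, pred,
                                matching = c("majority", "optimal")) {
  hc <- hom_com(truth, pred, matching = matching)
  data.frame(ari = ari(truth, pred), nmi = nmi(truth, pred),
             hom = unname(hc[["hom"]]), com = unname(hc[["com"]]))
}

#' Read or write two-column cell label TSVs
#'
#' `read_labels()` returns a named vector (cell_id -> label);
#' `write_labels()` writes one, with a `cell_id<TAB>label` header.
#'
#' @param labels named vector of labels.
#' @param path file path.
#' @return the labels (read) or `path` invisibly (write).
#' @export
write_labels <- function(labels, path) {
  if (inherits(labels, "fegfs_clustering")) labels <- labels$labels
  df <- data.frame(cell_id = names(labels) %||%
                     paste0("cell_", seq_along(labels)),
                   label = unname(labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  stats::setNames(df[[2L]], df[[1L]])
}
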