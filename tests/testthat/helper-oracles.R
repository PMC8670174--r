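# Independent oracles and small fixture builders shared by the suite.

# --- fixture ontologies -------------------------------------------------

# 3-term is_a chain C -> B -> A, written as OBO text
obo_chain_text <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: A", "name: root", "namespace: biological_process", "",
    "[Term]", "id: B", "name: mid", "namespace: biological_process",
    "is_a: A ! root", "",
    "[Term]", "id: C", "name: leaf", "namespace: biological_process",
    "is_a: B", "")
}

# 5-term DAG with a multi-parent leaf:
#   R <- M1, R <- M2, M1 <- L1, (M1, M2) <- L2
dag5 <- function() {
  ontology_graph(
    terms = c("R", "M1", "M2", "L1", "L2"),
    name = stats::setNames(paste("term", c("R", "M1", "M2", "L1", "L2")),
                           c("R", "M1", "M2", "L1", "L2")),
    namespace = stats::setNames(rep("BP", 5), c("R", "M1", "M2", "L1", "L2")),
    parents = list(R = character(), M1 = "R", M2 = "R",
                   L1 = "M1", L2 = c("M1", "M2"))
  )
}

# propagated annotations over dag5 with an even gene spread
dag5_annotations <- function() {
  direct <- list(g1 = "L1", g2 = "L1", g3 = "L2", g4 = "L2",
                 g5 = c("L1", "L2"), g6 = "M2", g7 = "M1", g8 = "R")
  propagate(dag5(), annotation_map(direct))
}

# --- exact-summation hypergeometric tail --------------------------------

# P(X >= k) from the pmf with exact binomial coefficients; every choose()
# value involved is an integer below 2^53 for N <= 40, so the summation
# is exact up to one final division.
oracle_hyper_tail <- function(k, n, M, N) {
  hi <- min(n, M)
  if (k > hi) return(0)
  i <- k:hi
  sum(choose(M, i) * choose(N - M, n - i)) / choose(N, n)
}

# --- pair-enumeration ARI ------------------------------------------------

oracle_ari <- function(truth, pred) {
  n <- length(truth)
  a <- b <- cc <- d <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      st <- truth[[i]] == truth[[j]]
      sp <- pred[[i]] == pred[[j]]
      if (st && sp) a <- a + 1
      else if (st && !sp) b <- b + 1
      else if (!st && sp) cc <- cc + 1
      else d <- d + 1
    }
  }
  denom <- (a + b) * (b + d) + (a + cc) * (cc + d)
  if (denom == 0) return(1)          # both partitions trivial and equal
  2 * (a * d - b * cc) / denom
}

# --- brute-force KPCA ----------------------------------------------------

# explicit centering matrix + full symmetric eigendecomposition, with the
# same component-count rule as kpca_reduce but none of its code
oracle_kpca <- function(X, ratio) {
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ni <- sqrt(sum(X[i, ]^2)); nj <- sqrt(sum(X[j, ]^2))
      K[i, j] <- if (ni == 0 || nj == 0) 0 else
        sum(X[i, ] * X[j, ]) / (ni * nj)
    }
  }
  diag(K) <- 1
  H <- diag(n) - matrix(1 / n, n, n)
  Kc <- H %*% K %*% H
  eig <- eigen(Kc, symmetric = TRUE)
  lam <- eig$values
  pos <- which(lam > 1e-10 * max(abs(lam)))
  lam_pos <- lam[pos]
  d <- max(1L, which(cumsum(lam_pos) >= ratio * sum(lam_pos))[1L])
  out <- eig$vectors[, pos[seq_len(d)], drop = FALSE] %*%
    diag(sqrt(lam_pos[seq_len(d)]), d)
  out
}

# column-wise comparison up to sign
expect_equal_up_to_sign <- function(A, B, tol = 1e-8) {
  expect_equal(dim(A), dim(B))
  for (k in seq_len(ncol(A))) {
    dif <- min(max(abs(A[, k] - B[, k])), max(abs(A[, k] + B[, k])))
    expect_lt(dif, tol)
  }
}

# --- misc ----------------------------------------------------------------

make_sets <- function(...) {
  args <- list(...)
  lapply(names(args), function(id) functional_gene_set(id, args[[id]]))
}

gene_range <- function(from, to) sprintf("g%04d", from:to)

random_set_collection <- function(n_sets = 20L, max_genes = 50L) {
  lapply(seq_len(n_sets), function(i) {
    functional_gene_set(sprintf("S%02d", i),
                        sample(gene_range(1, 120),
                               sample(2:max_genes, 1L)))
  })
}
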