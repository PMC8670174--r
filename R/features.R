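# Expression preprocessing and per-gene-set cosine-kernel KPCA feature
# extraction.

#' Construct an expression matrix
#'
#' Cells in rows, genes in columns, with unique cell and gene
#' identifiers as dimnames.  Raw (non-log) values must be non-negative;
#' the `log_transformed` attribute records whether [log_transform()] has
#' been applied.
#'
#' @param values numeric matrix, cells x genes.
#' @param cell_ids,gene_ids optional identifier vectors (default: the
#'   matrix dimnames, or generated `cell_i` / `gene_j` labels).
#' @param log_transformed has the matrix already been log-transformed?
#' @return a numeric matrix with attribute `log_transformed`.
#' @export
expression_matrix <- function(values, cell_ids = NULL, gene_ids = NULL,
                              log_transformed = FALSE) {
  values <- as.matrix(values)
  if (is.null(cell_ids)) cell_ids <- rownames(values) %||%
      paste0("cell_", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- colnames(values) %||%
      paste0("gene_", seq_len(ncol(values)))
  stopifnot(length(cell_ids) == nrow(values),
            length(gene_ids) == ncol(values),
            !anyDuplicated(cell_ids), !anyDuplicated(gene_ids))
  if (!log_transformed && any(values < 0)) {
    stop("raw expression values must be non-negative")
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  attr(values, "log_transformed") <- log_transformed
  values
}

#' Has an expression matrix been log-transformed?
#'
#' @param expr an [expression_matrix()].
#' @return TRUE after [log_transform()], FALSE for raw values.
#' @export
is_log_transformed <- function(expr) {
  isTRUE(attr(expr, "log_transformed"))
}

#' Noise-gene removal threshold
#'
#' The minimum number of cells a gene must be expressed in:
#' `factor * max(1, floor(pct * n_cells))`.  For 301 cells this is
#' `3 * floor(3.01) = 9`, i.e. genes expressed in fewer than nine cells
#' are dropped.
#'
#' @param n_cells number of cells.
#' @param factor multiplier (default 3).
#' @param pct fraction of cells (default 0.01).
#' @return integer threshold (>= `factor`).
#' @export
noise_threshold <- function(n_cells, factor = 3L, pct = 0.01) {
  as.integer(factor) * max(1L, as.integer(floor(pct * n_cells)))
}

#' Remove noise genes
#'
#' Drops genes expressed (strictly positive value) in fewer than
#' [noise_threshold()] cells; surviving genes keep their order.
#'
#' @param expr a raw (not log-transformed) [expression_matrix()].
#' @param factor,pct threshold parameters, see [noise_threshold()].
#' @return the filtered expression matrix.
#' @export
filter_noise_genes <- function(expr, factor = 3L, pct = 0.01) {
  if (is_log_transformed(expr)) {
    stop("filter_noise_genes expects raw (not log-transformed) values")
  }
  thr <- noise_threshold(nrow(expr), factor, pct)
  n_pos <- colSums(expr > 0)
  keep <- n_pos >= thr
  if (!any(keep)) stop("noise filter removed every gene (threshold ", thr, ")")
  message("noise filter (threshold ", thr, " cells): kept ", sum(keep),
          " of ", ncol(expr), " genes")
  expression_matrix(expr[, keep, drop = FALSE], rownames(expr),
                    colnames(expr)[keep], log_transformed = FALSE)
}

#' Log-transform expression values
#'
#' Elementwise `log10(x + 1)`.
#'
#' @param expr a raw [expression_matrix()] (values >= 0).
#' @return the transformed matrix, `log_transformed` flag set.
#' @export
log_transform <- function(expr) {
  if (any(expr < 0)) stop("negative expression value")
  expression_matrix(log10(expr + 1), rownames(expr), colnames(expr),
                    log_transformed = TRUE)
}

#' Principal-component retention ratio by dataset size
#'
#' The fraction of kernel-PCA signal kept per functional gene set: 40%
#' for small datasets (up to 1000 cells), 60% for 1000-3000 cells, 80%
#' above 3000 cells.
#'
#' @param n_cells number of cells (>= 2).
#' @return 0.40, 0.60 or 0.80.
#' @export
retention_ratio <- function(n_cells) {
  stopifnot(n_cells >= 2)
  if (n_cells <= 1000) 0.40 else if (n_cells <= 3000) 0.60 else 0.80
}

#' Cosine kernel matrix
#'
#' `K[i, j] = <x_i, x_j> / (||x_i|| ||x_j||)` over the rows of `X`:
#' symmetric, unit diagonal, entries in \[-1, 1\], invariant to positive
#' rescaling of any row.  Rows with zero norm get off-diagonal entries 0
#' (diagonal 1) with a warning.
#'
#' @param X numeric matrix, samples x features.
#' @return the samples x samples kernel matrix.
#' @export
cosine_kernel <- function(X) {
  X <- as.matrix(X)
  nrm <- sqrt(rowSums(X^2))
  zero <- nrm == 0
  if (any(zero)) {
    warning(sum(zero), " zero-norm row(s); their kernel entries set to 0")
    nrm[zero] <- 1
  }
  K <- tcrossprod(X / nrm)
  if (any(zero)) {
    K[zero, ] <- 0
    K[, zero] <- 0
  }
  diag(K) <- 1
  K <- (K + t(K)) / 2
  pmin(pmax(K, -1), 1)
}

#' Kernel PCA with the cosine kernel
#'
#' Builds the cosine kernel of the rows of `X`, double-centers it in
#' feature space, eigendecomposes, and keeps the smallest number `d` of
#' leading components whose eigenvalue sum reaches `ratio` times the sum
#' of positive eigenvalues (at least one).  Eigenvalues below
#' `1e-10 * max(eigenvalue)` are treated as zero.  Projections are the
#' unit eigenvectors scaled by `sqrt(eigenvalue)`; each component's sign
#' is fixed so its largest-magnitude coordinate is positive, making the
#' output deterministic.
#'
#' @param X numeric matrix, cells x genes (>= 2 cells).
#' @param ratio retention ratio in (0, 1\].
#' @return a cells x d matrix of projections, columns ordered by
#'   decreasing eigenvalue; attribute `"eigenvalues"` carries the
#'   retained eigenvalues.
#' @export
kpca_reduce <- function(X, ratio) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("kernel PCA needs at least 2 cells")
  stopifnot(ratio > 0, ratio <= 1)
  K <- cosine_kernel(X)
  rm <- rowMeans(K)
  Kc <- K - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + mean(K)
  eig <- eigen(Kc, symmetric = TRUE)
  lam <- eig$values
  tol <- 1e-10 * max(abs(lam), 1e-300)
  pos <- which(lam > tol)
  if (!length(pos)) {
    # fully degenerate kernel (e.g. all rows identical): one null component
    out <- matrix(0, n, 1L, dimnames = list(rownames(X), "PC1"))
    attr(out, "eigenvalues") <- 0
    return(out)
  }
  lam_pos <- lam[pos]
  d <- which(cumsum(lam_pos) >= ratio * sum(lam_pos))[1L]
  d <- max(1L, d)
  vec <- eig$vectors[, pos[seq_len(d)], drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (k in seq_len(d)) {
    m <- which.max(abs(vec[, k]))
    if (vec[m, k] < 0) vec[, k] <- -vec[, k]
  }
  out <- sweep(vec, 2L, sqrt(lam_pos[seq_len(d)]), `*`)
  dimnames(out) <- list(rownames(X), paste0("PC", seq_len(d)))
  attr(out, "eigenvalues") <- lam_pos[seq_len(d)]
  out
}

#' Build the concatenated feature matrix
#'
#' For each functional gene set, runs [kpca_reduce()] on the cells x
#' set-genes submatrix of the log-transformed expression matrix and
#' concatenates the reduced blocks column-wise, in the order the sets
#' are given.  Sets with no gene present in the matrix are skipped with
#' a warning.
#'
#' @param expr a log-transformed [expression_matrix()].
#' @param sets a list of [functional_gene_set()]s.
#' @param ratio retention ratio in (0, 1\]; defaults to
#'   [retention_ratio()] of the cell count.
#' @return a cells x features matrix with attribute `"block_index"`, a
#'   named list mapping each contributing set id to its column range.
#' @export
build_feature_matrix <- function(expr, sets,
                                 ratio = retention_ratio(nrow(expr))) {
  if (!is_log_transformed(expr)) {
    stop("build_feature_matrix expects a log-transformed matrix; ",
         "call log_transform() first")
  }
  stopifnot(length(sets) >= 1L)
  blocks <- list()
  block_index <- list()
  col0 <- 0L
  for (s in sets) {
    gs <- intersect(s$genes, colnames(expr))
    if (!length(gs)) {
      warning("gene set ", s$id, " has no gene in the expression matrix; ",
              "skipped")
      next
    }
    proj <- kpca_reduce(expr[, gs, drop = FALSE], ratio)
    blocks[[s$id]] <- proj
    block_index[[s$id]] <- (col0 + 1L):(col0 + ncol(proj))
    col0 <- col0 + ncol(proj)
  }
  if (!length(blocks)) {
    stop("no functional gene set overlaps the expression matrix genes")
  }
  out <- do.call(cbind, blocks)
  colnames(out) <- unlist(lapply(names(blocks), function(id) {
    paste0(id, ".", seq_along(block_index[[id]]))
  }))
  rownames(out) <- rownames(expr)
  attr(out, "block_index") <- block_index
  out
}
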