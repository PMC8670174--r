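test_that("noise threshold follows the 3-units-by-1%-of-cells rule", {
  expect_equal(noise_threshold(301), 9)    # floor(3.01) = 3, times 3
  expect_equal(noise_threshold(50), 3)     # floor(0.5) clamped to 1
  expect_equal(noise_threshold(1000), 30)
})

test_that("genes below the expression-count threshold are removed", {
  set.seed(3)
  n <- 301L
  vals <- matrix(stats::runif(n * 3, 1, 5), n, 3,
                 dimnames = list(NULL, c("keep_all", "at_thr", "below")))
  vals[10:n, "at_thr"] <- 0      # positive in exactly 9 cells
  vals[9:n, "below"] <- 0        # positive in 8 cells
  expr <- expression_matrix(vals)
  out <- suppressMessages(filter_noise_genes(expr))
  expect_setequal(colnames(out), c("keep_all", "at_thr"))

  allpos <- expression_matrix(matrix(1, 20, 4))
  expect_equal(ncol(suppressMessages(filter_noise_genes(allpos))), 4)
  expect_error(suppressMessages(filter_noise_genes(
    expression_matrix(matrix(0, 20, 2)))), "every gene")
})

test_that("log transform is elementwise log10(x + 1)", {
  expr <- expression_matrix(matrix(c(0, 9, 99, 999), 2, 2))
  out <- log_transform(expr)
  expect_equal(as.numeric(out), c(0, 1, 2, 3))
  expect_true(is_log_transformed(out))
  expect_error(log_transform(matrix(-1, 2, 2)), "negative")
})

test_that("retention ratio steps at 1000 and 3000 cells", {
  expect_equal(retention_ratio(301), 0.40)
  expect_equal(retention_ratio(1000), 0.40)
  expect_equal(retention_ratio(2717), 0.60)
  expect_equal(retention_ratio(3000), 0.60)
  expect_equal(retention_ratio(3005), 0.80)
})

test_that("cosine kernel matches hand-computed cases", {
  X <- rbind(c(1, 0), c(1, 1), c(2, 0), c(0, 3))
  K <- cosine_kernel(X)
  expect_equal(K[1, 2], 1 / sqrt(2))
  expect_equal(K[1, 3], 1)            # identical directions
  expect_equal(K[1, 4], 0)            # orthogonal
  expect_equal(unname(diag(K)), rep(1, 4))
  expect_equal(K, t(K))
})

test_that("cosine kernel is invariant to positive row rescaling", {
  set.seed(5)
  X <- matrix(stats::runif(30, 0.1, 2), 6, 5)
  Y <- sweep(X, 1L, stats::runif(6, 0.5, 10), `*`)
  expect_equal(cosine_kernel(Y), cosine_kernel(X), tolerance = 1e-12)
})

test_that("zero-norm rows get zero kernel entries with a warning", {
  X <- rbind(c(1, 2), c(0, 0), c(2, 4))
  expect_warning(K <- cosine_kernel(X), "zero-norm")
  expect_equal(K[2, c(1, 3)], c(0, 0))
  expect_equal(K[2, 2], 1)
})

test_that("kernel PCA matches the brute-force oracle", {
  set.seed(42)
  X <- matrix(stats::rlnorm(8 * 5), 8, 5)
  for (ratio in c(0.4, 0.8, 1.0)) {
    mine <- kpca_reduce(X, ratio)
    orac <- oracle_kpca(X, ratio)
    expect_equal_up_to_sign(unclass(mine)[, , drop = FALSE], orac)
  }
})

test_that("component counts follow the eigenvalue retention rule", {
  # rank-1 centered kernel: two distinct directions only
  X <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  expect_equal(ncol(kpca_reduce(X, 0.4)), 1)
  expect_equal(ncol(kpca_reduce(X, 1.0)), 1)
  # richer matrix: ratio 1 keeps every positive eigenvalue
  set.seed(8)
  Y <- matrix(stats::runif(60, 0.1, 3), 10, 6)
  full <- kpca_reduce(Y, 1.0)
  K <- cosine_kernel(Y)
  n <- nrow(K)
  Kc <- K - outer(rowMeans(K), rep(1, n)) -
    outer(rep(1, n), rowMeans(K)) + mean(K)
  lam <- eigen(Kc, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ncol(full), sum(lam > 1e-10 * max(lam)))
})

test_that("identical rows give a degenerate single null component", {
  X <- matrix(1, 5, 3)
  out <- kpca_reduce(X, 0.4)
  expect_equal(dim(out), c(5L, 1L))
  expect_equal(as.numeric(out), rep(0, 5))
})

test_that("projection columns are uncorrelated", {
  set.seed(9)
  X <- matrix(stats::rlnorm(15 * 7), 15, 7)
  P <- kpca_reduce(X, 1.0)
  G <- crossprod(unclass(P))
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
})

test_that("feature blocks concatenate per gene set with provenance", {
  set.seed(10)
  expr <- log_transform(expression_matrix(
    matrix(stats::rlnorm(20 * 12), 20, 12,
           dimnames = list(NULL, sprintf("g%02d", 1:12)))))
  all_set <- list(functional_gene_set("all", colnames(expr)))
  f1 <- build_feature_matrix(expr, all_set, ratio = 0.6)
  direct <- kpca_reduce(expr, 0.6)
  expect_equal(unname(unclass(f1)), unname(unclass(direct)),
               ignore_attr = TRUE)

  s2 <- list(functional_gene_set("left", sprintf("g%02d", 1:6)),
             functional_gene_set("right", sprintf("g%02d", 7:12)))
  f2 <- build_feature_matrix(expr, s2, ratio = 0.6)
  d1 <- ncol(kpca_reduce(expr[, 1:6], 0.6))
  d2 <- ncol(kpca_reduce(expr[, 7:12], 0.6))
  expect_equal(ncol(f2), d1 + d2)
  bi <- attr(f2, "block_index")
  expect_equal(bi$left, 1:d1)
  expect_equal(bi$right, (d1 + 1):(d1 + d2))
})

test_that("sets without expressed genes are skipped, none left is an error", {
  expr <- log_transform(expression_matrix(
    matrix(1:12, 4, 3, dimnames = list(NULL, c("a", "b", "c")))))
  sets <- list(functional_gene_set("ok", c("a", "b")),
               functional_gene_set("gone", c("x", "y")))
  expect_warning(f <- build_feature_matrix(expr, sets, ratio = 0.5),
                 "skipped")
  expect_equal(names(attr(f, "block_index")), "ok")
  expect_error(
    suppressWarnings(build_feature_matrix(
      expr, list(functional_gene_set("gone", "x")), ratio = 0.5)),
    "no functional gene set")
  raw <- expression_matrix(matrix(1:12, 4, 3))
  expect_error(build_feature_matrix(raw, sets, 0.5), "log-transformed")
})

test_that("feature extraction is deterministic", {
  set.seed(12)
  expr <- log_transform(expression_matrix(
    matrix(stats::rlnorm(30 * 10), 30, 10,
           dimnames = list(NULL, sprintf("g%02d", 1:10)))))
  sets <- list(functional_gene_set("s1", sprintf("g%02d", 1:5)),
               functional_gene_set("s2", sprintf("g%02d", 4:10)))
  f1 <- build_feature_matrix(expr, sets, ratio = 0.4)
  f2 <- build_feature_matrix(expr, sets, ratio = 0.4)
  expect_identical(f1, f2)
})
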