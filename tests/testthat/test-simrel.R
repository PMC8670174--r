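# A small chain ontology with controlled term frequencies: the
# frequency_override hook pins P() so SimRel values can be evaluated by
# hand.
chain_with_freq <- function(freq) {
  g <- ontology_graph(
    terms = c("root", "mid", "a", "b"),
    name = stats::setNames(rep("t", 4), c("root", "mid", "a", "b")),
    namespace = stats::setNames(rep("BP", 4), c("root", "mid", "a", "b")),
    parents = list(root = character(), mid = "root", a = "mid", b = "mid"))
  am <- propagate(g, annotation_map(list(g1 = "a", g2 = "b")),
                  frequency_override = freq)
  list(graph = g, annot = am)
}

test_that("simrel of a term with itself is 1 - P(t)", {
  fx <- chain_with_freq(c(root = 1, mid = 0.5, a = 0.25, b = 0.25))
  expect_equal(simrel(fx$graph, fx$annot, "a", "a"), 0.75)
  expect_equal(simrel(fx$graph, fx$annot, "mid", "mid"), 0.5)
})

test_that("terms meeting only at the root have similarity 0", {
  g <- ontology_graph(
    terms = c("root", "a", "b"),
    name = stats::setNames(rep("t", 3), c("root", "a", "b")),
    namespace = stats::setNames(rep("BP", 3), c("root", "a", "b")),
    parents = list(root = character(), a = "root", b = "root"))
  am <- propagate(g, annotation_map(list(g1 = "a", g2 = "b")))
  expect_equal(unname(am$frequency[["root"]]), 1)
  expect_equal(simrel(g, am, "a", "b"), 0)
})

test_that("simrel evaluates the scaled Lin formula", {
  # P(a) = P(b) = 0.25, P(MIA) = 0.5:
  # 2 log 0.5 / (log 0.25 + log 0.25) * (1 - 0.5) = 0.5 * 0.5 = 0.25
  fx <- chain_with_freq(c(root = 1, mid = 0.5, a = 0.25, b = 0.25))
  expect_equal(simrel(fx$graph, fx$annot, "a", "b"), 0.25)
})

test_that("simrel is symmetric and bounded by 1 - P(MIA)", {
  am <- dag5_annotations()
  g <- dag5()
  tms <- c("L1", "L2", "M1", "M2")
  for (i in seq_along(tms)) {
    for (j in seq_along(tms)) {
      s1 <- simrel(g, am, tms[[i]], tms[[j]])
      expect_equal(s1, simrel(g, am, tms[[j]], tms[[i]]))
      common <- intersect(ancestors(g, tms[[i]], include_self = TRUE),
                          ancestors(g, tms[[j]], include_self = TRUE))
      p_mia <- min(am$frequency[common])
      expect_lte(s1, 1 - p_mia + 1e-12)
      expect_gte(s1, 0)
    }
  }
})

test_that("cross-namespace pairs are rejected", {
  g <- ontology_graph(
    terms = c("bpR", "ccR"),
    name = stats::setNames(c("t", "t"), c("bpR", "ccR")),
    namespace = stats::setNames(c("BP", "CC"), c("bpR", "ccR")),
    parents = list(bpR = character(), ccR = character()))
  am <- propagate(g, annotation_map(list(g1 = "bpR", g2 = "ccR")))
  expect_error(simrel(g, am, "bpR", "ccR"), "namespace")
})

enriched_fixture <- function(terms, pvals, M, graph, annot) {
  data.frame(term = terms, name = terms, namespace = "BP",
             k = 2L, n = 4L, M = M, N = 8L,
             p_value = pvals, q_value = pvals,
             genes = I(lapply(terms, function(tm)
               annot$term_genes[[tm]])))
}

test_that("the smaller p-value survives among similar siblings", {
  fx <- chain_with_freq(c(root = 1, mid = 0.5, a = 0.25, b = 0.25))
  df <- enriched_fixture(c("a", "b"), c(1e-3, 1e-8), c(5L, 5L),
                         fx$graph, fx$annot)
  # siblings: no ancestry; simrel(a, b) = 0.25 >= cutoff 0.2
  out <- reduce_terms(df, fx$graph, fx$annot, cutoff = 0.2)
  expect_equal(out$term, "b")
  mapping <- attr(out, "mapping")
  expect_equal(mapping$discarded, "a")
  expect_equal(mapping$representative, "b")
  expect_equal(mapping$similarity, 0.25)
})

test_that("an ancestor represents its descendant regardless of p-values", {
  fx <- chain_with_freq(c(root = 1, mid = 0.5, a = 0.25, b = 0.25))
  # simrel(mid, a): MIA = mid, 2 log .5 / (log .5 + log .25) * .5 = 0.333
  df <- enriched_fixture(c("mid", "a"), c(1e-2, 1e-9), c(6L, 5L),
                         fx$graph, fx$annot)
  out <- reduce_terms(df, fx$graph, fx$annot, cutoff = 0.3)
  expect_equal(out$term, "mid")
  # with prefer_ancestor = FALSE the p-value rule wins instead
  out2 <- reduce_terms(df, fx$graph, fx$annot, cutoff = 0.3,
                       prefer_ancestor = FALSE)
  expect_equal(out2$term, "a")
})

test_that("a cutoff above every similarity leaves the list unchanged", {
  fx <- chain_with_freq(c(root = 1, mid = 0.5, a = 0.25, b = 0.25))
  df <- enriched_fixture(c("a", "b"), c(1e-3, 1e-8), c(5L, 5L),
                         fx$graph, fx$annot)
  out <- reduce_terms(df, fx$graph, fx$annot, cutoff = 1.0)
  expect_equal(out$term, df$term)
  expect_equal(nrow(attr(out, "mapping")), 0)
})

test_that("lower cutoffs never leave more survivors", {
  am <- dag5_annotations()
  g <- dag5()
  tms <- c("L1", "L2", "M1", "M2")
  df <- data.frame(term = tms, name = tms, namespace = "BP",
                   k = 2L, n = 4L, M = lengths(am$term_genes[tms]),
                   N = 8L, p_value = c(1e-4, 1e-3, 1e-2, 1e-1),
                   q_value = c(1e-4, 1e-3, 1e-2, 1e-1),
                   genes = I(am$term_genes[tms]))
  sizes <- vapply(c(0.1, 0.3, 0.5, 0.9),
                  function(ct) nrow(reduce_terms(df, g, am, cutoff = ct)),
                  1L)
  expect_true(all(diff(sizes) >= 0))
})

test_that("surviving pairs sit below the cutoff", {
  am <- dag5_annotations()
  g <- dag5()
  tms <- c("L1", "L2", "M1", "M2")
  df <- data.frame(term = tms, name = tms, namespace = "BP",
                   k = 2L, n = 4L, M = lengths(am$term_genes[tms]),
                   N = 8L, p_value = c(1e-4, 1e-3, 1e-2, 1e-1),
                   q_value = c(1e-4, 1e-3, 1e-2, 1e-1),
                   genes = I(am$term_genes[tms]))
  cutoff <- 0.2
  out <- reduce_terms(df, g, am, cutoff = cutoff)
  surv <- out$term
  if (length(surv) > 1L) {
    for (i in seq_len(length(surv) - 1L)) {
      for (j in (i + 1L):length(surv)) {
        expect_lt(simrel(g, am, surv[[i]], surv[[j]]), cutoff)
      }
    }
  }
})
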