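test_that("parse_obo reads an is_a chain into parent edges", {
  path <- withr::local_tempfile(lines = obo_chain_text(), fileext = ".obo")
  g <- suppressMessages(parse_obo(path))
  expect_setequal(g$terms, c("A", "B", "C"))
  expect_equal(g$parents[["C"]], "B")
  expect_equal(g$parents[["B"]], "A")
  expect_length(g$parents[["A"]], 0)
  expect_equal(unname(g$namespace[["C"]]), "BP")
})

test_that("obsolete terms are set aside without edges", {
  lines <- c(obo_chain_text(),
             "[Term]", "id: D", "name: dead",
             "namespace: biological_process",
             "is_a: A", "is_obsolete: true", "")
  path <- withr::local_tempfile(lines = lines, fileext = ".obo")
  g <- suppressMessages(parse_obo(path))
  expect_false("D" %in% g$terms)
  expect_true("D" %in% g$obsolete)
  expect_null(g$parents[["D"]])
})

test_that("alt_id values resolve to the primary term", {
  lines <- c(obo_chain_text()[1:2],
             "[Term]", "id: A", "name: root",
             "namespace: biological_process", "alt_id: A_old", "")
  path <- withr::local_tempfile(lines = lines, fileext = ".obo")
  g <- suppressMessages(parse_obo(path))
  expect_equal(ancestors(g, "A_old", include_self = TRUE), "A")
})

test_that("malformed stanzas and cycles are rejected", {
  bad <- c("[Term]", "name: no id here", "")
  path <- withr::local_tempfile(lines = bad, fileext = ".obo")
  expect_error(parse_obo(path), "line 1")
  cyc <- c("[Term]", "id: X", "name: x", "namespace: biological_process",
           "is_a: Y", "",
           "[Term]", "id: Y", "name: y", "namespace: biological_process",
           "is_a: X", "")
  path2 <- withr::local_tempfile(lines = cyc, fileext = ".obo")
  expect_error(suppressMessages(parse_obo(path2)), "cycle")
})

test_that("multi-parent ancestors contain both parent lineages", {
  g <- dag5()
  # hand-enumerated closure: L2 -> {M1, M2} -> R
  expect_setequal(ancestors(g, "L2"), c("M1", "M2", "R"))
  expect_setequal(ancestors(g, "L1"), c("M1", "R"))
  expect_setequal(ancestors(g, "L2", include_self = TRUE),
                  c("L2", "M1", "M2", "R"))
})

test_that("annotation TSV and GAF readers fill the direct map", {
  tsv <- withr::local_tempfile(
    lines = c("g1\tT1", "g1\tT2", "g2\tT1"), fileext = ".tsv")
  am <- suppressMessages(parse_annotations(tsv, fmt = "tsv"))
  expect_setequal(am$direct[["g1"]], c("T1", "T2"))
  expect_equal(am$direct[["g2"]], "T1")

  gaf_row <- function(sym, term, qual = "") {
    paste(c("DB", paste0("ID_", sym), sym, qual, term,
            rep("x", 12)), collapse = "\t")
  }
  gaf <- withr::local_tempfile(
    lines = c("!gaf-version: 2.2", gaf_row("geneA", "T1"),
              gaf_row("geneB", "T2", qual = "NOT"),
              gaf_row("geneA", "T3", qual = "NOT|involved_in")),
    fileext = ".gaf")
  am2 <- suppressMessages(parse_annotations(gaf))
  expect_equal(names(am2$direct), "geneA")
  expect_equal(am2$direct[["geneA"]], "T1")
})

test_that("an empty annotation file gives an empty map without error", {
  path <- withr::local_tempfile(lines = character(), fileext = ".tsv")
  am <- parse_annotations(path, fmt = "tsv")
  expect_length(am$direct, 0)
})

test_that("propagation closes annotations under ancestry", {
  g <- dag5()
  am <- propagate(g, annotation_map(list(g1 = "L1")))
  expect_setequal(am$propagated[["g1"]], c("L1", "M1", "R"))
  expect_equal(unname(am$frequency[["R"]]), 1)   # single-gene corpus

  # two genes, chain: frequency counts by hand
  am2 <- propagate(g, annotation_map(list(g1 = "M1", g2 = "R")))
  expect_equal(unname(am2$frequency[["M1"]]), 0.5)
  expect_equal(unname(am2$frequency[["R"]]), 1)
})

test_that("frequencies are computed per namespace independently", {
  g <- ontology_graph(
    terms = c("bpR", "ccR", "bpT", "ccT"),
    name = stats::setNames(rep("t", 4), c("bpR", "ccR", "bpT", "ccT")),
    namespace = stats::setNames(c("BP", "CC", "BP", "CC"),
                                c("bpR", "ccR", "bpT", "ccT")),
    parents = list(bpR = character(), ccR = character(),
                   bpT = "bpR", ccT = "ccR"))
  am <- propagate(g, annotation_map(list(
    g1 = c("bpT", "ccT"), g2 = "bpR")))
  expect_equal(unname(am$frequency[["bpR"]]), 1)    # 2 BP genes
  expect_equal(unname(am$frequency[["bpT"]]), 0.5)
  expect_equal(unname(am$frequency[["ccR"]]), 1)    # 1 CC gene
  expect_equal(unname(am$frequency[["ccT"]]), 1)
})

test_that("propagation is idempotent and consistent with term_genes", {
  am <- dag5_annotations()
  am2 <- propagate(dag5(), am)
  expect_equal(am2$propagated, am$propagated)
  expect_equal(am2$frequency, am$frequency)
  # mutual inversion
  for (tm in names(am$term_genes)) {
    for (g in am$term_genes[[tm]]) {
      expect_true(tm %in% am$propagated[[g]])
    }
  }
  for (g in names(am$propagated)) {
    for (tm in am$propagated[[g]]) {
      expect_true(g %in% am$term_genes[[tm]])
    }
  }
})

test_that("frequency is monotone along ancestry", {
  g <- dag5()
  am <- dag5_annotations()
  for (tm in g$terms) {
    for (p in g$parents[[tm]]) {
      expect_gte(am$frequency[[p]], am$frequency[[tm]])
    }
  }
})

test_that("unknown annotated terms are dropped with a warning", {
  g <- dag5()
  expect_warning(
    am <- propagate(g, annotation_map(list(g1 = c("L1", "NOPE")))),
    "absent from the ontology")
  expect_setequal(am$propagated[["g1"]], c("L1", "M1", "R"))
})

test_that("ontology and annotations round-trip through their writers", {
  g <- dag5()
  obo <- withr::local_tempfile(fileext = ".obo")
  write_obo(g, obo)
  g2 <- suppressMessages(parse_obo(obo))
  expect_setequal(g2$terms, g$terms)
  expect_equal(g2$parents[sort(g$terms)],
               lapply(g$parents[sort(g$terms)], sort))

  am <- annotation_map(list(g1 = c("L1", "L2"), g2 = "M1"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(am, tsv)
  am2 <- suppressMessages(parse_annotations(tsv, fmt = "tsv"))
  expect_equal(lapply(am2$direct, sort), lapply(am$direct, sort))
})
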