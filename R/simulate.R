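# Synthetic fixtures: a GO-like layered DAG with block annotations and
# an expression matrix with planted cell clusters whose marker genes
# align with the term gene sets.  These emulate the input structure the
# pipeline assumes; they make no attempt at realistic scRNA-seq noise
# (no batch effects or library-size gradients).

#' Specify a synthetic fixture
#'
#' Defaults describe the standard test conditions: 200 cells in 4
#' balanced clusters over 400 dataset genes drawn from an 800-gene
#' annotation corpus (the corpus is twice the dataset so enrichment has
#' a non-trivial background), a 3-level ontology of 16 terms, 30% of
#' dataset genes acting as cluster markers shifted by 2 log10 units,
#' and 20% dropout.
#'
#' @param n_cells number of cells.
#' @param n_genes number of dataset genes (the annotation corpus holds
#'   `2 * n_genes` genes).
#' @param n_clusters number of planted cell clusters.
#' @param n_terms ontology terms per namespace (>= `depth`).
#' @param depth ontology levels including the root.
#' @param frac_marker fraction of dataset genes that are cluster
#'   markers (split evenly and disjointly across clusters).
#' @param effect mean log10-expression shift of a cluster's markers in
#'   its own cells.
#' @param dropout probability that an expressed value is zeroed.
#' @param seed random seed (fixtures are byte-identical given the seed).
#' @return a list of class `fegfs_fixture_spec`.
#' @export
fixture_spec <- function(n_cells = 200L, n_genes = 400L, n_clusters = 4L,
                         n_terms = 16L, depth = 3L, frac_marker = 0.3,
                         effect = 2, dropout = 0.2, seed = 1L) {
  spec <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
               n_clusters = as.integer(n_clusters),
               n_terms = as.integer(n_terms), depth = as.integer(depth),
               frac_marker = frac_marker, effect = effect,
               dropout = dropout, seed = as.integer(seed))
  with(spec, stopifnot(
    n_cells > 0, n_genes > 0, n_clusters > 0, n_terms > 0, depth >= 2,
    frac_marker >= 0, frac_marker <= 1, dropout >= 0, dropout <= 1,
    effect >= 0, n_clusters <= n_cells))
  if (spec$n_terms < spec$depth) {
    stop("need at least one term per level: n_terms >= depth")
  }
  structure(spec, class = "fegfs_fixture_spec")
}

syn_gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Generate a synthetic ontology with annotations
#'
#' Builds, per namespace, a rooted layered DAG: one root, intermediate
#' levels, and a deepest level of leaf terms; every non-root term has
#' 1-2 parents in the level above.  Genes (`2 * n_genes` corpus ids)
#' are annotated to leaf terms in overlapping index windows, so that
#' neighbouring leaves share genes; the first two leaves are offset so
#' their repetitive rate is at least 0.8, guaranteeing the merging stage
#' has work to do, and parent/child frequency ratios keep several
#' SimRel values above 0.4 for the semantic stage.
#'
#' @param spec a [fixture_spec()].
#' @param namespaces namespaces to generate (default `"BP"`).
#' @return a list: `graph` (an [ontology_graph()]) and `annot` (an
#'   [annotation_map()], direct annotations only).
#' @export
make_ontology <- function(spec, namespaces = "BP") {
  stopifnot(inherits(spec, "fegfs_fixture_spec"),
            all(namespaces %in% c("BP", "MF", "CC")))
  set.seed(spec$seed)
  n_corpus <- 2L * spec$n_genes
  genes <- syn_gene_ids(n_corpus)
  all_terms <- character(); nm <- character(); ns_vec <- character()
  parents <- list(); direct_pairs <- list()
  for (ns in namespaces) {
    ids <- sprintf("%s:%04d", ns, seq_len(spec$n_terms))
    # level sizes: root, evenly filled inner levels, the rest as leaves
    n_inner_lv <- spec$depth - 2L
    inner_per <- if (n_inner_lv > 0L) {
      max(2L, (spec$n_terms - 1L) %/% (3L * max(1L, n_inner_lv)))
    } else 0L
    if (1L + n_inner_lv * inner_per >= spec$n_terms) {
      stop("infeasible fixture: too few terms (", spec$n_terms,
           ") for depth ", spec$depth, "; increase n_terms")
    }
    level <- integer(spec$n_terms)
    level[1L] <- 1L
    pos <- 2L
    if (n_inner_lv > 0L) {
      for (lv in seq_len(n_inner_lv) + 1L) {
        level[pos:(pos + inner_per - 1L)] <- lv
        pos <- pos + inner_per
      }
    }
    level[pos:spec$n_terms] <- spec$depth
    leaves <- ids[level == spec$depth]
    mids <- ids[level == spec$depth - 1L]   # the root itself when depth = 2
    for (i in seq_len(spec$n_terms)) {
      tm <- ids[[i]]
      all_terms <- c(all_terms, tm)
      nm[[tm]] <- paste0("synthetic ", ns, " term level ", level[[i]])
      ns_vec[[tm]] <- ns
      pool <- ids[level == level[[i]] - 1L]
      if (level[[i]] == spec$depth && spec$depth >= 3L) {
        # the high-overlap leaf pair shares a dedicated parent, and no
        # other leaf joins it: that parent's gene set stays close to its
        # children's, keeping their SimRel values comfortably above 0.4
        leaf_pos <- match(tm, leaves)
        pool <- if (leaf_pos <= 2L) mids[1L] else {
          if (length(mids) > 1L) mids[-1L] else mids
        }
      }
      parents[[tm]] <- if (level[[i]] == 1L) character() else {
        sort(sample(pool, size = min(length(pool), sample(1:2, 1L))))
      }
    }
    L <- length(leaves)
    s <- max(2L, n_corpus %/% L)
    w <- min(n_corpus, 2L * s)
    starts <- (seq_len(L) - 1L) * s + 1L
    # pull the second leaf towards the first: overlap 2s - floor(s/5),
    # min size 2s  ->  rate >= 0.9 > 0.8
    if (L >= 2L) starts[[2L]] <- starts[[1L]] + max(1L, s %/% 5L)
    for (j in seq_len(L)) {
      win <- genes[starts[[j]]:min(starts[[j]] + w - 1L, n_corpus)]
      for (g in win) direct_pairs[[g]] <- c(direct_pairs[[g]], leaves[[j]])
    }
  }
  graph <- ontology_graph(all_terms, nm, ns_vec, parents)
  annot <- annotation_map(direct_pairs)
  # sanity: the designed high-overlap leaf pair really is above 0.8
  chk <- propagate(graph, annot)
  leaf_ids <- unique(unlist(annot$direct, use.names = FALSE))
  leaf_sets <- chk$term_genes[intersect(names(chk$term_genes), leaf_ids)]
  if (length(leaf_sets) >= 2L) {
    top <- max(rate_matrix(lapply(names(leaf_sets), function(tm)
      functional_gene_set(tm, leaf_sets[[tm]]))) -
        diag(length(leaf_sets)))
    if (top < 0.8) stop("infeasible fixture: no leaf pair reaches ",
                        "repetitive rate 0.8 (max ", round(top, 3), ")")
  }
  list(graph = graph, annot = annot)
}

#' Generate a planted-cluster expression matrix
#'
#' Cells are split evenly into `n_clusters`; baseline expression is
#' log-normal (meanlog 1, sdlog 0.5); each cluster's marker-gene block
#' (disjoint slices of the dataset genes, which the ontology annotates)
#' is multiplied by `10^effect`, i.e. shifted by `effect` in log10
#' space, in that cluster's cells; dropout then zeroes each value
#' independently with probability `dropout`.
#'
#' @param spec a [fixture_spec()].
#' @param annot optional [annotation_map()] from [make_ontology()]
#'   (used only to check that marker genes are annotated).
#' @return a list: `expr` (a raw [expression_matrix()], cells x genes)
#'   and `truth` (named integer vector of planted cluster labels).
#' @export
make_expression <- function(spec, annot = NULL) {
  stopifnot(inherits(spec, "fegfs_fixture_spec"))
  set.seed(spec$seed + 1L)
  n <- spec$n_cells; m <- spec$n_genes; k <- spec$n_clusters
  genes <- syn_gene_ids(2L * m)[seq_len(m)]
  cells <- sprintf("cell_%04d", seq_len(n))
  truth <- stats::setNames(sort(rep_len(seq_len(k), n)), cells)
  values <- matrix(stats::rlnorm(n * m, meanlog = 1, sdlog = 0.5), n, m,
                   dimnames = list(cells, genes))
  n_marker <- floor(spec$frac_marker * m)
  per <- n_marker %/% k
  if (per >= 1L && spec$effect > 0) {
    for (c_ in seq_len(k)) {
      block <- genes[((c_ - 1L) * per + 1L):(c_ * per)]
      if (!is.null(annot)) {
        unann <- setdiff(block, names(annot$direct))
        if (length(unann)) warning(length(unann),
                                   " marker gene(s) not annotated")
      }
      values[truth == c_, block] <- values[truth == c_, block] *
        10^spec$effect
    }
  }
  if (spec$dropout > 0) {
    drop <- matrix(stats::runif(n * m) < spec$dropout, n, m)
    values[drop] <- 0
  }
  list(expr = expression_matrix(values, cells, genes),
       truth = truth)
}

#' Write a complete fixture bundle to a directory
#'
#' Emits `ontology.obo`, `annotations.tsv` (two-column), `expr.csv`
#' (cells x genes, cell ids in the first column) and `truth.tsv`, all
#' re-readable by the package's parsers.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return named character vector of the four file paths, invisibly.
#' @export
write_fixture_bundle <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  onto <- make_ontology(spec)
  em <- make_expression(spec, onto$annot)
  paths <- c(obo = file.path(dir, "ontology.obo"),
             annot = file.path(dir, "annotations.tsv"),
             expr = file.path(dir, "expr.csv"),
             truth = file.path(dir, "truth.tsv"))
  write_obo(onto$graph, paths[["obo"]])
  write_annotations(onto$annot, paths[["annot"]])
  write_expression(em$expr, paths[["expr"]])
  write_labels(em$truth, paths[["truth"]])
  invisible(paths)
}
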