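---
title: "Functional gene set feature extraction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional gene set feature extraction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Cell clustering from single-cell RNA-seq is dominated by the geometry of
the full expression matrix: tens of thousands of genes, most of them
uninformative for cell identity, with heavy dropout. `fegfs` restructures
the problem around gene function. Genes are grouped into functional gene
sets derived from Gene Ontology terms, redundancy between those sets is
reduced in two stages, each set's expression submatrix is compressed
separately by kernel PCA, and cells are clustered on the concatenation of
the compressed blocks. The working assumption is that cell types differ
in the coordinated expression of functional modules, so a per-module
compression preserves cluster signal that a global decomposition spreads
thin.

## Ontology and annotation model

The ontology is held as a DAG per namespace (biological process,
molecular function, cellular component) with `is_a` and `part_of` edges
as parent links; the regulates-family relations are ignored, as is usual
in enrichment tooling. Obsolete terms are excluded from every query and
alternative ids resolve to their primary term. Annotations are closed
under ancestry (the true-path rule) before anything downstream sees
them.

A term's relative frequency `P(t)` — the information-content input of
SimRel — is the fraction of genes annotated in the term's namespace that
carry the term after propagation. It is computed from the annotation
corpus the user supplies, not from any fixed external database: a
self-contained corpus keeps results reproducible and makes the frequency
consistent with the background actually used by the enrichment test. A
named-vector override (`propagate(..., frequency_override =)`) is the
hook for users who prefer frequencies from a large reference corpus.
Frequencies are monotone along ancestry and each namespace root has
frequency 1.

## Enrichment

Over-representation of the input gene list is tested per namespace. The
printed form of the test statistic is a hypergeometric point mass; an
over-representation decision needs a tail, and the upper tail
`P(X >= k)` is the universal convention, so that is what
`hypergeom_pvalue()` returns. The background `N` is the number of corpus
genes annotated in the namespace (there is no separate genome universe
once the corpus is self-contained), `n` the annotated input genes, `M`
the term's corpus count and `k` the overlap. FDR control is
Benjamini–Hochberg within each namespace, because `n` and `N` are defined
per namespace and mixing the three DAGs would couple tests with different
backgrounds. Defaults: `alpha = 0.05`, `min_genes = 2` (singleton hits
carry no set structure worth compressing; configurable).

## Semantic reduction

SimRel scales the Lin ratio by `1 - P(MIA)`, so similarity through a very
general shared ancestor counts for little and terms meeting only at the
root score exactly 0. The most informative ancestor is the common
ancestor with minimal frequency; if several tie, the lexicographically
smallest id is taken, purely for determinism. Logs are natural — the Lin
ratio is base-invariant.

Reduction is greedy, highest-similarity pair first (the published
REVIGO-style procedure), collapsing pairs with similarity at or above
the cutoff (default 0.4). The representative of a pair is the ancestor
when one term is an ancestor of the other — the "father" node — and
otherwise the term with the smaller p-value, ties broken by larger
corpus set then smaller id. `prefer_ancestor = FALSE` switches to the
pure p-value rule. Similarity is only defined within a namespace, so
reduction never crosses namespaces. Surviving terms keep their original
input-gene sets: reduction selects representatives, it does not merge
genes.

## Repetitive-rate reduction

The repetitive rate `|A ∩ B| / min(|A|, |B|)` is deliberately not
Jaccard: it measures how much of the *smaller* set is duplicated, so a
small set inside a big one scores 1 regardless of the size gap. The
screen alternates two moves:

* **coverage filtering** — any set fully covered by another (rate 1) is
  removed, the larger set retained; among identical sets the smallest id
  survives;
* **one merging pass** — best-first pairwise matching: the pair with the
  highest rate at or above the threshold (default 0.8; ties by larger
  union then smaller ids) is replaced by its union, and a set merged in
  this pass is not merged again until the next round.

Freezing newly merged sets for the rest of the pass is the design choice
that makes repeated screening meaningful: if a pass instead merged to
its own fixpoint, every rate would fall below the threshold after one
round and a second screening could never do anything, which would make
the documented two-round behaviour vacuous. With per-pass matching, a
chain A~B~C merges A+B in round one and (A+B)+C in round two. The
default is exactly two rounds; `until_converged = TRUE` repeats rounds
until nothing changes, which guarantees all final pairwise rates are
below the threshold (a warning reports the maximum remaining rate when a
fixed round count stops short). Both moves conserve the union of genes:
coverage removal deletes only true subsets, merging takes unions.

The sets screened here are the *input-gene* overlaps from enrichment,
not full corpus sets — the quantities being compressed downstream are
columns of the user's expression matrix, so redundancy must be measured
on the genes that are actually present.

## Feature extraction

Noise genes are removed before the log transform: a gene must be
expressed (strictly positive) in at least `3 × max(1, ⌊0.01 n⌋)` cells.
The inner floor is clamped at 1 so the rule stays meaningful below 100
cells. Values are then `log10(x + 1)`.

Each functional gene set's submatrix is reduced by KPCA with the cosine
kernel. The kernel is computed on the log-transformed values as they
are; genes are not re-centred per set, because the kernel is a function
of whole cell profiles and per-set centring would break the invariance
of the kernel to positive rescaling of a cell. Zero cell profiles within
a set (all set genes dropped out in that cell) get kernel row 0 with
unit diagonal, with a warning. The kernel matrix is double-centred in
feature space and eigendecomposed (base `eigen`, symmetric);
eigenvalues below `1e-10 ×` the largest are treated as numerical zeros.

The retention ratio — 40% up to 1000 cells, 60% up to 3000, 80% above —
is interpreted as the retained fraction of positive kernel eigenvalue
mass (explained variance), not of the component count: that is the
common reading of a "principal component retention ratio", and a
count-based reading would multiply feature width by the number of sets
into the thousands. `build_feature_matrix(..., ratio =)` accepts any
value in (0, 1] for users who want the other reading at a chosen
fraction. The size brackets are half-open at the top (`≤ 3000` takes
60%, `> 3000` takes 80%). At least one component is always kept per
set, and component signs are fixed (largest-magnitude loading positive)
so runs are bit-reproducible.

## Clustering and evaluation

Clustering is bottom-up agglomerative merging under Euclidean distance
in the concatenated feature space. The linkage is a free choice — the
method itself only requires "merge the closest sample sets" — and
defaults to Ward (`hclust` `ward.D2`), the variance-minimising criterion
that pairs naturally with Euclidean distances; average, complete and
single linkage are available. The number of clusters `k` is a required
input: the method is evaluated with known type counts and no estimator
of `k` is provided.

Four external scores compare a clustering to reference labels. ARI is
the Hubert–Arabie chance-corrected pair-counting index. NMI is
`2I/(H_t + H_p)` with the plug-in mutual information from the
contingency table; mutual information is non-negative by construction,
and two identical trivial partitions are defined to agree perfectly.
Homogeneity and completeness need a cluster-to-class correspondence
that the score definitions leave open when cluster and class counts
differ; the default matches each predicted cluster to its majority class
(ties to the smallest class index) and averages the matched fraction
over predicted clusters — homogeneity over cluster sizes, completeness
over matched class sizes. `matching = "optimal"` instead uses the exact
one-to-one assignment maximising the total matched count (exhaustive
search, practical to 10 clusters). All four scores are invariant to
relabelling.

## The synthetic fixture generator

`fixture_spec()` / `make_ontology()` / `make_expression()` build the
study conditions the test-suite runs under: a layered single-namespace
DAG (16 terms, depth 3 by default) whose leaf terms annotate overlapping
index windows over an 800-gene corpus, and a 200-cell expression matrix
over the first 400 corpus genes with 4 balanced planted clusters. The
corpus is twice the dataset so the enrichment background is non-trivial
(every term would otherwise have `k = M` and no term could be
significant). Two leaves are built with ~0.9 window overlap and share a
dedicated parent, guaranteeing the repetitive-rate screen and the
semantic screen both have work to do on every generated fixture.

Expression is log-normal (meanlog 1, sdlog 0.5) with 30% of dataset
genes acting as markers, split disjointly across clusters; a cluster's
markers are multiplied by `10^effect` (default `effect = 2`, i.e. a
2-unit shift in log10 space) in its own cells, then dropout zeroes each
entry with probability 0.2. These defaults are a deliberately strong,
clean signal — distinct cell types with ~100-fold marker shifts and
moderate dropout — chosen once as the regime in which the pipeline
should succeed essentially perfectly; `effect = 0` gives the matched
null with no signal at all. The generator emulates structure, not
realism: no batch effects, library-size gradients, negative-binomial
overdispersion or gene–gene correlation beyond the planted blocks. A
pipeline that recovers these planted clusters is shown to be wired
correctly end-to-end; that is evidence of correctness, not of expected
accuracy on real tissue.

Test problem sizes are kept small by design — fixtures of 40–200 cells,
120–400 genes and 10–16 terms, oracle sweeps up to background size 40
(hypergeometric) and 20 × 30 matrices (KPCA) — sizes at which exact
enumeration oracles are feasible and the whole suite runs in seconds.

## Degenerate inputs and numerical conventions

* Hypergeometric arguments are bound-checked; `k = 0` returns 1.
* Empty p-value collections adjust to empty; q-values are clipped to
  [0, 1].
* A fully degenerate kernel (all cells identical in a set) yields one
  zero component rather than an error.
* Sets with no gene present in the expression matrix are skipped with a
  warning; losing every set is an error.
* All tie-breaks (MIA choice, merge order, representative choice,
  coverage among identical sets) are lexicographic after the scientific
  criteria, so every stage is deterministic.

## Limitations

Gene identifiers are matched as exact strings; no id conversion is
attempted, so the expression matrix and annotation corpus must share a
vocabulary. Enrichment offers no ordered-query mode and no
under-representation test. The two-round default of the redundancy
screen reproduces the documented behaviour but is not a convergence
guarantee — use `until_converged = TRUE` when a redundancy-free panel
matters more than faithfulness to the two-pass recipe. Homogeneity and
completeness depend on the matching rule when cluster and class counts
differ; both rules are reported options rather than a single canonical
definition.
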