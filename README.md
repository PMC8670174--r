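# fegfs

Functional gene set feature extraction (FEGFS) for single-cell RNA-seq
cell clustering.

Most scRNA-seq clustering methods measure cell-to-cell similarity on the
whole expression matrix, ignoring what the genes *do*. FEGFS instead
derives a panel of non-redundant, Gene-Ontology-based functional gene
sets from the data, compresses the expression submatrix of each set with
kernel PCA, and clusters cells on the concatenated compressed features.
It is aimed at analysts who have a cell × gene expression matrix, a GO
ontology (OBO) and gene annotations (GAF or two-column TSV), and known
or suspected cluster counts.

## Method

1. **Preprocessing.** Genes expressed in fewer than
   `3 × max(1, ⌊0.01 · n_cells⌋)` cells are removed as noise (for 301
   cells the threshold is 9), then values are transformed as
   `F(x) = log10(x + 1)`.
2. **Enrichment.** Each namespace (BP/MF/CC) is tested separately:
   for a term with `M` of the `N` namespace background genes, and `k`
   of the `n` input genes, the p-value is the upper hypergeometric tail
   `P(X ≥ k)`; Benjamini–Hochberg FDR ≤ 0.05 defines the significant
   terms.
3. **Semantic reduction.** Similar terms are collapsed with SimRel
   similarity,

   `sim(g1, g2) = [2 log P(MIA) / (log P(g1) + log P(g2))] · (1 − P(MIA))`,

   where `P(·)` is the relative annotation frequency after true-path
   propagation and `MIA` the most informative common ancestor. Pairs
   with `sim ≥ 0.4` are repeatedly collapsed, keeping the ancestor
   (else the smaller p-value) as representative.
4. **Repetitive-rate reduction.** For gene sets `A`, `B` the repetitive
   rate is `|A ∩ B| / min(|A|, |B|)`. Fully covered sets (rate 1) are
   dropped in favour of the larger set; then pairs with rate ≥ 0.8 are
   merged into union sets, and the screen (coverage filter + one
   merging pass) is run twice by default, or to convergence.
5. **Feature extraction.** Each surviving set's cells × genes
   submatrix goes through cosine-kernel KPCA
   (`κ(x_i, x_j) = ⟨x_i, x_j⟩ / (‖x_i‖‖x_j‖)`, double-centered kernel,
   eigendecomposition), keeping enough components to reach a retention
   ratio of 40% (≤ 1000 cells), 60% (1000–3000) or 80% (> 3000) of the
   positive kernel eigenvalue mass. The blocks are concatenated into
   the final feature matrix.
6. **Clustering + evaluation.** Agglomerative hierarchical clustering
   (Euclidean, Ward by default) into `k` clusters, scored against
   reference labels with ARI, NMI, homogeneity (HOM) and completeness
   (COM).

## Worked example

The package ships a synthetic-fixture generator (layered GO-like DAG,
overlapping leaf annotations, planted cell clusters) so the whole
pipeline runs without downloads:

```r
library(fegfs)
spec <- fixture_spec(n_cells = 120, n_genes = 240, n_clusters = 3,
                     n_terms = 12, seed = 42)
onto <- make_ontology(spec)
em   <- make_expression(spec, onto$annot)
res  <- run_pipeline(pipeline_config(k = 3), expr = em$expr,
                     graph = onto$graph, annot = onto$annot,
                     truth = em$truth)
#> noise filter (threshold 3 cells): kept 240 of 240 genes
#> enriched terms: 4
#> terms after semantic reduction: 2
#> functional gene sets after repetition reduction: 2
#> feature matrix: 120 cells x 18 features (retention ratio 0.4)
#> metrics: ARI=1 NMI=1 HOM=1 COM=1
res$metrics
#>   ari nmi hom com
#> 1   1   1   1   1
```

Reading the log: 4 GO terms are significantly enriched in the 240
dataset genes; SimRel collapses them to 2 representatives; the
repetitive-rate screen leaves 2 functional gene sets; cosine-kernel
KPCA at the 40% retention ratio (120 cells ≤ 1000) yields 18 features;
Ward clustering recovers the 3 planted clusters exactly (all four
agreement scores equal 1).

The same pipeline is available from a shell:

```sh
Rscript inst/cli/fegfs.R simulate --spec fixture.cfg --out sim/
Rscript inst/cli/fegfs.R run --expr sim/expr.csv --obo sim/ontology.obo \
    --annot sim/annotations.tsv --truth sim/truth.tsv --k 3 --out sim/out
```

Subcommands: `simulate`, `enrich`, `reduce`, `features`, `cluster`,
`evaluate`, `run`.

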