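# snthyro

A tested, reusable R implementation of a single-nucleus RNA-seq
characterization pipeline for pediatric thyroid tissue. It covers the full
analysis path from 10x-style count triplets to annotated cell populations:

* **QC and normalization** — cells kept with 200–3,000 detected genes and
  ≤ 15% mitochondrial counts; `ln(1 + 10^4 · count / total)` normalization;
  vst-style selection of 2,000 highly variable genes; centering/scaling with
  a +10 cap.
* **Clustering** — 50 principal components with the retained number chosen
  to reach 90% of the computed variance; a shared-nearest-neighbor graph
  (k = 20, Jaccard weights, 1/15 prune); Leiden modularity clustering at
  resolutions 0.1–0.8 by 0.1; a resolution tree that flags over-clustering
  and an explicit, auditable schema-selection plan.
* **Markers** — one-vs-rest Wilcoxon rank-sum tests (exact for small
  tie-free problems) with BH adjustment; annotation markers at
  padj ≤ 0.05, log2FC ≥ 4, detection ≥ 25%; cross-sample conserved markers
  (max-p combination); a fold-ratio rule for subcluster-unique genes
  (3× the next cluster's mean, with a 0.25 expression floor); binned-control
  cell-cycle scoring.
* **Rare-cell detection** — per sample, non-zero raw counts of a marker gene
  (`CALCA` for thyroid C cells) are z-scored and cells with z ≥ 1.96
  (central 95% normal coverage) are called.
* **Sample similarity** — cluster-by-sample composition tables with
  Spearman correlations of proportions and of per-sample mean expression.
* **Preranked enrichment** — implemented from scratch: weighted
  Kolmogorov–Smirnov running-sum statistic, gene-label permutation null
  with add-one p-values, NES, BH adjustment at padj ≤ 0.1, and
  intersection/union algebra for pathways shared across or unique to
  clusters.

Because the tissue data this analysis style targets is typically not
publicly deposited, the package ships a first-class, seeded synthetic-data
module (`simulation_config()` / `simulate_counts()`) whose defaults emulate
the statistical structure of a three-donor pediatric thyroid dataset: a
dominant thyrocyte class (~92%) split into seven latent subtypes (the
largest, ~61%, deliberately carries no unique program), minor stromal and
immune classes at 0.4–4% with donor-specific shifts, and a ~0.04% C-cell
class defined by a single high-count marker. Every recovery claim in the
test suite is made against this generator's planted ground truth.

## Worked example

```r
library(snthyro)

# simulate a small three-donor thyroid dataset with planted structure
cfg <- simulation_config(n_genes = 700,
                         samples = c(C1 = 500, C2 = 450, C3 = 400),
                         seed = 7)
sim <- simulate_counts(cfg)
sim$counts
#> count_matrix: 700 genes x 1350 cells, 3 samples (C1, C2, C3)

t <- pipeline_thresholds(min_genes = 50)   # the demo simulation is shallow
qc <- compute_cell_qc(sim$counts, mito = "MT-")
filt <- filter_cells(sim$counts, qc, t)
#> cells kept: 1347 of 1350
expr <- lognormalize(filt, t$normalize_scale)

scl <- scale_center(expr, select_hvgs(filt, 400), t$scale_clip)
pca <- run_pca(scl, 30)
retain_components(pca, 0.90)
#> [1] 26
g <- build_snn_graph(pca, t$k_neighbors, t$snn_prune, n_dims = 26)
labs <- cluster_multires(g, t$resolutions, seed = 7)
final <- select_schema(labs, resolution_tree(labs))
#> default rule: highest unflagged resolution (0.8) -> 6 clusters

detect_rare_cells(filt, "CALCA", t$rare_z)$calls
#>      barcode sample count        z
#> 1 c000499-C1     C1    23 2.714062
#> 2 c000500-C1     C1    33 4.086340
#> 3 c000949-C2     C2    22 2.988253
#> 4 c000950-C2     C2    23 3.148208
#> 5 c001158-C3     C3     3 2.558832
```

The detector finds all four planted C cells (donors C1 and C2 were
configured with two each; C3 with none — its single call is a borderline
background cell, illustrating why calls are reported with their counts and
z-scores rather than as bare barcodes). Composition similarity across the
three donors:

```r
round(correlation_matrix(cluster_proportions(final, expr$sample)), 3)
#>       C1    C2    C3
#> C1 1.000 0.986 0.986
#> C2 0.986 1.000 1.000
#> C3 0.986 1.000 1.000
```

`run_pipeline()` drives all stages end to end from a YAML config (see
`inst/extdata/demo_config.yaml`), caching TSV artifacts and a JSON run
report; `inst/scripts/snthyro.R` is a thin command-line wrapper with
`pipeline` / `simulate` / `rarecells` / `enrich` subcommands.

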