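# SparseConnectome

Subject-specific sparse functional connectomes from regional time series,
node-level graph metrics, statistically controlled node selection, and
leave-one-out SVM evaluation — with a synthetic-cohort generator so the
whole pipeline is testable end to end without any imaging data.

## Who this is for

Researchers analysing regional (ROI-level) time series — e.g. parcellated
resting-state BOLD signals — who want per-subject *sparse* connectivity
graphs obtained by optimization rather than by thresholding a dense
correlation matrix, and an interpretable, leakage-aware downstream analysis
of which nodes separate two groups.

## The model

For each subject with time series $X \in \mathbb{R}^{T\times N}$, pairwise
squared distances $Z_{ij}=\lVert x_i-x_j\rVert_2^2$ enter the graph-learning
problem

$$\min_{W \ge 0,\, W=W^\top,\, \mathrm{diag}(W)=0}
\ \lVert W\circ Z\rVert_{1,1}\ -\ \alpha\sum_i \log d_i\ +\ \beta\lVert W\rVert_F^2 ,
\qquad d_i=\textstyle\sum_j W_{ij},$$

solved by a deterministic primal-dual splitting (Rcpp backend). The
log-degree barrier keeps every region connected; the learned weights are
rescaled ($\delta=2$), symmetrized and pruned below 0.03. Six local metrics
(degree, clustering, betweenness, nodal distance, local efficiency, local
assortativity) are computed per node; Welch's *t*-tests with
Benjamini–Hochberg FDR control rank nodes; a class-weighted linear SVM under
leave-one-out cross-validation (with selection nested inside each fold by
default) measures the discriminative power of the top-*k* nodes.

## Worked example

```r
library(SparseConnectome)

spec    <- cohortSpec(nNodes = 30, nGroupA = 12, nGroupB = 16, seed = 42)
cohort  <- generateCohort(spec)             # planted degree effect at nodes 1-5
connectomes <- buildConnectomes(cohort$timeSeries)
connectomes[[1]]
#> Connectome 'sub-001': 30 nodes, 79 edges (density 0.182)

labels  <- cohort$phenotype$group
metrics <- computeAllMetrics(connectomes, labels)   # SummarizedExperiment, 6 assays

sel <- selectFeatures(metrics, labels, metric = "degree", k = 5)
sel
#> NodeSelection (degree): 30 nodes tested, 20 significant at q = 0.05
#>   selected: 20, 12, 1, 4, 3

cv <- loocvEvaluate(metrics, labels, cvConfig(k = 5), metric = "degree")
cv
#> CVResult (degree, nested selection, k = 5): n = 28
#>   accuracy 0.893, sensitivity 0.833, specificity 0.938, precision 0.909, F1 0.870
```

The generator planted 3 extra edges at nodes 1–5 in the "case" group; the
selection stage recovers planted nodes among its top hits (alongside nodes
that gained the planted edges' far endpoints), and the degree-based
classifier separates the groups well above the 16/28 majority rate. At the
default cohort scale (50 nodes, 74 + 98 subjects) degree reaches ≈ 0.95–0.97
mean accuracy across seeds while the other metrics stay lower — see the
vignette (`vignettes/sparse-connectome-pipeline.Rmd`) for the model,
parameter and generator-design details.

File-based workflows use `writeCohort()` / `loadCohort()` (TSV time series +
phenotype CSV, with the inclusive T ≥ 140 scan-length filter) and
`runPipeline(pipelineConfig(...))`, which writes connectome edge lists,
metric tables, selection tables, performance and k-sweep tables,
violin-plot data and a checksummed manifest.

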