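# pathdist

Pathway-based distance scores for clustering gene-expression samples.

Distance-based unsupervised clustering is the standard route to disease
subtypes ("endotypes") in transcriptomics, but Euclidean distance over all
genes weights every transcript equally, ignores co-regulation, and buries
weak subtype signal under tens of thousands of uninformative genes.
`pathdist` instead clusters the samples once per pre-defined pathway —
a multivariate Gaussian mixture over the pathway's member genes, with the
number of components selected by BIC — and scores a pair of samples by how
often the informative pathways disagree about them:

```
d(j1, j2) = #{k : c_j1^k != c_j2^k, m_k > 1} / #{k : m_k > 1}
```

where `c_j^k` is sample `j`'s cluster under pathway `k` and `m_k` the
BIC-selected component count (single-cluster pathways abstain). The score
matrix is re-embedded as a data matrix (one column per sample, Euclidean
distance between columns) and the number of clusters is chosen by the
connectivity criterion. Pathways too large for a mixture at cohort sample
sizes are handled by downsampling: many small random gene subsets vote, and
the subset-vote distance is clustered once per pathway.

The package also ships the block-covariance simulator and benchmark harness
used to validate the method: three sample groups with mean shifts
`-δ / 0 / +δ` on a chosen fraction of pathway genes (pooled marginal
variance `σ² = 1 + 2δ²/3`), within-pathway equicovariance `ρ`, background
variance factor `B`, plus connectivity/Dunn internal validation and purity
against planted labels — so the method can be exercised and compared
against plain Euclidean distances with no external data.

## Worked example

```r
library(pathdist)

sets <- generate_synthetic_genesets(186, 10)          # 186 disjoint 10-gene pathways
ds   <- simulate_dataset(sim_config(delta = 1.5, p_w = 0.2, p_g = 0.8),
                         sets, seed = 1)              # 120 samples, 3 groups of 40

res <- pathway_distance(ds$expr, sets, seed = 1)
res$score
#> <score_matrix> 120 samples, 37 voting pathway(s)

sel <- select_k_connectivity(res$distance, features = res$score,
                             method = "kmeans", opts = eval_options(seed = 1))
sel$k
#> [1] 3
purity(sel$partition, ds$truth)
#> [1] 1
```

Exactly 37 of the 186 pathways (the 20% simulated as group-associated) find
more than one cluster and vote; the connectivity criterion selects k = 3,
and the partition at k = 3 reproduces the planted groups perfectly
(purity 1). The same cohort clustered with all-gene Euclidean distance
selects k = 2 with purity 0.667 — the signal of ~300 differential genes is
lost among 22,148.

`tidy()` / `glance()` give tibble views of every result object
(per-pathway labels, BIC traces, benchmark records), and `autoplot()`
draws the score heatmap, the connectivity trace, and benchmark summaries.

A command-line interface (`exec/pathdist`) exposes the pipeline as
`simulate`, `score`, `cluster`, `evaluate` and `benchmark` subcommands over
tab-separated files; see `?pathdist_cli`.

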