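# micascade

Cascading-failure robustness analysis of mutual-information gene networks.

Gene co-dependence networks built from expression profiles differ between
healthy and diseased tissue not only in which edges they contain but in how
*fragile* they are: how much of the network unravels when a single gene
(node) is knocked out and the transport load it carried is forced onto
other genes.  `micascade` implements that analysis end to end for
researchers in systems biology who want a tested, reproducible version of
the betweenness-load cascade methodology: build per-condition
mutual-information (MI) networks, simulate load-capacity cascades under
every single-node removal, quantify robustness across a coarse-graining
threshold sweep, and classify *structural key genes* (SKGs) — genes whose
removal collapses the network in some conditions but not in others.

## The model

For genes A, B with profiles discretized into K = 20 equal-frequency bins,

- mutual information: *I(A,B) = H(A) + H(B) − H(A,B)* (bits), with *H* the
  plug-in Shannon entropy;
- normalized MI: *m_AB = I(A,B) / min(H(A), H(B))* ∈ [0, 1];
- network at threshold *T*: edge (i,j) iff *m_ij > T*, distance weight
  *w_ij = 1/m_ij* (no edge ⇔ infinite distance); all N genes remain nodes;
- load: weighted betweenness *g(v) = Σ_{s≠v≠t} σ_st(v)/σ_st* over unordered
  pairs; capacity *C_j = (1+α) L_j*, fixed from the intact network (α = 0
  by default);
- cascade from seed *i*: remove the seed, recompute loads, fail every node
  with load > capacity (strict) or left without edges, iterate to a fixed
  point; *s_i* = nodes failed, *d_i = s_i/N*;
- robustness: *P* = fraction of seeds with *d_i ≥ t_cf* (t_cf = 0.5),
  *R* = mean *d_i*, and the survivor curve *P(d′ ≥ d)*; swept over the 18
  thresholds (0, 0.05, …, 0.7, 0.8, 0.9, 0.99);
- SKG rule: gene key in a condition iff *d_i ≥ 0.5* at ≥ 50 % of the sweep
  thresholds inside the separability window (0, 0.65); key-condition sets
  become type labels (`T_C`, `T_II_III`, …).

Upstream, probes mapping to zero or several genes are dropped, multi-probe
genes are averaged, and the working gene set is the intersection of
two-sided Wilcoxon rank-sum selections (control vs. each stage) at a raw
significance level (glioma: 2.5×10⁻⁷; renal: 1.5×10⁻⁸).

A synthetic-cohort generator (`generate_cohort()`) with planted
differentially-expressed genes and planted correlated modules provides
ground truth for every stage; no external data are downloaded.

## Worked example

```r
library(micascade)

# a star network: the centre carries all 6 leaf-pair shortest paths
net <- reference_graph("star", n = 5)
weighted_betweenness(net)
#> g1 g2 g3 g4 g5
#>  6  0  0  0  0

res <- cascade_all(net, alpha = 0, t_cf = 0.5)
res$d
#>  g1  g2  g3  g4  g5
#> 1.0 0.2 0.2 0.2 0.2
c(P = res$P, R = res$R)
#>    P    R
#> 0.20 0.36
```

Removing the centre isolates all four leaves (*d = 1*); removing a leaf
only halves the centre's load, which its capacity absorbs (*d = 0.2*).  So
P = 1/5 of knockouts collapse the star and the mean cascade ratio is
R = 0.36.

The full pipeline on a simulated 200-gene cohort:

```r
cfg <- pipeline_config(glioma_like_spec(n_genes = 200, seed = 8),
                       out_dir = "run")
res <- run_pipeline(cfg)
#> [simulate] done in 0.0s
#> [select] done in 0.2s
#> [network] done in 0.0s
#> [sweep] done in 5.3s
#> [skg] done in 0.0s
#> [pipeline] complete in 6.1s -> run
```

`run/` then contains the expression TSVs, per-stage gene sets, per-(condition,
threshold) edge lists and cascade tables (4 × 18 = 72), P/R summaries, the
cumulative size-ratio curves, the SKG table and a JSON manifest with the
configuration hash that heads every output table.

## The analysis workflow

`analysis/01_simulate.R` … `06_skg_benchmark.R` run the study as numbered
steps, writing tables under `results/analysis/`.  On the shipped 300-gene
cohort (stages with 23/45/31/81 samples, 60 planted DE genes) selection
recovers exactly the planted set (GI_II = GI_III = GI_IV = G1 = 60 genes),
and the cascade sweep shows the robustness statistics rising with the
threshold, e.g.

```
C:  P range 0.00-0.05, R range 0.017-0.064, Spearman(T, R) = 0.63
II: P range 0.00-0.48, R range 0.017-0.481, Spearman(T, R) = 0.40
```

At these sample sizes the 20-bin MI estimator's bias floor narrows the
usable threshold band and script 05 finds no gene satisfying the key-gene
rule — the expected outcome, discussed in the methods vignette.  Script 06
re-runs the classifier on the identifiability benchmark (40 genes, a
disease-only graded module, 3000 samples per group), where the planted hub
is labelled disease-only (`T_II`) in 5/5 seeds.

## Layout

```
R/                 package code (generator, selection, MI networks,
                   cascade model, SKG classification, pipeline/IO)
analysis/          numbered workflow drivers (simulate ... skg benchmark)
scripts/           acceptance.R
tests/testthat/    unit, property and acceptance suites
vignettes/         methods vignette (model, assumptions, limitations)
```
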