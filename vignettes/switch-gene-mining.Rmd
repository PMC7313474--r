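---
title: "Switch-gene mining: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Switch-gene mining: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchscan)
```

## The model

`switchscan` mines two-condition expression matrices for *switch genes*:
nodes of the signed co-expression network that are weakly embedded in
their own community (low within-module degree z-score Zg), connected
mainly outside it (high clusterphobic coefficient Kπ), and
*anti-correlated* with their network neighbors (negative average Pearson
correlation, APCC). The interpretation is that such genes sit between
transcriptional programs and flip their coordination as the system moves
from one condition to the other.

The pipeline is a chain of well-defined stages, each usable on its own:

| stage | function(s) | output |
|---|---|---|
| pre-filter | `prefilter_expression()` | expressed, variable genes |
| differential filter | `differential_stats()`, `select_fold_change_threshold()`, `apply_filter()` | 1000–2000 candidate genes |
| network | `correlation_matrix()`, `build_network()` | signed weighted graph |
| communities | `choose_k_scree()`, `kmeans_partition()` | module assignment |
| cartography | `node_cartography()`, `extract_switch_genes()` | Zg, Kπ, APCC, regions, switch set |
| robustness | `removal_curve()` | APL-vs-removal curves |
| comparison | `intersect_switch_sets()`, `bicluster_switch_expression()` | Venn regions, heat-map orders |
| annotation | `minimum_connected_subnetwork()`, `ora_hypergeometric()`, `rank_regulators()`, `rank_chemicals()` | enrichment and rankings |

### Assumptions

* Expression values are log2 intensities; both conditions have at least
  two samples (the Welch test needs within-group variances).
* Correlation is a meaningful similarity for the data at hand — the
  method is built for bulk intensity data, not zero-inflated counts.
* Communities are approximated well enough by k-means on standardized
  expression profiles; no network-topology clustering is attempted.

## Tunable parameters

All defaults are surfaced in `pipeline_config()` and echoed in the run
manifest so a run can be reproduced bit-for-bit.

* **Fold-change band 1.5–4 (linear), target 1000–2000 genes.** The
  threshold is scanned on a 0.05 grid, ascending, and the smallest value
  whose retained count (|FC| ≥ t and q < α) lands in the band is chosen.
  If the count curve never enters the band we return the closest
  approach; when every candidate over-retains this is the *highest*
  threshold, otherwise the lowest — the direction that moves the count
  toward the band.
* **α = 0.05** for the Benjamini–Hochberg FDR, in both the differential
  test and edge significance. Standard practice; no moderation
  (limma-style shrinkage) is applied, keeping the statistic
  self-contained.
* **Expression floor: 10th percentile of gene means.** "Unexpressed or
  slightly expressed" is rank-based, so roughly one gene in ten is always
  trimmed; this is intentional and mirrors how such floors behave on
  real intensity data.
* **Edge rule: |PCC| ≥ 0.6 and BH-adjusted correlation p < 0.05**, with
  the p-value from the t-transform `t = r √((n−2)/(1−r²))`. The floor
  uses a closed rule (values exactly at 0.6 keep their edge). Both knobs
  are recorded in `network$params`. Correlations are computed across
  **all** samples by default (`corr_scope = "all"`); a case-only scope is
  available, since on strongly shifted data the cross-condition
  correlation mixes the within-condition structure with the shift.
* **k-means: replicated, on z-scored profiles.** Each replicate starts
  from fresh random centroids; the lowest-SSE replicate wins. k is the
  elbow of the min-SSE scree curve — the grid point maximizing the
  second forward difference `SSE(k−1) − 2·SSE(k) + SSE(k+1)` — searched
  over 2–10 by default and overridable. Scree inspection is a manual
  step in interactive use of this method; the elbow rule automates it so
  the pipeline is testable, at the cost of occasionally preferring a
  slightly different k than an analyst would.
* **Cartography boundaries.** The hub boundary of the plane is Zg = 2.5,
  which is also the switch-gene Zg ceiling; the Kπ breakpoints
  (0.05/0.62/0.8 for non-hubs, 0.30/0.75 for hubs) follow the standard
  network-cartography convention, of which only the 0.8 switch boundary
  matters for switch calling. A stricter hub notion (Zg > 5) exists in
  the method's vocabulary and is reported separately as `is_strong_hub`;
  it never interacts with switch calling, and on every run the strong
  hubs are disjoint from the switch set. The date/party APCC boundary is
  0.5 ("low" vs "high" positive co-expression is not otherwise
  quantified).
* **Robustness: fractions are of class size**, grid 0–0.5 by 0.05,
  20 random removal orderings averaged. Removal order is uniform within
  the class.
* **Chemical ranking degree floor 4**; ties alphabetical.

## Numerical conventions and degenerate inputs

* Zg uses the **population** standard deviation of internal degrees; a
  module whose members all have the same internal degree yields Zg = 0
  for all of them.
* Isolated nodes get Kπ = 0 (hence region R1, never R4) and an undefined
  APCC, excluding them from hub classes and switch calling.
* `k = n` (one gene per cluster) is answered directly with SSE 0 rather
  than delegated to the clustering routine.
* Average shortest path is computed on the **largest connected
  component** (unweighted, breadth-first); a single-node component has
  APL 0. This keeps the mean defined after removals disconnect the
  graph, at the price that heavy disconnection can *lower* APL — the
  curves should be read together with component sizes.
* Biclustering sorts rows and columns by id before clustering
  (1 − Pearson distance, average linkage), which makes leaf order
  deterministic and invariant to input order.
* Empty k-means clusters in a replicate are re-drawn (up to 10 retries)
  before failing.
* The minimum connected PPI subnetwork is a heuristic Steiner
  construction — union of pairwise shortest paths among seeds, then
  iterative pruning of non-seed leaves. Optimal Steiner trees are
  NP-hard; the tests bound the result by the union of *all* shortest
  paths among seeds. Seeds outside the seed-richest component are
  reported as excluded rather than silently dropped.
* The ORA universe defaults to the genes of the minimum connected
  network when a PPI is supplied, else to all genes in the expression
  matrix.

## What the synthetic generator emulates

`generate_expression()` draws from a latent-factor model: module *m* has
a factor `f_m ~ N(0,1)` per sample, and a module gene is
`baseline + w·f_m + ε` with `ε ~ N(0, σ²)`. The loading
`w = σ √(ρ_w/(1−ρ_w))` gives expected within-module, within-condition
correlation exactly `ρ_w` (`ρ = w²/(w²+σ²)`). A planted switch gene
loads negatively, with equal weight, on **two** module factors; the
weight `v = |ρ_s| σ / √(ρ_w − 2ρ_s²)` gives expected switch-to-anchor
correlation `ρ_s < 0` (feasible when `ρ_w > 2ρ_s²`).

The condition effect enters **through the factor means**: case samples
shift each factor by `+δ/2` and controls by `−δ/2` with
`δ = log2fc_signal / w`. Consequences worth knowing:

* module genes shift by exactly `log2fc_signal` (default 1, i.e. 2×,
  inside the 1.5–4 filter band) and switch genes shift oppositely by
  `−2vδ` through their negative loadings, so the differential filter and
  the correlation structure agree with each other;
* because the shift is centered, gene means are unbiased and the
  rank-based expression floor trims switch genes no more often than any
  other gene (about one in ten — visible as recall plateauing near 0.9
  in recovery runs);
* across *all* samples the shared shift inflates correlations above
  `ρ_w`; the generator's calibration is therefore checked on control
  samples only, where the closed form applies.

Unstructured background genes sit at a lower baseline, emulating the
"slightly expressed" tail that the pre-filter removes.

**What it does not emulate:** probe-level artifacts, saturation, batch
effects, covariates, heavy-tailed noise, correlated noise between
modules, or count data. Passing the recovery checks therefore shows the
chain of statistics is implemented coherently — not that the method is
robust to real microarray pathology.

## Verification strategy and problem sizes

The test suite validates each statistic against independent brute-force
oracles (explicit adjacency walks for Zg/Kπ/APCC, step-up enumeration
for BH, combinatorial sums for the hypergeometric tail, vectorized
Floyd–Warshall for APL, naive O(n³) agglomeration for the linkage, BFS
path counting for betweenness) on a hundred random instances of up to 50
nodes each, exactly. End-to-end recovery uses the generator's standard
conditions (4 × 300 module genes, 20 switch genes, 20 + 20 samples) over
five seeds; robustness comparisons use twenty 3 × 60-gene networks with
12 planted switch genes. These sizes were chosen so the full suite
documents the behavior at realistic gene counts (≈1200 network nodes)
while remaining quick to run.

## Known limitations

* The edge-selection rule (hard |PCC| floor plus FDR) and the exact
  region breakpoints are conventions; other published uses of this
  method family may differ, which is why every threshold is mandatory in
  the manifest.
* k-means on profiles can split or merge planted communities when the
  scree elbow is ambiguous; the switch rule is robust to this in
  simulation, but k is overridable for a reason.
* APL-on-largest-component compresses information once removals shatter
  the graph.
* Welch's t-test per gene, without variance moderation, loses power at
  very small sample sizes (n < 5 per group).
* No batch correction, covariate adjustment, or paired designs.
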