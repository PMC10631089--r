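---
title: "Choosing the maximum reported cluster size for the multinomial spatial scan"
author: "mrcscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing the maximum reported cluster size for the multinomial spatial scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcscan)
```

## The problem

The spatial scan statistic detects geographic clusters by sliding a family
of scanning windows over a study map and maximising a likelihood ratio that
contrasts the outcome distribution inside each window with the outside.
For nominal categorical outcomes (disease subtypes, survey responses) the
multinomial model is the natural choice: region $i$ contributes counts
$c_{ik}$ over $K$ categories, and a window $z$ is interesting when its
category mix differs from the rest of the map.

Two size limits govern a scan. The *maximum scanning window size* (MSWS)
bounds the windows evaluated during the scan and is conventionally fixed at
50% of the data; re-running the scan at several MSWS values inflates the
multiple-testing burden, so it stays fixed. The *maximum reported cluster
size* (MRCS) bounds only which clusters are *reported* and can be varied
freely after a single scan: the fit, including its Monte Carlo null
distribution, is computed once, and reports at different MRCS values reuse
it. Reporting at the default 50% often returns one oversized cluster that
swallows neighbouring unremarkable regions; a well-chosen MRCS instead
surfaces the smaller clusters the big window shadows. This package
implements the multinomial scan end-to-end and five data-driven criteria
for choosing the MRCS.

## The scan statistic

With $a_k = \sum_{i \in z} c_{ik}$ (total $A$), $b_k = C_k - a_k$ (total
$B$), category totals $C_k$ and grand total $C$, the window statistic is

$$\log\lambda_z = \sum_k a_k \log\frac{a_k}{A}
  + \sum_k b_k \log\frac{b_k}{B} - \sum_k C_k \log\frac{C_k}{C},$$

with $0\log 0 = 0$. It is invariant to category relabelling and to
complementing the window, and zero exactly when inside and outside
proportions coincide. Windows are circles and ellipses grown around region
centroids: for each centre, shape $s \ge 1$ and orientation $\theta$,
regions are ranked by the area-preserving elliptic metric
$d = \sqrt{x'^2/s + s\,y'^2}$ (rotated frame; semi-axes $\sqrt s$ and
$1/\sqrt s$, so the axis ratio is $s$) and accumulated nearest-first until
the MSWS bound. The default configuration is the circle plus shapes
$\{1.5, 2, 3, 4, 5\}$ with $\{4, 6, 9, 12, 15\}$ evenly spaced
orientations; distance ties break by region index so enumeration is
deterministic, and duplicate region sets are kept once. No eccentricity
penalty is applied to elongated windows.

Significance uses Monte Carlo randomisation that conditions on *both*
margins: null tables are drawn uniformly among tables with the observed
per-region totals $c_i$ and per-category totals $C_k$ (equivalently, the
category labels of the $C$ cases are permuted), via `stats::r2dtable`. The
p-value of a window is the rank of its $\log\lambda_z$ among the $R$
replicate maxima, $(1 + \#\{\max_r \ge \lambda\})/(R+1)$; secondary
clusters are compared against the same max-statistic null, the
conservative convention. Reported clusters at any level are greedily
non-overlapping: descending $\log\lambda_z$, keeping a window only if it
shares no region with a higher-ranked keeper.

## The selection criteria

At each candidate MRCS $m$ (grid
`r paste(mrcs_grid(), collapse = ", ")` percent), the report is rebuilt:
windows are filtered to size at most $m$%, re-ranked for non-overlap, and
thresholded at $\alpha$ (default 0.05, $R = 999$ by default). Filtering by
size *before* the overlap pass is what allows small clusters shadowed at
50% to surface. With $J_m$ significant clusters of summed statistic
$\sum_j \log\lambda_{Z_j}$, total cases $\tau^{(m)}$ and total regions
$\delta^{(m)}$:

* **SCIC** (spatial cluster information criterion), a BIC-style penalised
  fit, minimised over the grid:
  $\mathrm{SCIC}_1(m) = -2\sum_j \log\lambda_{Z_j} + K J_m \log\tau^{(m)}$,
  and $\mathrm{SCIC}_2$ with $\delta^{(m)}$ in place of $\tau^{(m)}$.
  Undefined when $J_m = 0$ — an empty report is excluded from the argmin
  rather than treated as zero, otherwise "no clusters" would always win.
* **Elbow**: the point of the profile $(m, -\sum_j \log\lambda_{Z_j})$
  with maximal orthogonal distance to the chord joining the first and last
  grid points; when $J_m = 0$ the profile falls back to the negative
  maximum statistic among size-admissible windows. The profile sums *log*
  likelihood ratios; raw $\lambda$ summation (which overflows quickly) is
  available via `elbow_use_log = FALSE` for sensitivity analysis.
* **MCS-P**: the union log likelihood ratio of all significant clusters
  pooled as one homogeneous zone, maximised over the grid.
* **MCHS-P**: the same union statistic with the clusters first merged into
  $W_m \le J_m$ groups by spatial contiguity (connected components of the
  cluster contact graph), each group keeping its own internal
  distribution. Requires an adjacency relation; an edge list can be
  supplied with the map.

The union statistic is written so that a single group holding a single
cluster reduces *exactly* to $\log\lambda_z$ of that window, and MCHS-P
with $W_m = 1$ equals MCS-P: the no-contrast baseline term
$\sum_k C_k \log(C_k/C)$ enters with a minus sign, keeping the whole
family internally consistent with the window statistic. Ties in any
criterion break toward the smallest $m$ (parsimony). When no grid value
yields a significant cluster, no selection is made — the criteria never
manufacture clusters.

## A worked run

```{r example}
map <- grid_geography(8)                  # 64-region lattice, rook adjacency
scenario <- design_scenario(map, model = "B", hypothesis = "1")
cases <- simulate_dataset(scenario, seed = 11)
fit <- multinom_scan(cases, map = map, R = 199, seed = 42)
fit
sel <- select_mrcs(fit, map = map)
sel
```

```{r profile, fig.width = 6, fig.height = 8}
plot(sel)
```

## The synthetic-data generator

`scenario_table()` enumerates the full simulation design: five true-cluster
models — one circular (A) or elliptic (B) cluster of 5 regions (8% of the
64-region stand-in lattice), one irregular 10-region cluster (C, 15%), and
two circular (D) or elliptic (E) clusters of 5 regions each — crossed with
alternative hypotheses for $K = 4$ categories. The null probabilities are
$p^{(0)} = (0.25, 0.25, 0.25, 0.25)$; inside a cluster one of
$(0.05, 0.15, 0.35, 0.45)$, $(0.05, 0.25, 0.25, 0.45)$,
$(0.10, 0.10, 0.40, 0.40)$, $(0.15, 0.15, 0.15, 0.55)$ applies, two-cluster
models also pairing the first vector with each of the others
(heterogeneous settings), 26 scenarios in all. Each dataset allocates
exactly 1000 cases: every case draws a region (uniform weights by default;
population-proportional available) and then a category from that region's
probability vector.

Design choices worth stating explicitly:

* **Geography.** The generator uses a square lattice with rook adjacency
  as a neutral stand-in at district-centroid scale; real maps load from
  CSV. Planted clusters sit at fixed interior positions so the truth is
  identical across replicates; circular/elliptic truths take the
  `round(0.08 * 64) = 5` nearest regions under the corresponding metric
  (elliptic elongation 3), irregular truths grow a seeded contiguous walk.
* **Window-size denominator in the study.** `run_simulation_study()`
  measures window size against the scenario's at-risk allocation
  (`size_by = "population"`). With the observed-case denominator, a
  planted cluster's reportable size fluctuates binomially around its
  expectation — a 5-region cluster on 64 regions straddles the 8% grid
  bin — and whether the true window is reportable at its own size becomes
  a coin flip of the sampling noise rather than a property of the design.
  The fixed at-risk denominator, which is also what standard scanning
  software bounds cluster size against, keeps the design's intended
  cluster size aligned with the grid. Interactive scans of real data
  default to the observed-case denominator, the only denominator always
  available.
* **Scoring.** Sensitivity $|D \cap T|/|T|$ and PPV $|D \cap T|/|D|$
  compare the union $D$ of reported-cluster regions with the union $T$ of
  planted regions; misclassification is $(|D \setminus T| + |T \setminus
  D|)$ over the total region count (an $|D \cup T|$ denominator is
  available via `denominator = "union"`). When nothing is detected, PPV is
  excluded from averages and sensitivity counts as zero; per-$m$ columns
  average over the replicates that selected that $m$, and "overall" over
  all replicates with at least one significant cluster.
* **Reproducibility.** One master seed draws a sub-seed per replicate, so
  any replicate can be reproduced in isolation; identical seeds give
  bytewise-identical summaries.

What passing simulations show — and what they do not: the generator draws
independent multinomial cases on a regular lattice. Real surveillance data
carry unequal at-risk populations, irregular geographies, and possible
spatial autocorrelation within regions, none of which the generator
emulates; performance there should be read qualitatively, not as error
rates.

## Numerical and scale choices

Window LLR evaluation over all windows and null replicates is implemented
in C++ (the per-window inside counts are accumulated through the sparse
membership matrix), and the case-independent part of window enumeration —
distance rankings and set deduplication — can be precomputed once per map
(`window_skeleton()`) and reused across datasets, which is what
`run_simulation_study()` does. Set deduplication uses exact integer prefix
hashes with a verification pass, so enumeration is exact and
deterministic. Degenerate windows (covering no or all cases) score zero; a
relative risk is 0 for a category absent inside a window and infinite for
one absent outside.

The built-in checks use sizes chosen to make their Monte Carlo behaviour
sharp at desk scale: the null calibration uses 200 datasets at $R = 99$
with circular windows (the validity of the conditional Monte Carlo
p-value does not depend on the window family), and the recovery study 100
datasets at $R = 99$ with the full elliptic configuration; at these sizes
the modal selected MRCS and the selected-vs-default comparisons are stable
across master seeds while a full-scale run (1000 datasets, $R = 999$)
remains a straightforward parameter change.

## Limitations

The scan is purely spatial (no space–time windows), unadjusted for
covariates, and the multinomial statistic is the single model-specific
plug point — other outcome models would slot in behind the same window
machinery but are not provided. Lat–long coordinates must be projected
before use; the elliptic metric is planar. MCHS-P needs a contiguity
relation and inherits its cost from the contact-graph construction. The
elbow method assumes a roughly monotone profile; when many small clusters
make $-\sum_j \log\lambda_{Z_j}$ non-monotone, its knee can be ambiguous —
a limitation of the criterion itself, not of the implementation.
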