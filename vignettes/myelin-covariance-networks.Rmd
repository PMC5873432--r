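---
title: "Myelin covariance networks: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Myelin covariance networks: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myelinnets)
```

## The analysis in one paragraph

Gray-matter myelination, indexed in vivo by the semi-quantitative
Magnetization Transfer (MT) parameter, does not fluctuate independently
across brain structures: subjects with above-average myelin content in
one region tend to show above-average content in specific other regions.
`myelinnets` quantifies this as a *network of myelin covariance*: nodes
are atlas regions, and edges are across-subject Pearson correlations of
regional MT after the modelled mean effects of age, age², sex and
age×sex have been regressed out within the analysis group. The weighted
correlation matrix is binarized over a grid of sparsity degrees; the
binary graphs are summarized by clustering index (C), characteristic
path length (L), global and local efficiency (Eglob, Eloc) and
normalized betweenness centrality (NBC); scalar summaries (areas under
the attribute-versus-sparsity curve, pooled connectivity strengths,
targeted-attack robustness) are compared between groups with a
subject-level bootstrap and bias-corrected (BC) percentile confidence
intervals; and lifespan dynamics are traced with fixed-size sliding
windows fitted by AIC-selected polynomials.

## The statistical model, step by step

### Confound detrending

For each region, ordinary least squares removes the group-level mean
structure from the M×N MT matrix using the five-column design
(intercept, age, age², sex, age×sex), and the residuals replace the raw
values. Only fluctuations around the mean aging trajectory should drive
the covariance estimates; without detrending, the shared age dependence
of mean MT would inflate every pairwise correlation. Age is mean-centered
within the group before squaring — this changes the reported
coefficients but provably not the residuals, so it is pure numerical
hygiene. Sex is coded F = 0, M = 1 (echoed in every report; the coding
also does not affect residuals). Global MT is *not* regressed out: global
signal removal would reshape genuine covariance patterns with no way to
estimate the introduced bias.

Rank-deficient designs arise in practice — a single-sex group makes sex
and age×sex collinear, and tied ages within a narrow sliding window can
collapse the age columns. The fit then drops the collinear columns,
warns, and records the dropped set; group runs and window series carry
the count in their reports.

### The correlation matrix and connectivity summaries

Edges are Pearson correlations across subjects; self-connections are
excluded (the diagonal is forced to 0). Partial correlations are out of
scope by design: with more regions than subjects per group they cannot
be estimated robustly.

Mean connectivity over any pair scope (global, homologous left–right
pairs, within-lobe, per-region) is pooled on Fisher's z scale:
`tanh(mean(atanh(|r|)))`. The z-transform is variance-stabilizing, so
pooling on that scale weights pairs more evenly than a raw average of
`|r|`. The source methodology prescribes Fisher pooling explicitly only
for intra-lobe connectivity; this package applies the same estimator to
*all* mean-correlation summaries for internal consistency, and stores
the raw arithmetic mean alongside so both conventions are available.
Magnitudes at or above `1 - 1e-7` are clamped before `atanh` (the clamp
count is recorded).

### Sparsity thresholding

A binary graph at sparsity *s* keeps the fraction `1 - s` of strongest
`|Cij|`: the threshold Rk is the order statistic such that
`round((1 - s) · N(N-1)/2)` pairs satisfy `|Cij| > Rk` strictly. With
continuous data the target edge count is hit exactly; ties at Rk make
the realized count undershoot, which is recorded on the graph object
(an all-equal matrix is rejected as tie-degenerate). Thresholding by
rank rather than by a fixed correlation value normalizes all compared
networks to the same number of nodes and edges, so group differences in
topology are not confounded by differences in overall correlation
strength. The default grid is 0.5 to 0.9 in steps of 0.02 (21 points) —
sparse enough to suppress spurious edges, dense enough to estimate the
attributes stably.

### Graph attributes

Definitions follow the standard unweighted-graph conventions:

* **Clustering index.** Per node, existing links among neighbors over
  possible links; 0 for degree < 2; the global index is the mean over
  all N nodes and equals 1 exactly on a complete graph.
* **Characteristic path length.** Mean BFS geodesic over ordered pairs.
  Graphs fragment at high sparsity and infinite distances would make L
  useless, so L averages over *connected* pairs only and the
  disconnected-pair fraction is reported alongside — the common
  convention in the covariance-network literature.
* **Global efficiency.** Mean of `1/d_ij` with disconnected pairs
  contributing 0; robust to fragmentation by construction.
* **Local efficiency.** Per node, the global efficiency of the subgraph
  induced by its neighbors (node excluded; 0 for degree < 2), averaged
  over all N nodes. Degree-0/1 nodes stay in the denominators of the
  clustering and local-efficiency means because the defining equations
  average over all nodes of the graph.
* **Betweenness.** Fractional (Freeman/Brandes) shortest-path counting
  over unordered pairs, endpoints excluded. NBC divides by the network
  mean betweenness over all N nodes (an alternative — normalizing only
  over nodes with nonzero betweenness — was considered and rejected to
  keep `mean(NBC) = 1` exact); when every betweenness is 0 (e.g. a
  complete graph) all NBC values are defined as 0 and flagged. Hubs are
  nodes with NBC strictly above 1.5.

Each attribute's curve over the sparsity grid is summarized by its
trapezoid area under the curve (AUC) — the simplest defensible reading
of an area summary on a discrete grid — and the AUC is the scalar that
enters group comparisons.

All four attributes and betweenness are verified in the test suite
against brute-force oracles (explicit triangle counting,
Floyd–Warshall distances, shortest-path counting via adjacency powers)
on hundreds of random graphs, to 1e-9.

### Bootstrap inference

Groups are compared by the classical Efron bootstrap: each of
`n_boot = 2000` draws (200 in desk-scale runs) resamples the M subjects
*with replacement at full size M*, recomputes the correlation matrix
from the resampled residual rows, and re-evaluates every statistic.
A subset-sized resample would change the sampling variance and was
rejected. The difference distribution subtracts the two groups'
bootstrap samples pairwise by bootstrap index; since the groups are
resampled independently this is statistically equivalent to any other
pairing. The 95% interval is the bias-corrected percentile interval:
`z0 = Φ⁻¹(P(diff < point estimate))` shifts the percentile bounds to
`Φ(2 z0 + z_{α/2})` and `Φ(2 z0 + z_{1−α/2})`; a difference is
significant when 0 falls outside the interval. BC rather than BCa: the
acceleration constant is not computable from the difference
distribution alone. Empirical quantiles use the `(B+1)p`
order-statistic convention (R quantile type 6), the standard choice for
bootstrap intervals; the default type-7 interpolation is visibly
anti-conservative in the tails at moderate B. Boundary bias proportions
(0 or 1) are clamped to `1/(2B)` with a warning; a degenerate
difference distribution raises an error.

One master seed derives a child seed per group and per statistic
stream, so any single comparison can be reproduced in isolation. The
package reports raw per-comparison decisions; no multiplicity
correction is applied across the many simultaneous comparisons, and
users who need family-wise control should apply it downstream.

### Targeted attack

Resilience is probed by deleting nodes one at a time in descending NBC
order — computed once on the intact graph (static order; ties broken by
higher degree, then region id) — and recording the size of the largest
connected component (LCC) after each removal. The static order matches
the procedure of naming the hubs up front and attacking them; a variant
that re-ranks the remaining nodes after every removal is available
behind `recompute = TRUE`. The robustness parameter is the trapezoid
area under the relative LCC (normalized by the *original* N, keeping
the curve monotone) versus the *fraction* of removed nodes (making the
area comparable across parcellation sizes); it lies in [0, 1]. Repeating
this at every sparsity yields a robustness-versus-sparsity curve whose
own AUC is the bootstrapped group statistic.

### Sliding-window trajectories

Subjects are age-ordered (ties broken by subject id so the window
sequence is deterministic) and grouped into overlapping windows of
constant size — by default 73, the young-group size — shifted one
subject at a time; the window age is the median age of its members.
Keeping the count constant keeps the correlation matrices across
windows unbiased by sample size. Within each window the full analysis
is repeated without bootstrapping, including the same 5-column
detrending design as the group analysis (uniformity was preferred over
a window-specific reduced model; near-collinear columns in narrow
windows are dropped automatically and counted).

Property series versus window age are fitted with OLS polynomials of
order 1..6 (6 because the most complex trajectory this analysis is
designed to represent is an order-6 fit of a nodal NBC series). The
order is chosen by Gaussian-OLS AIC, `n ln(RSS/n) + 2(k+1)` with
`k = order + 1` coefficients. Two numerical decisions matter here:

* **Parsimony selection.** The default rule returns the *lowest* order
  whose AIC lies within 2 units of the minimum, the conventional margin
  within which models are considered equivalently supported. The raw
  AIC argmin overfits polynomials with substantial probability
  (~25% on long series, independent of the noise level), while the
  parsimony rule recovers a generating cubic on 300-window series about
  91% of the time in this package's Monte Carlo suite; `select = "min"`
  gives the raw argmin.
* **Exact-fit floor.** RSS is floored at `n (1e-8 · SD(y))²` inside the
  AIC, so fits that reproduce the data to double-precision rounding tie
  instead of being ranked by floating-point noise in their residuals.

Coefficients are reported on the raw age scale (ascending powers,
converted from the internally centered fit); coefficient p-values are
the usual t-tests from the centered fit.

## The synthetic cohort generator

No MT data are distributed with the analysis, so the package ships a
generator that emulates the statistical structure the pipeline assumes,
with known ground truth:

* **Ages** uniform over the configured range; **sex** assigned by a
  rounded female fraction (e.g. 35/73 and 40/78 in the two-group
  defaults that mirror the study design of 73 young (20–31 y) and 78
  old (60–71 y) subjects).
* **Mean MT** per region follows a concave quadratic in age peaking at
  a per-region `peak_age` drawn from 40–50 y by default — the mid-life
  myelination peak window — with curvature `1e-4` p.u./year² and a
  baseline near 1.8 p.u., values chosen to resemble the scale and
  gentle lifespan amplitude (a few percent) of semi-quantitative MT
  maps. An additive sex offset and optional age×sex slope complete the
  mean. Because the mean model is quadratic, the analysis' own
  detrending design removes it exactly and the residual structure is
  purely the planted covariance.
* **Residuals** come from a latent-factor model: one unit-variance
  factor per homologous pair (loading `√h`), one per lobe (loading
  `√l`), plus independent Gaussian noise scaled so each region's
  residual SD is `noise_sd`. The implied covariance is positive
  semi-definite *by construction* (a sum of rank-one factors plus a
  diagonal), which is why couplings are specified through factor
  loadings rather than as arbitrary target matrices; configurations
  with `h + l > 1` are rejected. The planted correlation between any
  two regions is the sum of their shared squared loadings and is
  recorded as ground truth. An optional linear drift of the homologous
  coupling with age lets trajectory tests plant a rising interhemispheric
  coupling.

What the generator deliberately does **not** emulate: image-level or
voxel noise, iron/R2* contributions to the MT signal, non-Gaussian
residuals, regional heterogeneity of aging *effect sizes* (per-region
curvatures are free parameters, not calibrated values — the source data
for such a calibration are not public), and distance- or
gradient-dependent covariance beyond the pair/lobe block structure.
Passing recovery tests therefore demonstrates that the estimators are
correct and calibrated under the assumed model, not that real MT data
satisfy that model.

## Problem sizes used by the tests and scripts

The packaged test suite and acceptance script run everything at desk
scale, chosen as the smallest sizes at which each property is
informative: oracle equivalence on 200 random graphs of up to 10 nodes;
parameter recovery on single cohorts of 500 subjects × 114 regions;
type-I calibration on 200 replicate two-group experiments (75 + 75
subjects, 32 regions, 200 bootstrap draws) and power on 100 replicates;
trajectory model selection on 600 replicate 300-window series; and one
full two-group run at the study's dimensionality (73 + 78 subjects,
114 regions, 21 sparsity points, 200 bootstrap draws). The
2000-bootstrap study configuration is the package default for real
analyses.

## Known limitations

* Binary, undirected graphs only; no weighted metrics, small-world
  indices or community detection.
* Pearson covariance only; no shrinkage or partial-correlation
  estimators (the latter are explicitly out of scope at these sample
  sizes).
* The BC percentile test is per-comparison; multiplicity control is
  left to the user.
* Sliding-window values are strongly autocorrelated by construction
  (consecutive windows share all but one subject); the polynomial fits
  describe the trajectory shape, and their nominal coefficient p-values
  should be read with that dependence in mind.
* LCC normalization by original N makes attack curves comparable across
  steps but means a fragmented *initial* graph starts below 1.
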