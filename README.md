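# myelinnets

Networks of myelin covariance from regional quantitative MRI.

Gray-matter myelination — indexed in vivo by the semi-quantitative
Magnetization Transfer (MT) parameter — varies in a coordinated way across
brain structures: subjects with more myelin in one region tend to have
more in specific other regions. `myelinnets` builds and analyses these
**myelin covariance networks**: graphs whose nodes are atlas regions and
whose edges are across-subject Pearson correlations of regional MT after
confound detrending. It is aimed at researchers studying structural
covariance, brain aging, and graph-theoretical organization of
morphometric or microstructural measures.

## What it computes

Given a subjects × regions MT matrix **X**, a subject covariate table and
a region (parcellation) table:

1. **Detrending.** Per region, OLS removes the mean effects of age, age²,
   sex and age×sex within the analysis group; residuals replace raw
   values, so only fluctuations around the mean aging trajectory enter
   the covariance.
2. **Covariance network.** The N×N Pearson matrix C (zero diagonal);
   connectivity summaries are Fisher-pooled means of |r|:
   `tanh(mean(atanh|r|))` — globally, between homologous L–R pairs,
   within lobes, and per region.
3. **Binary graphs over a sparsity grid.** At sparsity *s* the strongest
   `(1−s)·N(N−1)/2` values of |Cij| become edges (default grid 0.5–0.9 in
   steps of 0.02). Per graph: clustering index C, characteristic path
   length L, global and local efficiency E<sub>glob</sub>,
   E<sub>loc</sub>, and normalized betweenness centrality
   b<sub>i</sub> = B<sub>i</sub>/⟨B⟩ (hubs: b<sub>i</sub> > 1.5). Each
   attribute's curve over the grid is summarized by its trapezoid AUC.
4. **Bootstrap group inference.** Subjects are resampled with replacement
   (classical bootstrap, default N<sub>boot</sub> = 2000); group
   differences in any statistic get a 95% bias-corrected percentile CI,
   significant when the interval excludes 0.
5. **Targeted attack.** Nodes are removed in descending NBC order;
   robustness is the area under the relative largest-connected-component
   curve, compared between groups over the sparsity grid.
6. **Aging trajectories.** Fixed-size sliding windows (default 73
   subjects, step 1) over the age-ordered cohort; each property series is
   fitted with an AIC-selected polynomial (orders 1–6) of the median
   window age.

A seeded synthetic-cohort generator (`generate_cohort()`) with planted
homologous/lobe covariance and quadratic age trajectories provides ground
truth for calibration and recovery testing; `synthetic_region_table()`
supplies a 114-region parcellation-like table (56 homologous pairs + 2
midline) so the pipeline runs at realistic dimensionality without any
atlas files.

## Worked example

Two synthetic age groups mirroring a young (73 subjects, 20–31 y) versus
old (78 subjects, 60–71 y) design, with a planted increase in homologous
coupling in the old group (0.35 → 0.55) and matched global structure:

```r
library(myelinnets)
rt <- synthetic_region_table()          # 114 regions
cfg <- pipeline_config(
  simulate = list(
    young = cohort_config(73, age_range = c(20, 31), female_fraction = 35/73,
                          region_table = rt, homologous_coupling = 0.35,
                          lobe_coupling = 0.10, seed = 2),
    old   = cohort_config(78, age_range = c(60, 71), female_fraction = 40/78,
                          region_table = rt, homologous_coupling = 0.55,
                          lobe_coupling = 0.15, seed = 3)),
  grid = sparsity_grid(0.5, 0.9, 0.02), n_boot = 200, seed = 1)
report <- run_group_comparison(cfg)
```

Key lines of the report (point estimates per group, young − old
difference, 95% BC CI):

```
conn_homologous        young=0.466 old=0.686 diff=-0.220 CI[-0.250, -0.190] *
conn_global            young=0.109 old=0.112 diff=-0.003 CI[-0.025, +0.009] n.s.
auc_clustering         young=0.134 old=0.144 diff=-0.010 CI[-0.018, -0.005] *
auc_robustness         young=0.195 old=0.195 diff=-0.000 CI[-0.003, +0.001] n.s.
```

Read: the planted homologous-coupling difference is recovered (pooled
homologous |r| 0.47 vs 0.69, CI excluding 0) while global connectivity —
matched by construction — shows no significant difference; the stronger
within-pair coupling also nudges the clustering AUC upward in the old
group. Per-group hub tables and the 15 most-connected regions are in
`report$groups$<name>$hubs` / `$top_connected`.

Trajectories work the same way from a single cohort config:

```r
traj <- run_trajectory(pipeline_config(
  simulate = cohort_config(437, age_range = c(48, 87), region_table = rt,
                           homologous_coupling = 0.45,
                           homologous_coupling_slope = 0.01, seed = 7),
  window_size = 73, properties = c("clustering", "homologous_connectivity"),
  seed = 7))
traj$properties$homologous_connectivity$fit$order    # AIC-selected order
```

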