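---
title: "Hemispheric lateralization of neonatal structural connectomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemispheric lateralization of neonatal structural connectomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemilat)
```

## The analysis this package implements

Diffusion-MRI tractography reduces a neonatal brain to a region-by-region
structural network: atlas labels are nodes, and an edge is present wherever
streamlines connect two regions. In studies of prematurity, a question of
particular interest is whether the *left-right organization* of these
networks differs between preterm infants scanned at term-equivalent age and
term-born controls, globally and in the fronto-limbic circuit (medial
fronto-orbital gyrus, superior temporal gyrus, amygdala, hippocampus) that
underpins early social-emotional development.

`hemilat` implements that analysis end to end:

1. **Connectome construction.** Streamline summaries (endpoint labels plus
   per-voxel FA samples) become symmetric fiber-count, tract-mean-FA, and
   binary matrices. The FA of a tract is a two-stage mean: FA averaged over
   the voxels of each fiber, then averaged over fibers with equal weight, so
   long fibers do not dominate.
2. **Hemispheric networks.** Each binary connectome is split into the
   induced subgraphs on left-hemisphere and right-hemisphere labels.
   Interhemispheric edges are excluded (their count is reported); midline
   labels, if present, are excluded likewise.
3. **Graph measures per hemisphere.** Characteristic path length $L_p$,
   global efficiency $E_{glob}$, clustering coefficient $C_p$, local
   efficiency $E_{local}$, small-worldness $\sigma$, and per-node
   betweenness centrality, from which the four fronto-limbic values are
   extracted per side.
4. **Asymmetry scoring.** For each subject and measure $X$,
   $AS = 100\,(X_L - X_R)/(X_L + X_R)$.
5. **Group comparison.** Ordinary least squares of each $AS$ on a group
   indicator plus covariates, with Benjamini-Hochberg FDR control within
   outcome families; plus an age-at-scan correlation screen and a
   social-emotional subgroup comparison.

A synthetic-cohort generator with plantable hemispheric effects makes every
stage testable and lets the pipeline's error rates be calibrated without
imaging data.

## Graph measures and their conventions

All measures are defined on simple, undirected, binary graphs. Where the
literature leaves a convention open, the package fixes it as follows and
applies it uniformly:

* **Distances** are BFS hop counts. $L_p$ is the mean of $L_{ij}$ over
  ordered pairs $i \ne j$; on a disconnected graph it is computed within
  the largest connected component (recorded in a `component_note`), keeping
  $L_p$ finite. $E_{glob}$ is the mean of $1/L_{ij}$ with $1/\infty = 0$,
  needing no component restriction.
* **Clustering** of node $i$ is $2E_i / (k_i(k_i-1))$ with $E_i$ the edges
  among its neighbours; nodes with degree < 2 contribute 0 but stay in the
  $1/N$ average, keeping the network-level formula literal. Local
  efficiency averages, over nodes, the global efficiency of the induced
  subgraph on each node's neighbours (the node itself excluded), with the
  same degree-< 2 convention.
* **Betweenness** of node $n$ accumulates, over unordered pairs $\{a,b\}$
  not containing $n$, the fraction of $a$-$b$ geodesics through $n$,
  normalized by $(N-1)(N-2)/2$ so values lie in $[0,1]$ — the scale on
  which fronto-limbic hub values of order $10^{-3}$ to $10^{-1}$ are
  conventionally reported.
* **Small-worldness** compares the graph with `n_random` degree-preserving
  references built by double-edge swaps (10 attempted swaps per edge;
  swaps creating loops or multi-edges are rejected; connectivity of
  references is not enforced). The default orientation is
  $\sigma = (C_p/C_{ran}) / (L_p/L_{ran})$, under which small-world
  networks score above 1. Reports in this literature sometimes *print* the
  reciprocal form while clearly interpreting $\sigma > 1$ as small-world
  and reporting values around 1.2; we therefore default to the standard
  orientation and expose `orientation = "printed"` for the reciprocal,
  rather than guessing at a typographic intent. Both orientations share
  the same reference ensemble, so their product is exactly 1.

Computationally, distances, clustering and neighbourhood efficiencies are
evaluated with dense matrix operations (frontier-expansion BFS, triangle
counting via $A^2 \odot A$), which at the 32-nodes-per-hemisphere scale is
both exact and fast; betweenness and degree-preserving rewiring are
delegated to igraph's Brandes and edge-swap implementations. The test suite
checks every measure, exactly, against independent brute-force
Floyd-Warshall and geodesic-enumeration oracles on all connected graphs
with up to five nodes.

## The asymmetry score

$AS(X) = 100\,(X_L - X_R)/(X_L + X_R)$ is bounded in $[-100, 100]$ for
nonnegative measures, scale-invariant, and antisymmetric under hemisphere
swap. **Positive values mean leftward dominance of the measure itself**:
this is what the formula implies and how results in this literature are
interpreted (a positive small-worldness score described as leftward
lateralization). A sentence occasionally seen stating the opposite sign
convention is inconsistent with the formula and is treated as an erratum.
For path length, where larger is *less* efficient, the score is reported
without a sign flip; interpretation ("leftward $AS(L_p)$ means rightward
efficiency advantage") is left to the analyst. Pairs with $X_L + X_R = 0$
yield an undefined score, which is flagged and dropped per-outcome with a
logged count rather than aborting a cohort.

## Statistical stage

* **Covariate-adjusted comparison.** Each $AS$ is regressed on the group
  indicator plus covariates — by default sex, age at MRI, and
  bronchopulmonary dysplasia, the standard adjustment set for
  preterm-vs-term contrasts; the subgroup analysis instead adjusts for
  gestational age and age at MRI. The effect is the group coefficient with
  its two-sided t-test.
* **FDR families** follow how such results are reported figure by figure:
  the five global measures form one Benjamini-Hochberg family, the four
  fronto-limbic betweenness scores a second, the age-correlation screen a
  third, and the subgroup comparison (all nine outcomes) a fourth.
  Two-sided tests throughout.
* **Cohort-table tests.** Fisher's exact test (two-sided, by summation of
  hypergeometric point probabilities), the 2x2 chi-square with optional
  Yates correction, the pooled-variance Student t, and the Mann-Whitney U
  (exact for untied samples of total size <= 20, tie-corrected normal
  approximation otherwise).
* **Sample size.** The pooled normal-approximation two-proportion formula,
  rounded up per group and inflated by $1/(1-\text{dropout})$. For the
  reference scenario (15% vs 40%, $\alpha = 0.05$, power 0.8, 10% dropout)
  it gives 49 per group, 98 total, 110 after dropout inflation. Published
  sentences quoting "94 in total (52 per group)" for this scenario are
  internally inconsistent ($52 \times 2 \ne 94$); the package reports both
  pre- and post-dropout numbers so the arithmetic is explicit.

One further reproducibility note: for the 2x2 delay table with cells
13/44 vs 0/21 the exact Fisher p is 0.0155 while the uncorrected chi-square
gives 0.0165; printed tables in this literature round the latter to 0.017.
When both tests are named in a methods section without a per-row
assignment, agreement should be checked against both — the package exposes
both and its acceptance checks report both.

## The synthetic cohort generator

The generator's defaults describe the study conditions the package is
calibrated under; they are fixed once and not tuned per analysis.

* **Cohort structure.** 64 preterm and 33 term subjects; gestational age
  truncated-normal (preterm mean 30.1 wk, SD 3.9, capped below 37 wk; term
  38.4 +/- 1.2 within 37-42 wk); age at MRI 37.3 +/- 1.3 vs 38.6 +/- 0.9 wk
  within the 36-41 wk scan window; male proportions 39.4% / 34.8%; BPD
  prevalence 45.3% / 0%; assessment completion 57/64 and 21/33; Bayley-III
  composites drawn per group from the corresponding means and SDs (e.g.
  social-emotional 97.3 +/- 17.4 vs 108.6 +/- 12.0), with the < 85 cutoff
  (1 SD below the normative mean of 100) defining the social-emotional
  subgroup. Under these defaults the expected abnormal fraction among
  assessed preterm subjects is $\Phi((85-97.3)/17.4) \approx 0.24$,
  matching the ~13/57 structure the subgroup analysis expects.
* **Network substrate.** Each hemisphere is a Watts-Strogatz graph: a ring
  lattice at density 0.32 (10 neighbours per node at $n = 32$) with every
  edge rewired with probability 0.15, retried until connected. This
  substrate was chosen over Erdős–Rényi because it reaches the
  $\sigma \approx 1.2$, $L_p \approx 1.7$, $E_{glob} \approx 0.67$ regime
  typical of neonatal hemispheric networks; under the defaults the
  generated cohorts sit at $L_p \approx 1.7$, $E_{glob} \approx 0.65$,
  $\sigma \approx 1.3$. Interhemispheric edges are sprinkled independently
  at density 0.05 (a knob, since conventions for handling them in
  hemispheric analyses vary; the hemispheric metrics never use them).
  Existing edges carry truncated-normal FA weights (mean 0.25, SD 0.05 —
  neonatal white-matter range, and mean +/- 3 SD stays inside (0,1)) and
  zero-truncated Poisson fiber counts (rate 5).
* **Asymmetry planting is mechanistic.** Effects act on topology, never on
  computed metrics: `sigma_shift_rewire` moves the left and right rewiring
  probabilities apart (in the preterm group only), which shifts
  small-worldness through real clustering/path-length changes;
  `roi_extra_edges` re-attaches edges onto a left-hemisphere ROI node,
  raising its betweenness. A development-time pilot (150 preterm subjects,
  two seeds) fixed `sigma_shift_rewire = 0.06` as the documented effect
  condition producing a leftward $AS(\sigma)$ shift of about 1.5
  within-group SDs; the default remains 0 (null). Because the plant acts on
  topology, it is not metric-selective: a hemisphere-wise rewiring offset
  also shifts clustering, path length and the efficiencies, in their
  mechanically coupled directions — which is exactly why planting at the
  metric level was rejected.
* **Reproducibility.** Every subject draws from its own RNG stream seeded
  by an affine counter on the master seed
  ($s_i = (s + 1000003\,i) \bmod (2^{31}-1)$), so cohorts are bit-identical
  across runs and subjects can be regenerated in isolation.

What the generator does **not** emulate: spatial embedding and registration
error, distance-dependent connection probability, realistic inter-regional
FA covariance, hub topology beyond the planted ROI boosts, or any
correlation between Bayley scores and network asymmetry (a config hook
exists but defaults to independence). Passing calibration on these cohorts
therefore demonstrates that the *pipeline machinery* is unbiased and
sensitive at the stated effect size — not that real neonatal data meet the
generator's assumptions.

## Calibration studies and problem sizes

The package's calibration experiments (run by the test suite and
`scripts/acceptance.R`) use 100 replicate cohorts of 64 + 33 subjects, 32
nodes per hemisphere, and 10 random references per small-worldness
evaluation — the reference count is an exposed knob whose Monte-Carlo noise
simply enters the within-group SD, against which the planted effect was
calibrated at the same setting. Two quantities are estimated:

* **Null error rate.** With no planted effects, the fraction of replicate
  cohorts in which *any* global-family asymmetry comparison is
  FDR-significant must stay within $0.05 + 2\sqrt{0.05 \cdot 0.95/100}$.
* **Effect recovery.** With the 1.5-SD leftward small-worldness plant, the
  $AS(\sigma)$ comparison must be FDR-significant in at least 80 of 100
  replicates.

## Degenerate inputs and numerical choices

* Graphs with no connected pair have undefined $L_p$ (classed warning,
  `NA`); $E_{glob}$ is 0 by the $1/\infty = 0$ convention.
* Triangle-free graphs (e.g. a star, or a hemisphere so sparse its lattice
  has $k = 2$) have $C_p = 0$ and hence undefined $\sigma$; downstream, the
  undefined asymmetry records are flagged and dropped per-outcome.
* Graphs admitting no valid double-edge swap are returned unchanged by the
  rewiring step, with a warning.
* Ties in the Mann-Whitney test use midranks; identical groups give
  exactly p = 1.
* Self-loop fibers are dropped (counted in a message): all measures are
  defined on simple graphs.
* `fdr_bh()` enforces the (0,1] contract of the step-up procedure; the
  age-correlation screen, which can produce an exact p = 0 from a perfect
  linear fit, adjusts via `p.adjust()` directly.

## Limitations

The hemispheric networks are induced subgraphs on same-side labels; an
alternative reading (whole-brain metrics restricted to one side's nodes) is
computable from the same objects but is not the default, and neither choice
can be disambiguated from summary tables alone. Metrics on FA-weighted
graphs are deliberately out of scope for the calibrated claims: the binary
view is the default throughout, matching the unweighted-matrix convention.
The statistical stage fits ordinary least squares; mixed models,
longitudinal structure, and imputation of missing developmental scores are
out of scope.
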