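---
title: "Structural covariance network analysis of cortical thickness: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance network analysis of cortical thickness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnthick)
```

## The model

Regional cortical thickness is measured once per subject per atlas region
(mm, averaged over the region's surface). Two kinds of group contrast are
supported:

1. **Mass-univariate**: per region, a Student's pooled-variance two-sample
   *t* between patients and controls, with Bonferroni control at
   `alpha / n_regions`. With the default 148-region bilateral Destrieux
   parcellation and `alpha = 0.05` the threshold is 0.05/148 = 0.00033784.
   Thickness of flagged regions is then correlated with clinical variables
   within the patient group — Spearman for continuous or graded scores,
   point-biserial for binary antibody status — pairwise-complete and
   deliberately uncorrected (each row reports its own `n` and raw `p`; an
   optional BH mode exists and the choice is recorded in the output's
   attributes).

2. **Network-level**: a structural covariance network (SCN) per group.
   Thickness is residualized on age and sex by OLS *within each group*,
   regions are correlated across subjects (Pearson), and the association
   matrix is binarized over a grid of densities. At density $d$ the
   $\mathrm{round}(d\,\binom{n}{2})$ top-ranked pairs become edges. Graph
   measures are computed on every thresholded graph and compared between
   groups by permutation.

The per-group SCN is a *group-level* statistic: each group yields one
network, so no subject-level variance estimate exists and parametric tests
do not apply. Inference therefore permutes group labels (group sizes
preserved) and re-runs the complete construction — re-residualization
within the permuted groups included — for every permutation. Skipping the
re-residualization step would test a different (and anticonservative)
hypothesis, because covariate fits would then leak the observed grouping.

## Density thresholding, not a correlation cutoff

Thresholding keeps the top $\mathrm{round}(d \cdot E_{max})$ pairs of a
single ranking of the association matrix (most positive first, ties broken
by row/column order). This has three consequences the package relies on:

- **Comparability**: both groups' graphs have exactly the same number of
  edges at each density, so metric differences reflect topology, not edge
  count.
- **Nestedness**: because one ranking serves the whole grid, the edge set
  at a lower density is a subset of the edge set at any higher density.
- **Rank invariance**: any strictly increasing transform of the
  associations yields identical graphs.

An absolute correlation cutoff has none of these properties; in
field practice the density formulation is what makes a density *range*
(here 0.38–0.50 in steps of 0.01, 13 graphs) and a "minimum connected
density" meaningful, so that is the default and the package's canonical
semantics. Negative correlations are never *sought* as edges — ranking is
by signed value — but in weakly correlated data at high densities the edge
quota can exceed the number of positive pairs; the package then keeps the
edge-count contract and warns that non-positive associations were admitted,
rather than silently changing the graph's density.

Edge counts use half-away-from-zero rounding (`floor(x + 0.5)`), stated
explicitly so counts are bit-reproducible: base R's `round()` rounds half
to even, which would make, e.g., a 4-node graph's edge quota at some
densities differ from the documented rule.

The **minimum connected density** (Dmin) is the smallest grid density (at
0.01 resolution) at which every group's graph forms a single connected
component; metric comparison is meaningful from Dmin upward. Below it,
characteristic path length falls back to the mean over reachable pairs with
a prominent warning — a diagnostic convenience, never silent.

## Graph measures and the small-world normalization

Clustering (per node: realised neighbour-pair edges over possible ones,
zero below degree 2), transitivity (3 × triangles / connected triples),
characteristic path length, global efficiency (mean inverse distance,
unreachable pairs contributing 0), local efficiency (global efficiency of
each node's neighbour subgraph), degree, and betweenness (Brandes-style,
normalized by $(n-1)(n-2)/2$) follow the standard binary-graph definitions;
the test suite pins every one of them to independent brute-force oracles
(Floyd–Warshall, neighbour-pair enumeration, walk-count shortest-path
counting) on all-graph samples of up to 8 nodes.

Modularity is Newman's $Q$ of the best partition over 10 seeded Louvain
restarts — the optimizer is stochastic, so the seed and restart count are
part of the result's provenance.

Normalized clustering ($\gamma$), normalized path length ($\lambda$) and
the small-world index $\sigma = \gamma / \lambda$ are computed against
degree-preserving edge-swap (Maslov–Sneppen) null graphs: each null
attempts $10\,|E|$ swaps, and 20 nulls per (group, density) are used by
default. The literature the method descends from names no null count; 20 is
the convention of the toolboxes in this space and is exposed in the
configuration along with the swap multiplier, since $\sigma$'s sampling
noise scales with both. $\sigma > 1$ is read as small-world organisation.

## Permutation comparison and AUC analysis

For each metric the package reports, per density: the observed case-minus-
control difference, the 95% percentile interval of the permutation null,
and a two-tailed p-value with the add-one estimator
$p = (\#\{|\Delta^\ast| \ge |\Delta|\} + 1)/(B + 1)$, which is never 0 and
respects the permutation test's discreteness. Per-density p-values are
BH-adjusted across the 13 densities within each metric; the curve-level
summary integrates each metric over density (trapezoid) and tests the AUC
difference against the permutation AUC differences. Nodal measures are
tested on their per-node AUC with BH across the 148 nodes within each
metric. Where BH is applied (within-metric across densities for global
curves, across nodes for nodal AUC) is itself a choice the source
literature leaves open; the scope used is recorded in the comparison
object.

A practical floor matters here: with $B$ permutations the smallest
attainable p is $1/(B+1)$. BH across $m$ nodes needs the smallest p to
clear $\alpha/m$, so detecting even a perfect nodal effect among 148 nodes
at $\alpha = 0.05$ requires $B \gtrsim 3000$; the default `n_perm = 1000`
suits global curves and small node sets, and should be raised for full-atlas
nodal inference.

## Hubs

A hub is a node whose betweenness lies at least 2 standard deviations above
the network mean. Since the analysis spans a density range but one hub set
per group is wanted, betweenness is first summarised per node as its AUC
across the grid; a per-density mode is available and the mode used is
stored on the result. The sample (n−1) SD is used — at 148 nodes the
population/sample distinction moves the threshold by under 0.4% and the
choice is configurable. The criterion is scale-invariant, so the
betweenness normalization convention cannot change hub identity.

## The synthetic cohort generator

No subject-level data are distributed with packages in this space, so the
generator is a first-class module: it emulates the *design* of the study
population the package targets, and every acceptance-level property of the
pipeline is demonstrated on it.

Per group, thickness is multivariate normal: a region mean profile plus
linear age and sex effects plus correlated noise. Defaults, chosen once:

- groups `case` n=108 and `control` n=88; ages uniform on 18–50; male
  prevalence 0.176 vs 0.284 (sex coded 1 = male);
- bilateral mean profile spanning 2.0–3.0 mm with SDs 0.10–0.30 mm (the
  scale of published per-region thickness tables); the case group is
  thinned by 0.09 mm in 57 designated regions (27 left, 30 right),
  matching the magnitude and laterality pattern of reported patient-vs-
  control differences;
- age slope −0.005 mm/year (modest adult cortical thinning), sex offset
  0.02 mm, both centred so region means are population means;
- six hemisphere-mirrored correlation modules with within-module r of 0.55
  (case) vs 0.45 (control) and between-module r 0.15 — the published
  finding the default emulates is a *higher* patient clustering
  coefficient; absolute covariance magnitudes are unreported in this
  literature and are therefore free parameters here, set to values typical
  of thickness SCN matrices;
- two planted hub regions coupled to all others at r = 0.35, which
  reliably become the top-betweenness nodes after thresholding;
- a clinical menu mirroring the emulated cohort's tables: log-normal
  durations/accumulations with the published medians and IQR-derived
  dispersions, per-variable observation counts (e.g. antibody assays in 79
  of 108 patients) implemented as missing-completely-at-random subsets,
  integer-rounded scale scores, antibody prevalences (anti-dsDNA 0.685,
  etc.), and Gaussian-copula couplings between two variables and named
  regions' thickness.

Block-constant correlation targets can be slightly indefinite once hub rows
are overlaid; the generator clips eigenvalues at $10^{-8}$ and rescales to
unit diagonal, records that the repair happened, and refuses (naming the
offending module pair) if the repair would move any entry by more than 0.1.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: spatial autocorrelation on the cortical
sheet (regions are exchangeable given the module structure), non-Gaussian
thickness tails, scanner/site effects, age–covariance interactions, and
any realistic magnitude of inter-regional covariance (unreported in the
source literature). Results on real cohorts depend on those properties;
the synthetic cohort certifies the *machinery*, not effect sizes.

### A planted effect must survive rank thresholding

One generator subtlety is worth recording because it shapes the recovery
tests: uniformly inflating one group's within-module correlation (say 0.6
vs 0.4 over a 0.15 between-module baseline at n=100) produces *no*
difference in the thresholded graphs — in both groups every within-module
pair already outranks the entire between-module cloud, and density
thresholding only sees ranks. A planted difference in binary-graph terms
requires the within/between *margin* to be comparable to the sampling noise
of a correlation ($\approx 1/\sqrt{n}$) in one group and clear of it in the
other. The recovery suite therefore uses within-module r of 0.5 (case)
vs 0.25 (control) over a 0.1 baseline, which makes the case modules crisp
and lets the control modules blur into noise — and yields the planted
higher-clustering signature at every grid density.

## Numerical and degenerate-input policy

- Residualization is exact OLS via QR; zero-variance covariates are
  dropped with a message (an intercept-only fit centres each region), and
  rank-deficient designs error naming the collinear columns.
- Zero-variance regions make correlations undefined: the association step
  errors naming the region; inside the permutation loop the offending
  permutation is redrawn and the redraw count reported.
- Zero pooled variance in a *t* comparison returns t = 0, p = 1 when means
  agree and errors otherwise; zero-variance regions in the ROI battery are
  reported non-significant with a warning rather than failing the battery.
- Constant vectors in the correlation battery yield flagged-undefined rows,
  not errors; all-missing variables are dropped with a warning.
- Threshold ties are broken by (row, column) order after sorting by value,
  so equal-valued associations cannot reorder between runs or platforms.
- Graphs admitting no degree-preserving swap (e.g. a triangle) return
  themselves as nulls with a warning, making $\sigma = 1$ exactly.

## Problem sizes used by the test suite

The suite demonstrates statistical properties at sizes chosen to make the
checks sharp yet quick to audit: permutation size (type-I error within
[0.02, 0.09] at $\alpha = 0.05$) on 50 null cohorts of 40+40 subjects and
60 regions at 200 permutations; planted-clustering recovery on 10 cohorts
of 100+100 subjects; hub recovery on 20 cohorts of 150+150; oracle
equivalence on 500 random connected graphs of up to 8 nodes plus the
canonical families; end-to-end determinism on a 40+40 × 60 pipeline run
executed twice. Monte-Carlo claims use fixed seeds so every reported rate
is reproducible.

## Known limitations

- Binary undirected graphs only: no weighted, signed, or directed
  variants, and no measures beyond those listed (no rich-club, no NBS,
  no robustness/attack analysis).
- Group-level networks only; individual-subject covariance networks are a
  different construct and out of scope.
- The per-density permutation tests are marginal: the BH correction treats
  densities as separate tests although nested graphs are strongly
  dependent, which is conservative for FDR but means "significant at k of
  13 densities" should not be over-read — the AUC test is the intended
  curve-level summary.
- Whether the ROI *t*-tests should adjust for age/sex is left to the user
  (`adjust = "covariates"`); the default is unadjusted and the mode used is
  recorded in the result's attributes.
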