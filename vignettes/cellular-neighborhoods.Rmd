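---
title: "Cellular neighborhood analysis of TMA single-cell data: methods and design"
author: "spatialTMA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cellular neighborhood analysis of TMA single-cell data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialTMA)
```

# The problem

High-grade serous ovarian carcinoma (HGSC) tumors are infiltrated by T
cells, macrophages and NK cells whose *spatial arrangement*, not just their
density, carries prognostic information. Multiplexed immunofluorescence of
tissue-microarray (TMA) cohorts yields, after segmentation, a per-cell
table: coordinates, tissue compartment (epithelium vs stroma), and marker
signals. `spatialTMA` implements the downstream analysis chain on such
tables:

1. **Phenotyping** — marker signals or positivity calls become phenotype
   labels through a hierarchical gate.
2. **Neighbor profiling** — each cell is described by the phenotype
   composition of its k nearest neighbors within the same core.
3. **Cellular neighborhoods** — profiles are pooled across the cohort and
   clustered with k-means into n recurrent composition patterns, which are
   then named by rule ("cold epithelium", "CD16a enriched stroma", ...).
4. **Coverage metrics** — fraction of each core's (and patient's) cells in
   each neighborhood, plus ratios between neighborhoods.
5. **Cohort statistics** — five-year Cox proportional-hazards models over
   dichotomized coverage, Kaplan-Meier curves, Pearson co-infiltration
   matrices, ANOVA by clinical strata, all with Benjamini-Hochberg FDR
   control.

Because segmented clinical cohorts are rarely public, the package ships a
synthetic TMA generator with complete ground truth so every stage is
testable end to end.

# The phenotype gate

Gating is an ordered, first-match-wins rule list over binary marker calls.
For the five-marker panel (panCK, CD68, CD3, CD94, CD16a):

```{r}
defaultHierarchy("panel1")
```

panCK dominates: any panCK+ cell is epithelial regardless of other
markers. CD16a splits the myeloid, T-cell and NK classes into `_CD16a`
variants because those variants are analyzed separately downstream; CD94
positivity on T cells is stored as a boolean attribute (`mod_CD94`) rather
than a class, since no analysis treats CD94+ T cells as a separate
population. All-negative cells are `Other`. A hierarchy is only valid if
it tiles marker space: the validity method enumerates all $2^{|panel|}$
combinations and requires each to match a rule, so gating is a total
function by construction.

When only marker intensities are available, signals are `log(1+x)`
normalized, clustered with k-means (k-means++ seeding, 10 restarts, best
inertia kept) over a candidate range of cluster counts, and the count at
the knee of the within-cluster dispersion curve is kept — the knee being
the point of maximum perpendicular distance to the chord joining the
curve's endpoints after scaling both axes to [0, 1] (ties go to the
smaller count). Each cluster's mean signal is thresholded per marker
(Otsu's histogram threshold on the normalized signal by default,
overridable) and gated; member cells inherit the cluster label. On data
with well-separated positive/negative intensity components the two routes
agree to within 1% of cells, which the test suite checks.

# Neighbor profiles and neighborhoods

For every cell we count the categories of its k nearest neighbors
(Euclidean distance on the micrometre coordinates, self excluded, ties
broken by (distance, cell_id) so results are deterministic). Categories
are phenotype × compartment (e.g. `S_CD16a`, `E_PanCK`) because stromal
and epithelial variants of the same neighborhood are biologically
distinct; a phenotype-only mode exists for comparison. Neighbor search
never crosses cores, and cores with fewer than k+1 cells are excluded
entirely (their profiles would have a deflated k and bias the pooled
clustering); every exclusion is logged. The default k is 15, in the range
(5–20) typically swept.

Profiles are raw counts, not frequencies — with fixed k the two differ
only by scale. Pooled profiles from all cores are clustered once per
cohort (never per patient) with k-means on the unscaled counts, k-means++
seeding, 10 restarts, best inertia; one pooled model is what makes
coverage comparable across patients. Neighborhood ids are 0-based and
ordered by decreasing size. Composition heatmaps z-score the centroid
matrix per category across neighborhoods; with a single neighborhood the
z-score is undefined and raw means are returned flagged degenerate.

## Choosing k and n

`selectKN()` fits every (k, n) on a grid (default k ∈ {5, 10, 15, 20},
n ∈ 5–10), flags centroid pairs with cosine similarity ≥ 0.95 as "highly
similar" (the threshold is configurable; the cutoff is a design choice,
as no formal definition exists), and recommends the combination at the
boundary between under- and over-fitting: the largest n whose model has
no flagged pair, whose (k, n+1) fit introduces a flagged (redundant)
split, and whose (k, n−1) fit merges two previously distinct
neighborhoods (detected by two centroids of the n-model matching the same
(n−1)-centroid under maximal cosine similarity). A "smallest n with a
merge below it" rule sounds similar but under-fits: planted-archetype
data shows every n below the true count also "merges below", while only
the true count additionally turns redundant one step above. On six
well-separated planted archetypes the rule recovers n = 6. The
recommendation is advisory — the (k, n) actually used is a configuration
value, because "clusters of interest" is ultimately observer-defined.

## Naming

Neighborhoods are named from their centroids: immune neighbor fraction
below 0.1 makes a neighborhood "cold" ("cold epithelium" vs "cold stroma"
by dominant compartment); otherwise, if the top z-scored category is a
CD16a class the neighborhood is "CD16a enriched <compartment>"; remaining
immune neighborhoods are ranked by immune fraction into "immune-rich" and
"immune-moderate". With phenotype-only categories the compartment is
unknown, so immune-poor non-epithelial neighborhoods keep their fallback
id name (`N<i>`). Manual overrides always win.

# The synthetic cohort generator

The generator is first-class, tested code; its defaults are the study
conditions of the test suite and were chosen once, from what is typical
for TMA material, before any downstream result was inspected:

* **Geometry** — each core is a disc of radius 0.3 mm (a 0.6 mm TMA
  core); epithelial "nests" are non-overlapping discs (default 3 per
  core, radii 0.04–0.08 mm) placed fully inside the core. Compartment
  areas are analytic (sum of nest areas; disc minus nests), so density
  denominators are exact.
* **Cellularity** — homogeneous Poisson placement per region, defaults
  2000 cells/mm² in epithelium and 1000 cells/mm² in stroma (no
  hard-core repulsion: neighborhood detection does not require it). The
  epithelium mixture is dominated by tumor cells (92% PanCK); the stroma
  mixture is dominated by non-staining cells (60% Other) with ~30%
  immune cells. No spatial statistics are published for comparable
  cores, so these are order-of-magnitude choices and fully configurable.
* **Hotspots** — spatial aggregates with their own phenotype composition,
  anchored by default on the boundary between a nest and the stroma,
  where CD16a-enriched neighborhoods are typically observed. The number
  of instances per core is Poisson, so planted coverage varies across
  patients — without that variation no survival contrast on coverage
  would exist. A hotspot cell's compartment is decided by its sampled
  position, keeping compartment purely geometric.
* **Clinical covariates** — age ~ N(60, 10²), stage (high/low), grade
  (2/3), debulking and chemo-sensitivity as Bernoulli draws.
  Chemo-sensitivity is an input flag: its clinical definition
  (responsiveness at six months) is applied upstream, never computed here.
* **Survival** — exponential event times with hazard
  $h_0 e^{X\beta}$, $h_0 = 1/36$ per month for OS (median ≈ 25 months)
  and $1/18$ for PFS; uniform censoring on [0, 120] months, giving ≈ 30%
  censoring. The linear predictor can include planted-coverage terms
  (linear or above-mean coding). Times beyond any horizon are recorded
  as-is; truncation belongs to the analysis stage. Richer baselines are
  out of scope.
* **Reproducibility** — one master seed; every core draws from a
  substream derived by a stable hash of (patient_id, core_index), so a
  cohort is byte-identical across runs and invariant to the order cores
  are generated in.

What the generator deliberately does **not** emulate: segmentation error,
marker spillover/unmixing artifacts, hard-core repulsion between nuclei,
irregular nest shapes, intra-tumoral gradients, or informative censoring.
Passing tests therefore demonstrate correctness of the analysis chain
under idealized geometry, not robustness to imaging artifacts.

# Statistics layer

* **Five-year outcomes** are implemented as administrative censoring at
  60 months: times beyond the horizon are truncated and their events
  removed.
* **Cox models** use the Breslow tie approximation (the simplest
  defensible default), Wald 95% CIs and p-values. Zero events after
  truncation yields a missing result; monotone likelihood (separation)
  is flagged and the CI marked unreliable. The multivariate model
  contains the variables whose univariate BH-adjusted p is below 0.05
  (the selection rule can be disabled); collinear variables are dropped
  with a warning.
* **Dichotomization**: "high" is strictly above the cohort median (ties
  low — a documented, arbitrary choice); mean splits are analogous;
  quartile mode keeps only Q1 and Q4, middle half missing.
* **FDR** is Benjamini-Hochberg (`p.adjust(method = "fdr")`); no other
  variant is supported.
* **Correlations** are pairwise-complete Pearson with a 3-pair minimum
  per cell; zero-variance variables are masked.
* **ANOVA** is one-way, or two-way with type-II sums of squares; BH
  adjustment spans all effects tested in one call.

# Numerical choices and degenerate inputs

k-means: Lloyd iterations (max 100) from k-means++ seeds, 10 restarts,
best total within-cluster sum of squares kept; duplicate seed rows (fewer
distinct points than clusters) are nudged apart by ~1e-8 so the fit
proceeds. Empty neighborhoods produce missing centroid rows that are
excluded from similarity and merge diagnostics. Coverage ratios with a
zero denominator are missing, never infinite, and counted in the log.
Degenerate splits (all values identical) abort the affected Cox contrast
with a log entry, not the run. A zero-width censoring window yields an
all-censored cohort flagged degenerate.

# Problem sizes used by the test suite

The suite verifies the kNN kernel against an O(N²) full-distance-matrix
oracle on cores up to 2,000 cells; archetype recovery on 40 patients × 2
cores (~29,000 cells); Cox recovery on 200 replicates of 800 patients;
and end-to-end power on 20 replicates per arm of 600-patient cohorts
simulated at reduced cellularity (500/200 cells/mm², ~100–170 cells per
core), a size at which the power properties of interest are already
stable.

# Known limitations

* The kNN search is exact brute force per core (C++, partial selection).
  Fine for TMA cores (10²–10⁴ cells); whole-slide millions-of-cells data
  would need a spatial index.
* Neighborhood definitions are k-means on counts; graph-based or
  Delaunay neighborhoods, and spatial statistics such as Ripley's K, are
  out of scope.
* Proportional-hazards diagnostics, competing risks and time-varying
  covariates are not provided.
* The panel-2 hierarchy below the myeloid rule is a configurable default:
  published category lists pin down its outputs, not its rule order.
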