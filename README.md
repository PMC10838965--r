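# spatialTMA

Cellular-neighborhood analysis of multiplexed tissue-microarray (TMA)
single-cell data, built for tumor immune-microenvironment studies such as
high-grade serous ovarian carcinoma (HGSC) cohorts profiled with panels
like panCK / CD68 / CD3 / CD94 / CD16a.

Digital-pathology pipelines export a per-cell table: coordinates, tissue
compartment (epithelium vs stroma), and marker signals per segmented cell.
`spatialTMA` takes that table (or simulates one with known ground truth)
and runs the full downstream analysis:

* **Phenotyping** — ordered, first-match-wins gating of binary marker
  calls (panCK dominates; CD16a splits the myeloid/T/NK classes; all
  negatives are "Other"), or log-normalization → k-means expression
  clustering with elbow selection → per-cluster gating when only
  intensities are available.
* **Neighbor profiles** — for each cell, the phenotype-by-compartment
  counts of its *k* nearest neighbors within the same core (default
  k = 15; self excluded; deterministic tie-breaking; exact C++ search).
* **Cellular neighborhoods** — k-means (k-means++ seeding, 10 restarts)
  over the pooled profiles into *n* neighborhoods, with a (k, n) sweep
  diagnostic based on centroid cosine similarity, and rule-based naming
  ("cold epithelium", "CD16a enriched stroma", "immune-rich", ...).
* **Coverage and ratios** — per-core neighborhood fractions, averaged
  over each patient's duplicate cores; ratios between neighborhoods.
* **Survival statistics** — five-year (60-month administratively
  censored) univariate and multivariate Cox models with Breslow ties over
  median/mean/quartile-dichotomized coverage, Kaplan-Meier curves,
  pairwise Pearson co-infiltration matrices, one/two-way ANOVA, all with
  Benjamini-Hochberg FDR control.

The model at the core: each cell *i* gets a profile
$c_i \in \mathbb{N}^{P\times C}$ counting phenotypes $P$ by compartment
$C$ among its k nearest neighbors; k-means minimizes
$\sum_i \lVert c_i - \mu_{z_i}\rVert^2$ over neighborhood assignments
$z_i \in \{0..n-1\}$; patient-level coverage of neighborhood $j$ enters a
Cox model $h(t) = h_0(t)\,e^{\beta x}$ with $x$ the high/low coverage
group, reporting $HR = e^{\hat\beta}$ with Wald 95% CI, and BH-adjusted
p-values across the family of contrasts.

The synthetic cohort generator plants all of it: disc-shaped 0.6 mm
cores with epithelial nests, Poisson cellularity, per-compartment
phenotype mixtures, CD16a hotspots at nest boundaries, clinical
covariates and exponential proportional-hazards survival tied to planted
hotspot coverage — so recovery of every quantity is testable against
ground truth.

## Worked example

```r
library(spatialTMA)

cfg <- runConfig(
  simulation = simulationConfig(n_patients = 30, seed = 7),
  k = 15, n = 6, seed = 7, outdir = file.path(tempdir(), "demo"))
bundle <- runPipeline(cfg)

bundle$model
#> NeighborhoodModel: k=15, n=6, 22042 labeled cells
#>   neighborhoods: immune-moderate, immune-rich, immune-moderate 1,
#>     immune-moderate 2, CD16a enriched stroma, CD16a enriched epithelium

head(bundle$coverage$patient[, 1:5], 4)
#>   patient_id immune-moderate immune-rich immune-moderate 1 immune-moderate 2
#> 1      P0001           0.284       0.225             0.153             0.122
#> 2      P0002           0.344       0.273             0.198             0.185
#> 3      P0003           0.377       0.330             0.134             0.158
#> 4      P0004           0.255       0.190             0.107             0.164

subset(bundle$results$cox, endpoint == "OS",
       select = c(variable, hr, ci_low, ci_high, p, n_events))
#>                    variable    hr ci_low ci_high      p n_events
#> 1           immune-moderate 3.419  1.170    9.99 0.0246       17
#> 2               immune-rich 1.812  0.689    4.77 0.2284       17
#> 3         immune-moderate 1 1.335  0.513    3.48 0.5538       17
#> 4         immune-moderate 2 0.552  0.202    1.51 0.2466       17
#> 5     CD16a enriched stroma 0.590  0.223    1.56 0.2863       17
#> 6 CD16a enriched epithelium 0.698  0.264    1.85 0.4699       17
```

The simulated cohort plants CD16a hotspots whose above-mean coverage
carries a protective hazard (HR 0.7 by default), and the fitted CD16a
neighborhoods indeed show HR < 1 — at 30 patients and 17 events the CIs
are wide; the acceptance script below demonstrates recovery at cohort
scale. Each run writes its outputs (cells, profiles, labels, coverage,
co-localization, composition, similarity, Cox/correlation/ANOVA/KM
tables, manifest and run log) as CSVs under `outdir`; identical config
and seed reproduce them byte for byte.

A thin command-line front end over the same functions lives at
`inst/scripts/run_pipeline.R` (`--config run.yaml --seed 7 --out dir`).

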