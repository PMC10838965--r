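# Independent oracles and small fixture builders used across the suite.

# Full-distance-matrix kNN profile oracle: O(N^2), ties broken by
# (distance, cell_id). Independent of the package's spatial search.
bruteForceProfiles <- function(cellTable, k, mode = "phenotype_compartment") {
  catOf <- function(comp, phen) {
    if (mode == "phenotype") phen
    else paste0(ifelse(comp == "epithelium", "E_", "S_"), phen)
  }
  cats <- sort(unique(catOf(cellTable$compartment, cellTable$phenotype)))
  rows <- list()
  for (core in unique(cellTable$core_id)) {
    sub <- cellTable[cellTable$core_id == core, ]
    if (nrow(sub) < k + 1) next
    sub <- sub[order(sub$cell_id), ]
    D <- as.matrix(dist(cbind(sub$x_um, sub$y_um)))
    catv <- catOf(sub$compartment, sub$phenotype)
    for (i in seq_len(nrow(sub))) {
      ord <- order(D[i, ], seq_len(nrow(sub)))
      ord <- ord[ord != i][seq_len(k)]
      cnt <- table(factor(catv[ord], levels = cats))
      rows[[paste(core, i)]] <- c(list(cell_id = sub$cell_id[i],
                                       core_id = core), as.list(cnt))
    }
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
  rownames(out) <- NULL
  out
}

# Grid maximization of the written-out Breslow partial likelihood for a
# single binary/numeric covariate.
coxGridOracle <- function(time, event, x, grid = seq(-3, 3, by = 1e-4)) {
  logpl <- vapply(grid, function(b) {
    s <- 0
    for (t in sort(unique(time[event == 1]))) {
      dead <- which(time == t & event == 1)
      risk <- which(time >= t)
      s <- s + b * sum(x[dead]) - length(dead) * log(sum(exp(b * x[risk])))
    }
    s
  }, numeric(1))
  grid[which.max(logpl)]
}

# uniform random core: one core of n cells at random positions
randomCore <- function(n, core_id = "C1", patient_id = "P1", seed = 1,
                       phenotypes = c("A", "B", "C")) {
  set.seed(seed)
  data.frame(
    cell_id = sprintf("c%05d", seq_len(n)),
    core_id = core_id, patient_id = patient_id,
    x_um = runif(n, 0, 600), y_um = runif(n, 0, 600),
    compartment = sample(c("epithelium", "stroma"), n, replace = TRUE),
    phenotype = sample(phenotypes, n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# Minimal NeighborhoodModel straight from slots (for metric unit tests).
makeModel <- function(centroids, labels = NULL, k = 10L,
                      names = paste0("N", seq_len(nrow(centroids)) - 1L)) {
  n <- nrow(centroids)
  if (is.null(labels))
    labels <- data.frame(cell_id = character(), core_id = character(),
                         patient_id = character(), neighborhood = integer())
  new("NeighborhoodModel", k = as.integer(k), n = as.integer(n),
      centroids = centroids, labels = labels,
      categories = colnames(centroids), inertia = 0, seed = 1L,
      nbhdNames = names)
}

# Cohort config with three spatially segregated pure-phenotype archetypes
# planted as hotspots (no background cells): ground truth for clustering
# recovery. Phenotypes chosen so profiles form three well-separated
# composition archetypes.
archetypeConfig <- function(n_patients = 40L, seed = 1L, cell_count = 120,
                            n_per_core = 1) {
  simulationConfig(
    n_patients = n_patients, cores_per_patient = 2L, n_nests = 0L,
    cell_intensity_epithelium = 0, cell_intensity_stroma = 0,
    hotspot_spec = list(
      hotspotSpec(cell_count = cell_count, n_per_core = n_per_core,
                  radius = 0.04, anchor = "stroma",
                  composition = c(PanCK = 0.9, CD68 = 0.1)),
      hotspotSpec(cell_count = cell_count, n_per_core = n_per_core,
                  radius = 0.04, anchor = "stroma",
                  composition = c(CD3 = 0.9, CD3_CD16a = 0.1)),
      hotspotSpec(cell_count = cell_count, n_per_core = n_per_core,
                  radius = 0.04, anchor = "stroma",
                  composition = c(CD16a = 0.9, CD94_CD16a = 0.1))),
    survival_spec = list(baseline_hazard_os = 1 / 36,
                         baseline_hazard_pfs = 1 / 18,
                         censoring_window = c(0, 120), age_center = 60,
                         betas = c(), coverage_terms = list()),
    seed = seed)
}

# Reduced-cellularity cohort whose above-mean planted CD16a hotspot
# coverage carries a known OS hazard ratio: the end-to-end power testbed.
powerConfig <- function(n_patients, hr = 0.7, seed = 1L) {
  simulationConfig(
    n_patients = n_patients, cores_per_patient = 2L, n_nests = 3L,
    nest_radius_range = c(0.05, 0.08),
    cell_intensity_epithelium = 500, cell_intensity_stroma = 200,
    hotspot_spec = list(hotspotSpec(cell_count = 50, n_per_core = 1)),
    survival_spec = list(
      baseline_hazard_os = 1 / 36, baseline_hazard_pfs = 1 / 18,
      censoring_window = c(0, 120), age_center = 60, betas = c(),
      coverage_terms = list(list(hotspot = 1L, coding = "above_mean",
                                 beta = log(hr)))),
    emit = "pos", seed = seed)
}
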