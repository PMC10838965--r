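test_that("kNN profiles equal the full-distance-matrix oracle", {
  for (s in 1:2) {
    tab <- randomCore(400, seed = s)
    prof <- neighborProfiles(tab, k = 15L)
    oracle <- bruteForceProfiles(tab, 15L)
    cats <- attr(prof, "categories")
    prof <- prof[order(prof$cell_id), ]
    oracle <- oracle[order(oracle$cell_id), ]
    expect_equal(unname(as.matrix(prof[cats])),
                 unname(as.matrix(oracle[cats])))
  }
})

test_that("profile counts always sum to k and degenerate cores work", {
  tab <- data.frame(cell_id = paste0("c", 1:4), core_id = "C", patient_id = "P",
                    x_um = c(0, 10, 20, 30), y_um = 0,
                    compartment = "stroma", phenotype = "A")
  prof <- neighborProfiles(tab, k = 3L)
  expect_equal(prof$S_A, rep(3L, 4))

  tab2 <- randomCore(200, seed = 5)
  prof2 <- neighborProfiles(tab2)  # default k
  expect_equal(attr(prof2, "k"), 15L)
  expect_true(all(rowSums(prof2[attr(prof2, "categories")]) == 15L))

  expect_error(neighborProfiles(tab, k = 0L), "k must be")
  dup <- tab; dup$cell_id[2] <- dup$cell_id[1]
  expect_error(neighborProfiles(dup, k = 2L), "duplicate cell_id")
  # undersized cores are excluded with a warning
  small <- rbind(tab, transform(randomCore(30, core_id = "C2", seed = 2),
                                phenotype = "A", compartment = "stroma"))
  expect_warning(p <- neighborProfiles(small, k = 10L), "excluded")
  expect_false("C" %in% p$core_id)
})

test_that("co-localization rows are percentages that reflect spatial mixing", {
  # single-phenotype cohort: 100% on the diagonal
  tab <- randomCore(50, seed = 3, phenotypes = "A")
  prof <- neighborProfiles(tab, k = 5L)
  M <- colocalizationMatrix(prof, tab)
  expect_equal(M["A", "A"], 100)

  # alternating stripes: interior cells see ~50/50 at k = 4
  g <- expand.grid(x = 1:30, y = 1:30)
  tab2 <- data.frame(cell_id = sprintf("c%04d", seq_len(nrow(g))),
                     core_id = "C", patient_id = "P",
                     x_um = g$x * 10, y_um = g$y * 10,
                     compartment = "stroma",
                     phenotype = ifelse(g$x %% 2 == 0, "A", "B"))
  prof2 <- neighborProfiles(tab2, k = 4L)
  M2 <- colocalizationMatrix(prof2, tab2)
  expect_lt(abs(M2["A", "A"] - 50), 5)
  expect_lt(abs(M2["B", "B"] - 50), 5)
  # row normalization holds on any input
  expect_equal(unname(rowSums(M2)), rep(100, nrow(M2)), tolerance = 1e-6)
})

test_that("neighborhood clustering recovers planted profile archetypes", {
  # two archetypes far apart relative to within-spread
  set.seed(6)
  k <- 10L
  arch <- rbind(c(10, 0, 0), c(0, 6, 4))
  X <- arch[rep(1:2, each = 150), ]
  prof <- data.frame(cell_id = sprintf("c%04d", 1:300), core_id = "C",
                     patient_id = "P", A = X[, 1], B = X[, 2], C = X[, 3])
  attr(prof, "k") <- k
  attr(prof, "categories") <- c("A", "B", "C")
  attr(prof, "mode") <- "phenotype"
  m <- clusterNeighborhoods(prof, n = 2L, seed = 3L)
  truth <- rep(1:2, each = 150)
  expect_equal(mclust::adjustedRandIndex(m@labels$neighborhood, truth), 1)

  expect_error(clusterNeighborhoods(prof, n = 301L), "more neighborhoods")
  expect_warning(m1 <- clusterNeighborhoods(prof, n = 1L), "degenerate")
  cov1 <- neighborhoodCoverage(m1)
  expect_true(all(cov1$core$N0 == 1))
})

test_that("composition z-scores are centered and flag planted enrichment", {
  ctr <- rbind(c(9, 1, 0), c(1, 8, 1), c(0, 1, 9))
  colnames(ctr) <- c("E_PanCK", "S_Other", "S_CD16a")
  m <- makeModel(ctr)
  Z <- neighborhoodComposition(m)
  expect_equal(unname(colMeans(Z)), rep(0, 3), tolerance = 1e-9)
  expect_equal(which.max(Z[3, ]), c(S_CD16a = 3L))

  m1 <- makeModel(ctr[1, , drop = FALSE])
  Z1 <- neighborhoodComposition(m1)
  expect_true(attr(Z1, "degenerate"))
  expect_equal(unname(Z1[1, ]), unname(ctr[1, ]))
})

test_that("centroid cosine similarity matches closed forms", {
  ctr <- rbind(a = c(1, 1, 0), b = c(1, 0, 1), c = c(1, 1, 0),
               d = c(0, 0, 0), e = c(0, 1, 0))
  colnames(ctr) <- c("x", "y", "z")
  m <- makeModel(ctr)
  s <- neighborhoodSimilarity(m, threshold = 0.95)
  expect_equal(s$similarity["a", "b"], 0.5)
  expect_equal(s$similarity["a", "c"], 1)
  expect_true(is.na(s$similarity["d", "a"]))
  # orthogonal pair not flagged; identical pair flagged
  expect_equal(s$similarity["b", "e"], 0)
  expect_true(any(s$flagged$i == 0 & s$flagged$j == 2))
  expect_false(any(s$flagged$i == 1 & s$flagged$j == 4))
})

test_that("coverage fractions and ratios follow hand counts", {
  lab <- data.frame(
    cell_id = sprintf("c%02d", 1:20),
    core_id = rep(c("C1", "C2"), each = 10),
    patient_id = "P1",
    neighborhood = c(rep(0L, 7), rep(1L, 3),   # core 1: 0.7 / 0.3
                     rep(0L, 8), rep(1L, 2)))  # core 2: 0.8 / 0.2
  ctr <- rbind(c(1, 0), c(0, 1)); colnames(ctr) <- c("E_PanCK", "S_CD16a")
  m <- makeModel(ctr, labels = lab, names = c("A", "B"))
  cov <- neighborhoodCoverage(m)
  expect_equal(cov$core$A, c(0.7, 0.8))
  expect_equal(cov$core$B, c(0.3, 0.2))
  expect_equal(unname(rowSums(cov$core[c("A", "B")])), c(1, 1),
               tolerance = 1e-9)
  # patient value averages duplicate cores
  expect_equal(cov$patient$A, 0.75)
  expect_equal(cov$patient$B, 0.25)

  r <- coverageRatio(list(patient = data.frame(patient_id = "P1",
                                               A = 0.5, B = 0.25)), "A", "B")
  expect_equal(r$ratio, 2)
  r0 <- coverageRatio(list(patient = data.frame(patient_id = "P1",
                                                A = 0, B = 0.25)), "A", "B")
  expect_equal(r0$ratio, 0)
  expect_message(
    rz <- coverageRatio(list(patient = data.frame(patient_id = "P1",
                                                  A = 0.5, B = 0)), "A", "B"),
    "zero denominator")
  expect_true(is.na(rz$ratio))
  expect_error(coverageRatio(list(patient = data.frame(patient_id = "P1",
                                                       A = 1)), "A", "Z"),
               "unknown neighborhood")
})

test_that("rule-based names match neighborhood content", {
  ctr <- rbind(c(14, 1, 0, 0, 0),    # almost pure epithelial tumor cells
               c(0, 0, 14, 1, 0),    # stromal, immune-poor
               c(1, 1, 3, 2, 8),     # stromal CD16a-dominated
               c(2, 2, 4, 5, 2))     # mixed immune
  colnames(ctr) <- c("E_PanCK", "E_CD3", "S_Other", "S_CD3", "S_CD16a")
  m <- makeModel(ctr, k = 15L)
  m <- annotateNeighborhoods(m)
  nms <- neighborhoodNames(m)
  expect_equal(nms[1], "cold epithelium")
  expect_equal(nms[2], "cold stroma")
  expect_equal(nms[3], "CD16a enriched stroma")
  expect_equal(nms[4], "immune-rich")

  # phenotype-only categories: an all-Other neighborhood is unresolvable
  ctr2 <- rbind(c(0, 10), c(8, 2))
  colnames(ctr2) <- c("CD3", "Other")
  m2 <- makeModel(ctr2, k = 10L)
  expect_equal(neighborhoodNames(annotateNeighborhoods(m2))[1], "N0")
  # manual overrides always win
  m3 <- annotateNeighborhoods(m2, overrides = c("0" = "custom"))
  expect_equal(neighborhoodNames(m3)[1], "custom")
})

test_that("profiles and labels are invariant under rigid motions", {
  tab <- randomCore(300, seed = 9)
  prof <- neighborProfiles(tab, k = 10L)
  th <- pi / 5
  rot <- tab
  rot$x_um <- cos(th) * tab$x_um - sin(th) * tab$y_um + 500
  rot$y_um <- sin(th) * tab$x_um + cos(th) * tab$y_um - 120
  profR <- neighborProfiles(rot, k = 10L)
  cats <- attr(prof, "categories")
  expect_equal(prof[cats], profR[cats])
  mA <- clusterNeighborhoods(prof, n = 3L, seed = 4L)
  mB <- clusterNeighborhoods(profR, n = 3L, seed = 4L)
  expect_equal(mA@labels$neighborhood, mB@labels$neighborhood)
})

test_that("restarts never increase k-means inertia", {
  set.seed(11)
  X <- matrix(rnorm(600), ncol = 3)
  f10 <- spatialTMA:::.kmeansFit(X, 4L, nstart = 10L, seed = 2L)
  for (s in 1:5) {
    f1 <- spatialTMA:::.kmeansFit(X, 4L, nstart = 1L, seed = s)
    expect_lte(f10$tot.withinss, f1$tot.withinss + 1e-8)
  }
})

test_that("selectKN flags redundancy and recommends the planted count", {
  # six well-separated spatial patches of pure phenotypes in one core
  set.seed(12)
  centers <- cbind(x = c(0, 400, 800, 0, 400, 800),
                   y = c(0, 0, 0, 400, 400, 400))
  rows <- list()
  for (i in 1:6) {
    n <- 80
    rows[[i]] <- data.frame(
      cell_id = sprintf("p%d_%03d", i, 1:n), core_id = "C", patient_id = "P",
      x_um = centers[i, "x"] + runif(n, 0, 60),
      y_um = centers[i, "y"] + runif(n, 0, 60),
      compartment = "stroma",
      # near-pure patches with a patch-private minority phenotype, so
      # profiles vary within an archetype but any extra cluster can only
      # be a near-parallel split of one archetype
      phenotype = sample(paste0(c("T", "U"), i), n, TRUE, c(0.9, 0.1)))
  }
  tab <- do.call(rbind, rows)
  res <- selectKN(tab, kGrid = 10L, nGrid = 3:8, seed = 2L)
  expect_equal(unname(res$recommended["n"]), 6L)
  d <- res$diagnostics
  expect_equal(d$n_flagged[d$n == 6], 0L)
  expect_gt(d$n_flagged[d$n == 8], 0L)

  # a single archetype (one dominant phenotype with trace admixture):
  # every n >= 2 yields near-parallel centroids, flagged; no recommendation
  set.seed(13)
  tab1 <- transform(randomCore(300, seed = 13), compartment = "stroma",
                    phenotype = sample(c("A", "B"), 300, TRUE, c(0.95, 0.05)))
  expect_message(res1 <- selectKN(tab1, kGrid = 10L, nGrid = 2:4, seed = 2L),
                 "no \\(k, n\\)")
  expect_null(res1$recommended)
  expect_true(all(res1$diagnostics$n_flagged > 0))
})
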