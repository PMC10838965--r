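test_that("log normalization is log1p with rank preservation", {
  expect_equal(logNormalize(0), 0)
  expect_equal(logNormalize(exp(1) - 1), 1)
  expect_error(logNormalize(c(1, -0.5)), "negative")
  set.seed(7)
  x <- runif(2000, 0, 100)
  y <- logNormalize(x)
  i <- sample(2000, 1000); j <- sample(2000, 1000)
  expect_true(all(sign(y[i] - y[j]) == sign(x[i] - x[j])))
})

test_that("panel-1 gating partitions all 32 marker combinations", {
  h <- defaultHierarchy("panel1")
  mk <- markerPanel("panel1")
  combos <- expand.grid(rep(list(0:1), 5))
  names(combos) <- paste0("pos_", mk)
  combos$cell_id <- seq_len(32)
  out <- assignPhenotypes(combos, h)
  expect_equal(nrow(out), 32L)
  expect_false(anyNA(out$phenotype))
  expect_true(all(out$phenotype %in% phenotypeLevels(h)))
  # panCK dominates regardless of all other markers
  expect_true(all(out$phenotype[combos$pos_panCK == 1] == "PanCK"))
  # all-negative cells are Other
  allneg <- rowSums(combos[paste0("pos_", mk)]) == 0
  expect_equal(out$phenotype[allneg], "Other")
  # CD16a splits the myeloid, T and NK lineages
  pick <- function(...) {
    v <- setNames(rep(0, 5), paste0("pos_", mk)); v[paste0("pos_", c(...))] <- 1
    r <- which(apply(combos[paste0("pos_", mk)], 1,
                     function(z) all(z == v)))
    out$phenotype[r]
  }
  expect_equal(pick("CD68", "CD16a"), "CD68_CD16a")
  expect_equal(pick("CD3", "CD16a"), "CD3_CD16a")
  expect_equal(pick("CD94", "CD16a"), "CD94_CD16a")
  expect_equal(pick("CD16a"), "CD16a")
  # CD94 on T cells is an attribute, not a class
  tcd94 <- out[combos$pos_panCK == 0 & combos$pos_CD68 == 0 &
                 combos$pos_CD3 == 1 & combos$pos_CD94 == 1, ]
  expect_true(all(tcd94$phenotype %in% c("CD3", "CD3_CD16a")))
  expect_true(all(tcd94$mod_CD94 == 1))
})

test_that("panel-2 gating is a total function on 128 combinations", {
  h <- defaultHierarchy("panel2")
  mk <- markerPanel("panel2")
  combos <- expand.grid(rep(list(0:1), 7))
  names(combos) <- paste0("pos_", mk)
  out <- assignPhenotypes(combos, h)
  expect_false(anyNA(out$phenotype))
  expect_true(all(out$phenotype %in% phenotypeLevels(h)))
  i <- which(combos$pos_CD68 == 1 & combos$pos_CD163 == 1 &
               combos$pos_CD16a == 1 & combos$pos_panCK == 0)
  expect_true(all(out$phenotype[i] == "CD68_CD163_CD16a"))
})

test_that("gating rejects missing or malformed calls", {
  h <- defaultHierarchy("panel1")
  df <- data.frame(pos_panCK = 1, pos_CD68 = 0, pos_CD3 = 0, pos_CD94 = 0)
  expect_error(assignPhenotypes(df, h), "pos_CD16a")
  df$pos_CD16a <- NA
  expect_error(assignPhenotypes(df, h), "missing marker call")
  df$pos_CD16a <- 2
  expect_error(assignPhenotypes(df, h), "0/1")
  expect_error(gatingHierarchy(c("a", "b"), list(
    list(label = "A", positive = "a", negative = character(),
         splits = character(), attrs = character()))),
    "not covered")
})

test_that("expression clustering finds the knee of the dispersion curve", {
  set.seed(3)
  X <- rbind(matrix(rnorm(300, 0, 0.3), ncol = 3),
             matrix(rnorm(300, 5, 0.3), ncol = 3))
  m <- clusterExpression(X, candidates = 1:6, seed = 2L)
  expect_equal(m@nClusters, 2L)
  grp <- m@clusterIds
  expect_equal(length(unique(grp[1:100])), 1L)
  expect_equal(length(unique(grp[101:200])), 1L)
  expect_false(grp[1] == grp[101])

  # identical cells: zero dispersion at one cluster, elbow selects 1
  X0 <- matrix(1, nrow = 50, ncol = 3)
  m0 <- clusterExpression(X0, candidates = 1:3, seed = 1L)
  expect_equal(m0@nClusters, 1L)
  expect_equal(m0@elbow$withinss[1], 0)

  # a single candidate is honoured exactly (e.g. a configured count of 43)
  set.seed(8)
  Xb <- matrix(rnorm(600), ncol = 3)
  m43 <- clusterExpression(Xb, candidates = 43L, seed = 1L)
  expect_equal(m43@nClusters, 43L)
  expect_equal(nrow(m43@centers), 43L)
  expect_error(clusterExpression(Xb[1:10, ], candidates = 11L),
               "more clusters")
})

test_that("cluster means gate to phenotypes like single cells do", {
  h <- defaultHierarchy("panel1")
  mk <- markerPanel("panel1")
  centers <- rbind(
    panCKonly = c(panCK = 2, CD68 = 0.1, CD3 = 0.1, CD94 = 0, CD16a = 0.1),
    allneg = c(panCK = 0.1, CD68 = 0.2, CD3 = 0.1, CD94 = 0.1, CD16a = 0.2),
    tcell16 = c(panCK = 0.1, CD68 = 0.2, CD3 = 2, CD94 = 0.1, CD16a = 2))
  model <- new("ExpressionClusterModel", nClusters = 3L,
               centers = centers[, mk], clusterIds = c(1L, 2L, 3L),
               elbow = data.frame(k = 3, withinss = 0), markers = mk,
               seed = 1L)
  thr <- setNames(rep(0.5, 5), mk)
  map <- clusterToPhenotype(model, h, thr)
  expect_equal(map$phenotype, c("PanCK", "Other", "CD3_CD16a"))
  expect_error(clusterToPhenotype(model, h, thr[-1]), "panCK")
})

test_that("the clustering route recovers ground-truth phenotypes", {
  cfg <- simulationConfig(n_patients = 4L, emit = c("phenotype", "pos",
                                                    "intensity"),
                          seed = 31L)
  co <- simulateCohort(cfg)
  tab <- cells(co)
  truthPhen <- tab$phenotype

  # gating on calls reproduces the generative phenotype exactly
  gated <- assignPhenotypes(tab[setdiff(names(tab), "phenotype")],
                            defaultHierarchy("panel1"))
  expect_equal(gated$phenotype, truthPhen)

  # clustering well-separated intensities recovers >= 99% of labels
  intens <- tab[setdiff(names(tab), c("phenotype",
                                      grep("^pos_", names(tab), value = TRUE)))]
  clustered <- phenotypeCells(intens, defaultHierarchy("panel1"),
                              candidates = 12L, seed = 5L)
  expect_gt(mean(clustered$phenotype == truthPhen), 0.99)
})

test_that("cell order does not change gating labels", {
  cfg <- simulationConfig(n_patients = 2L, emit = "pos", seed = 17L)
  tab <- cells(simulateCohort(cfg))
  h <- defaultHierarchy("panel1")
  a <- assignPhenotypes(tab, h)
  set.seed(2)
  perm <- sample(nrow(tab))
  b <- assignPhenotypes(tab[perm, ], h)
  expect_equal(b$phenotype[order(perm)], a$phenotype)
})

test_that("Otsu threshold separates two well-separated components", {
  set.seed(4)
  x <- c(rnorm(500, 1, 0.2), rnorm(500, 4, 0.2))
  thr <- otsuThreshold(x)
  # the cut must classify the two components nearly perfectly
  expect_gt(mean((x > thr) == rep(c(FALSE, TRUE), each = 500)), 0.995)
  expect_equal(otsuThreshold(rep(2, 10)), 2)
})
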