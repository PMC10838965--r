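test_that("densities divide counts by compartment area and average cores", {
  # 50 stromal cells on 0.25 mm^2 -> 200 cells/mm^2
  mkCore <- function(core, n) data.frame(
    cell_id = sprintf("%s_%03d", core, seq_len(n)), core_id = core,
    patient_id = "P1", x_um = seq_len(n), y_um = 0,
    compartment = "stroma", phenotype = "CD3")
  cells <- rbind(mkCore("C1", 50), mkCore("C2", 150))
  areas <- data.frame(core_id = c("C1", "C2"), patient_id = "P1",
                      area_epithelium_mm2 = 0.1,
                      area_stroma_mm2 = c(0.25, 0.5))
  d <- cellDensities(cells, areas)
  s <- d[d$compartment == "stroma" & d$phenotype == "CD3", ]
  # core densities 200 and 300 average to 250 for the patient
  expect_equal(s$density, 250)
  # zero cells is density 0, not missing
  e <- d[d$compartment == "epithelium", ]
  expect_equal(e$density, 0)

  # explicit duplicate-core averaging: 100 and 300 -> 200
  cells2 <- rbind(mkCore("C1", 25), mkCore("C2", 75))
  areas2 <- transform(areas, area_stroma_mm2 = 0.25)
  d2 <- cellDensities(cells2, areas2)
  expect_equal(d2$density[d2$compartment == "stroma"], 200)
})

test_that("dichotomization follows the stated tie and quartile rules", {
  g <- dichotomize(c(1, 2, 3, 4), "median")
  expect_equal(as.character(g), c("low", "low", "high", "high"))
  expect_equal(attr(g, "split"), 2.5)
  # ties go low under the median rule
  g2 <- dichotomize(c(1, 2, 2, 4), "median")
  expect_equal(as.character(g2), c("low", "low", "low", "high"))
  gm <- dichotomize(c(0, 0, 10, 2), "mean")
  expect_equal(as.character(gm), c("low", "low", "high", "low"))
  q <- dichotomize(1:8, "quartile")
  expect_equal(as.character(q), c("Q1", "Q1", NA, NA, NA, NA, "Q4", "Q4"))
  expect_warning(gd <- dichotomize(rep(3, 5)), "degenerate")
  expect_true(attr(gd, "degenerate"))
  expect_error(dichotomize(c(1, NA)), "at least 2")
})

test_that("Cox estimates match the explicit partial-likelihood oracle", {
  time <- c(1, 2, 3, 4); event <- c(1, 1, 1, 1)
  x <- c(0, 1, 0, 1)
  df <- data.frame(os_months = time, os_event = event, x = x)
  fit <- coxUnivariate(df, "x", "os", horizon = 60)
  bOracle <- coxGridOracle(time, event, x)
  expect_lt(abs(log(fit$hr) - bOracle), 1e-3)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)
  expect_equal(fit$n, 4L)
  expect_equal(fit$n_events, 4L)

  # a perfectly separated toy (all A failures precede all B) has a
  # monotone partial likelihood and must be flagged
  sep <- data.frame(os_months = time, os_event = event, x = c(0, 0, 1, 1))
  fsep <- coxUnivariate(sep, "x", "os", horizon = 60)
  expect_true(fsep$flagged)

  # administrative censoring truncates times and events at the horizon
  ac <- adminCensor(c(10, 59, 61, 100), c(1, 0, 1, 1), 60)
  expect_true(all(ac$time <= 60))
  expect_equal(ac$event, c(1, 0, 0, 0))

  # no events after truncation -> missing result, flagged
  df2 <- data.frame(os_months = c(70, 80), os_event = c(1, 1))
  df2$x <- c(0, 1)
  expect_warning(r2 <- coxUnivariate(df2, "x", "os", 60), "no events")
  expect_null(r2)
})

test_that("multivariate Cox reduces to univariate and attenuates proxies", {
  set.seed(20)
  n <- 2000
  x1 <- rbinom(n, 1, 0.5)
  x2 <- ifelse(runif(n) < 0.85, x1, 1 - x1)  # correlated proxy of x1
  t_ev <- rexp(n, 1 / 36 * exp(log(0.6) * x1))
  cens <- runif(n, 0, 120)
  df <- data.frame(os_months = pmin(t_ev, cens),
                   os_event = as.integer(t_ev <= cens), x1 = x1, x2 = x2)
  # single variable: multivariate equals univariate
  single <- coxMultivariate(df, "x1", "os", select = FALSE)
  uni <- coxUnivariate(df, "x1", "os")
  expect_equal(single$multivariate$hr, uni$hr, tolerance = 1e-10)
  # joint model: causal variable keeps its effect, proxy attenuates
  both <- coxMultivariate(df, c("x1", "x2"), "os", select = FALSE)
  hrs <- setNames(both$multivariate$hr, both$multivariate$variable)
  uniProxy <- coxUnivariate(df, "x2", "os")
  expect_lt(hrs[["x1"]], 0.75)
  expect_lt(abs(log(hrs[["x2"]])), abs(log(uniProxy$hr)))
  # selection keeps only univariately significant variables
  sel <- coxMultivariate(df, c("x1", "x2"), "os", select = TRUE)
  expect_true("x1" %in% sel$selected)
  # collinear duplicate is dropped with a warning
  df$x3 <- df$x1
  expect_warning(coll <- coxMultivariate(df, c("x1", "x3"), "os",
                                         select = FALSE), "collinear")
  expect_false(any(is.na(coll$multivariate$hr)))
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(fdrAdjust(0.03), 0.03)
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(5)
  p <- runif(50)
  expect_true(all(fdrAdjust(p) >= p))
  # monotone in the ranks of raw p
  adj <- fdrAdjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(fdrAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Pearson matrix matches closed forms and handles degeneracy", {
  x <- c(1, 2, 3); y <- c(2, 4, 7)
  M <- pearsonMatrix(cbind(x = x, y = y, z = -x))
  expect_equal(M["x", "y"], 0.99339927, tolerance = 1e-6)
  expect_equal(M["x", "x"], 1)
  expect_equal(M["x", "z"], -1)
  Mz <- pearsonMatrix(cbind(x = x, c = rep(2, 3)))
  expect_true(all(is.na(Mz["c", ])))
  # fewer than 3 complete pairs -> NA
  Mp <- pearsonMatrix(cbind(a = c(1, 2, NA, NA), b = c(1, NA, 2, 3)))
  expect_true(is.na(Mp["a", "b"]))
})

test_that("ANOVA F matches the hand-computed table and the permutation null", {
  df <- data.frame(v = c(1, 2, 3, 4, 5, 6),
                   g = rep(c("a", "b"), each = 3))
  out <- anovaFdr(df, "v", "g")
  expect_equal(out$F, 13.5, tolerance = 1e-9)
  # identical groups: F = 0, p = 1
  df0 <- data.frame(v = c(1, 2, 3, 1, 2, 3), g = rep(c("a", "b"), each = 3))
  out0 <- anovaFdr(df0, "v", "g")
  expect_equal(out0$F, 0, tolerance = 1e-12)
  expect_equal(out0$p, 1, tolerance = 1e-12)
  # permutation null: p-values uniform
  set.seed(9)
  v <- rnorm(20)
  ps <- replicate(1000, {
    g <- sample(rep(c("a", "b"), each = 10))
    anovaFdr(data.frame(v = v, g = g), "v", "g")$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  # two-way: main effects and interaction, BH across the family
  set.seed(10)
  df2 <- data.frame(v = rnorm(40), f1 = rep(c("x", "y"), 20),
                    f2 = rep(c("u", "w"), each = 20))
  out2 <- anovaFdr(df2, "v", c("f1", "f2"))
  expect_setequal(out2$effect, c("f1", "f2", "f1:f2"))
  expect_true(all(out2$p_adj >= out2$p))
})

test_that("Kaplan-Meier steps follow the product-limit formula", {
  df <- data.frame(os_months = c(1, 2, 3), os_event = 1)
  km <- kmCurve(df, NULL, "os")
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # a censored observation after the last event adds no step: drops occur
  # only at the event times, with hand-computed product-limit values
  df2 <- rbind(df, data.frame(os_months = 10, os_event = 0))
  km2 <- kmCurve(df2, NULL, "os")
  expect_equal(km2$time[km2$n_event > 0], c(1, 2, 3))
  expect_equal(km2$surv[km2$n_event > 0], c(3 / 4, 1 / 2, 1 / 4))
  expect_equal(km2$surv[km2$time == 10], 1 / 4)
  # no events: flat curve at 1
  df3 <- data.frame(os_months = c(5, 8), os_event = 0)
  km3 <- kmCurve(df3, NULL, "os")
  expect_true(all(km3$surv == 1))

  # KM and Cox agree directionally on a cohort with a true effect
  set.seed(30)
  n <- 400
  grp <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 1 / 36 * exp(log(2) * grp))
  cens <- runif(n, 0, 120)
  d <- data.frame(os_months = pmin(t_ev, cens),
                  os_event = as.integer(t_ev <= cens),
                  grp = factor(ifelse(grp == 1, "high", "low"),
                               levels = c("low", "high")))
  fit <- coxUnivariate(d, "grp", "os")
  expect_gt(fit$hr, 1)
  km4 <- kmCurve(d, "grp", "os")
  lastLow <- min(km4$surv[km4$group == "low"])
  lastHigh <- min(km4$surv[km4$group == "high"])
  expect_lt(lastHigh, lastLow)
})
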