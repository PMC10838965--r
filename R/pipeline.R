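# Pipeline orchestration: canonical file formats, a single run config,
# stage sequencing, logging, and the report bundle.

#' Read the canonical cell table
#'
#' Comma-separated, UTF-8, "." decimal, missing = empty field. Required
#' columns: \code{cell_id}, \code{core_id}, \code{patient_id},
#' \code{x_um}, \code{y_um} (micrometres, origin per core, y downward),
#' \code{compartment}; marker information as \code{marker_<name>},
#' \code{pos_<name>} or a ready \code{phenotype} column. Unknown columns
#' are preserved.
#'
#' @param path file path.
#' @return validated cell data.frame.
#' @export
readCellTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(REQUIRED_CELL_COLS, names(df))
  if (length(miss))
    stop("cell table missing required column(s): ",
         paste(miss, collapse = ", "))
  for (cc in c("x_um", "y_um")) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop("non-numeric ", cc, " at data row ", bad)
    }
  }
  if (anyDuplicated(paste(df$core_id, df$cell_id, sep = "\r"))) {
    dup <- which(duplicated(paste(df$core_id, df$cell_id, sep = "\r")))[1L]
    stop("duplicate (core_id, cell_id) at data row ", dup)
  }
  df
}

#' Write a table in the canonical CSV dialect
#' @param df data.frame.
#' @param path file path.
#' @export
writeCellTable <- function(df, path) {
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read the patient-level clinical table
#' @param path CSV with a \code{patient_id} column.
#' @return data.frame.
#' @export
readClinicalTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(df))
    stop("clinical table missing required column: patient_id")
  df
}

.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  # hash a canonical text rendering, stable across sessions
  writeLines(deparse(config, control = c("all", "digits17")), tmp)
  unname(tools::md5sum(tmp))
}

#' Assemble a pipeline run configuration
#'
#' Exactly one of \code{simulation} (a \code{\link{simulationConfig}}) or
#' \code{cell_table}+\code{clinical_table} paths must be given.
#'
#' @param simulation optional \code{\link{simulationConfig}}.
#' @param cell_table,clinical_table optional input CSV paths.
#' @param hierarchy gating hierarchy (default panel 1).
#' @param thresholds optional named positivity thresholds.
#' @param k neighbors per profile (default 15).
#' @param n neighborhoods (default 6).
#' @param split dichotomization mode for coverage Cox models.
#' @param endpoints survival endpoints to analyze.
#' @param horizon months of administrative censoring (default 60).
#' @param ratio optional c(numerator, denominator) neighborhood names for
#'   the coverage-ratio analysis; defaults to CD16a enriched stroma over
#'   cold epithelium when both exist.
#' @param outdir output directory.
#' @param seed master seed (overrides the simulation config's).
#' @return a validated run-config list (class \code{"RunConfig"}).
#' @export
runConfig <- function(simulation = NULL, cell_table = NULL,
                      clinical_table = NULL,
                      hierarchy = defaultHierarchy("panel1"),
                      thresholds = NULL, k = 15L, n = 6L,
                      split = "median", endpoints = c("os", "pfs"),
                      horizon = 60, ratio = NULL,
                      outdir = tempfile("tma_run_"), seed = 1L) {
  hasSim <- !is.null(simulation)
  hasFiles <- !is.null(cell_table)
  if (hasSim == hasFiles)
    stop("exactly one of simulation or cell_table input must be given")
  if (hasSim) {
    stopifnot(inherits(simulation, "SimulationConfig"))
    simulation$seed <- as.integer(seed)
  }
  k <- as.integer(k); n <- as.integer(n)
  if (k < 1L) stop("k must be >= 1")
  if (n < 1L) stop("n must be >= 1")
  cfg <- list(simulation = simulation, cell_table = cell_table,
              clinical_table = clinical_table, hierarchy = hierarchy,
              thresholds = thresholds, k = k, n = n, split = split,
              endpoints = match.arg(endpoints, c("os", "pfs"),
                                    several.ok = TRUE),
              horizon = horizon, ratio = ratio, outdir = outdir,
              seed = as.integer(seed))
  class(cfg) <- "RunConfig"
  cfg
}

.emitCsv <- function(df, outdir, name) {
  p <- file.path(outdir, name)
  write.csv(df, p, row.names = FALSE, na = "")
  p
}

#' Run the full analysis pipeline
#'
#' Stages: simulate or load -> phenotype -> kNN profiles -> neighborhood
#' clustering -> annotation -> coverage and ratios -> cohort statistics.
#' Each stage's outputs are written before the next begins; failures
#' abort with the stage name. All exclusions (small cores, zero-area
#' compartments, zero-denominator ratios) are counted in the run log.
#'
#' @param config a \code{\link{runConfig}}.
#' @return invisibly, a report bundle: list with \code{manifest},
#'   \code{paths} (named output files), and the in-memory stage objects
#'   (\code{cohort}, \code{profiles}, \code{model}, \code{coverage},
#'   \code{results}).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  logLines <- character(0)
  note <- function(...) {
    logLines <<- c(logLines, paste0(...))
  }
  collect <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)),
      message = function(m) {
        note("[", stage, "] ", sub("\n$", "", conditionMessage(m)))
        invokeRestart("muffleMessage")
      },
      warning = function(w) {
        note("[", stage, "] warning: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  paths <- list()

  # --- input stage ---
  cohort <- collect("input", {
    if (!is.null(config$simulation)) simulateCohort(config$simulation)
    else {
      cellsDf <- readCellTable(config$cell_table)
      clin <- if (!is.null(config$clinical_table))
        readClinicalTable(config$clinical_table) else data.frame()
      areas <- .areasFromCells(cellsDf)
      new("TmaCohort", cells = cellsDf, clinical = clin, areas = areas,
          groundTruth = data.frame())
    }
  })
  paths$clinical <- .emitCsv(clinical(cohort), config$outdir, "clinical.csv")
  paths$areas <- .emitCsv(coreAreas(cohort), config$outdir, "areas.csv")
  if (nrow(groundTruth(cohort)))
    paths$ground_truth <- .emitCsv(groundTruth(cohort), config$outdir,
                                   "ground_truth.csv")

  # --- phenotyping stage ---
  cellsPh <- collect("phenotype",
    phenotypeCells(cells(cohort), hierarchy = config$hierarchy,
                   thresholds = config$thresholds, seed = config$seed))
  paths$cells <- .emitCsv(cellsPh, config$outdir, "cells.csv")

  # --- spatial profiling stage ---
  profiles <- collect("profiles",
    neighborProfiles(cellsPh, k = config$k))
  note("[profiles] ", length(attr(profiles, "excluded_cores")),
       " core(s) excluded (fewer than k+1 cells)")
  paths$profiles <- .emitCsv(profiles, config$outdir, "profiles.csv")
  coloc <- collect("profiles", colocalizationMatrix(profiles, cellsPh))
  paths$colocalization <- .emitCsv(
    data.frame(phenotype = rownames(coloc), as.data.frame(coloc),
               check.names = FALSE), config$outdir, "colocalization.csv")

  # --- neighborhood stage ---
  model <- collect("neighborhoods", {
    m <- clusterNeighborhoods(profiles, n = config$n, seed = config$seed)
    annotateNeighborhoods(m)
  })
  paths$labels <- .emitCsv(neighborhoodLabels(model), config$outdir,
                           "labels.csv")
  comp <- neighborhoodComposition(model)
  paths$composition <- .emitCsv(
    data.frame(neighborhood = neighborhoodNames(model), as.data.frame(comp),
               check.names = FALSE), config$outdir, "composition.csv")
  simil <- neighborhoodSimilarity(model)
  paths$similarity <- .emitCsv(
    as.data.frame(simil$similarity), config$outdir, "similarity.csv")
  note("[neighborhoods] ", nrow(simil$flagged),
       " highly similar centroid pair(s) at threshold ", simil$threshold)

  # --- coverage stage ---
  cov <- collect("coverage", neighborhoodCoverage(model, clinical(cohort)))
  paths$coverage_core <- .emitCsv(cov$core, config$outdir,
                                  "coverage_core.csv")
  paths$coverage_patient <- .emitCsv(cov$patient, config$outdir,
                                     "coverage_patient.csv")
  nms <- neighborhoodNames(model)
  ratioPair <- config$ratio
  if (is.null(ratioPair) &&
      all(c("CD16a enriched stroma", "cold epithelium") %in% nms))
    ratioPair <- c("CD16a enriched stroma", "cold epithelium")
  ratios <- NULL
  if (!is.null(ratioPair)) {
    ratios <- collect("coverage",
      coverageRatio(cov, ratioPair[1], ratioPair[2]))
    paths$ratios <- .emitCsv(ratios, config$outdir, "ratios.csv")
  }

  # --- statistics stage ---
  results <- collect("stats", {
    clin <- clinical(cohort)
    res <- list(cox = NULL, correlation = NULL, anova = NULL, km = NULL)
    if (nrow(clin) && all(c("os_months", "os_event") %in% names(clin))) {
      dat <- merge(clin, cov$patient, by = "patient_id")
      rows <- NULL
      for (ep in config$endpoints) for (nm in nms) {
        g <- tryCatch(dichotomize(dat[[nm]], config$split),
                      warning = function(w) {
                        note("[stats] degenerate split for ", nm)
                        NULL
                      })
        if (is.null(g)) next
        dat$.grp <- g
        r <- coxUnivariate(dat, ".grp", ep, config$horizon)
        if (!is.null(r)) { r$variable <- nm; rows <- rbind(rows, r) }
      }
      if (!is.null(ratios)) {
        dat2 <- merge(clin, ratios, by = "patient_id")
        for (ep in config$endpoints) {
          g <- tryCatch(dichotomize(dat2$ratio, config$split),
                        warning = function(w) NULL)
          if (is.null(g)) next
          dat2$.grp <- g
          r <- coxUnivariate(dat2, ".grp", ep, config$horizon)
          if (!is.null(r)) {
            r$variable <- paste(ratioPair, collapse = ":")
            rows <- rbind(rows, r)
          }
          res$km <- kmCurve(dat2, ".grp", ep, config$horizon)
        }
      }
      if (!is.null(rows)) {
        for (ep in unique(rows$endpoint)) {
          i <- rows$endpoint == ep
          rows$p_adj[i] <- fdrAdjust(rows$p[i])
        }
        res$cox <- rows
      }
      res$correlation <- pearsonMatrix(cov$patient[nms])
      if ("grade" %in% names(clin) && length(unique(clin$grade)) > 1L) {
        long <- stats::reshape(
          dat[c("patient_id", "grade", nms)], direction = "long",
          varying = nms, v.names = "coverage", timevar = "neighborhood",
          times = nms, idvar = "patient_id")
        res$anova <- tryCatch(
          anovaFdr(long, "coverage", c("neighborhood", "grade")),
          error = function(e) { note("[stats] ANOVA skipped: ",
                                     conditionMessage(e)); NULL })
      }
    } else note("[stats] no survival columns in clinical table; skipped")
    res
  })
  if (!is.null(results$cox))
    paths$cox <- .emitCsv(results$cox, config$outdir, "cox_results.csv")
  if (!is.null(results$correlation))
    paths$correlation <- .emitCsv(
      data.frame(variable = rownames(results$correlation),
                 as.data.frame(results$correlation), check.names = FALSE),
      config$outdir, "correlation.csv")
  if (!is.null(results$anova))
    paths$anova <- .emitCsv(results$anova, config$outdir, "anova.csv")
  if (!is.null(results$km))
    paths$km <- .emitCsv(results$km, config$outdir, "km.csv")

  manifest <- c(
    package = "spatialTMA",
    version = as.character(utils::packageVersion("spatialTMA")),
    config_hash = .configHash(unclass(config)[setdiff(names(config),
                                                      "outdir")]),
    seed = as.character(config$seed),
    k = as.character(config$k), n = as.character(config$n))
  writeLines(paste(names(manifest), manifest, sep = ": "),
             file.path(config$outdir, "manifest.txt"))
  writeLines(logLines, file.path(config$outdir, "run_log.txt"))
  paths$manifest <- file.path(config$outdir, "manifest.txt")
  paths$log <- file.path(config$outdir, "run_log.txt")

  invisible(list(manifest = manifest, paths = paths, cohort = cohort,
                 cells = cellsPh, profiles = profiles, model = model,
                 coverage = cov, ratios = ratios, results = results,
                 log = logLines))
}

# When cells come from a file without an area table, approximate each
# core's compartment areas from the convex bounding disc of its cells:
# the fallback keeps densities computable; real analyses should supply
# measured areas.
.areasFromCells <- function(cellsDf) {
  cores <- unique(cellsDf[c("core_id", "patient_id")])
  out <- cores
  out$area_epithelium_mm2 <- NA_real_
  out$area_stroma_mm2 <- NA_real_
  for (i in seq_len(nrow(cores))) {
    sub <- cellsDf[cellsDf$core_id == cores$core_id[i], ]
    r_mm <- max(sqrt(sub$x_um^2 + sub$y_um^2)) / 1000
    total <- pi * max(r_mm, 1e-6)^2
    fE <- mean(sub$compartment == "epithelium")
    out$area_epithelium_mm2[i] <- total * fE
    out$area_stroma_mm2[i] <- total * (1 - fE)
  }
  out
}

#' Scatter plot of a core colored by neighborhood
#'
#' Best-effort figure (requires ggplot2); the numeric CSVs are the
#' contract surface.
#'
#' @param model a \code{\linkS4class{NeighborhoodModel}}.
#' @param cellTable the phenotyped cell table.
#' @param core_id core to draw.
#' @return a ggplot object.
#' @export
plotNeighborhoods <- function(model, cellTable, core_id) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  lab <- neighborhoodLabels(model)
  lab <- lab[lab$core_id == core_id, ]
  sub <- cellTable[cellTable$core_id == core_id, ]
  sub <- merge(sub, lab[c("cell_id", "neighborhood")], by = "cell_id")
  sub$neighborhood <- factor(neighborhoodNames(model)[sub$neighborhood + 1L])
  ggplot2::ggplot(sub, ggplot2::aes(x = x_um, y = y_um,
                                    color = neighborhood)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = core_id, x = "x (um)", y = "y (um)")
}
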