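# Synthetic TMA cohort generator. Emulates the geometry of ~0.6 mm TMA
# cores (disc with epithelial nests embedded in stroma), compartment
# phenotype mixtures, spatially aggregated hotspots at nest boundaries,
# clinical covariates, and exponential proportional-hazards survival tied
# to planted hotspot coverage. Every quantity is recorded as ground truth
# so downstream recovery is testable.

.defaultEpitheliumMix <- function()
  c(PanCK = 0.92, CD68 = 0.01, CD68_CD16a = 0.005, CD3 = 0.02,
    CD3_CD16a = 0.005, CD94 = 0.01, CD94_CD16a = 0.0025, CD16a = 0.0075,
    Other = 0.02)

.defaultStromaMix <- function()
  c(PanCK = 0.08, CD68 = 0.08, CD68_CD16a = 0.03, CD3 = 0.10,
    CD3_CD16a = 0.02, CD94 = 0.02, CD94_CD16a = 0.005, CD16a = 0.065,
    Other = 0.60)

#' Default CD16a-enriched hotspot specification
#'
#' A spatial aggregate of CD16a-expressing cells anchored at the boundary
#' between an epithelial nest and the stroma, where such neighborhoods are
#' typically observed. The number of instances per core is Poisson so
#' planted coverage varies across patients.
#'
#' @param cell_count mean cells per hotspot instance.
#' @param n_per_core Poisson mean of instances per core.
#' @param radius hotspot radius in mm.
#' @param anchor one of "nest-boundary", "stroma", "epithelium".
#' @param composition phenotype probabilities (sum 1).
#' @export
hotspotSpec <- function(cell_count = 60, n_per_core = 1, radius = 0.04,
                        anchor = "nest-boundary",
                        composition = c(CD16a = 0.40, CD68_CD16a = 0.25,
                                        CD94_CD16a = 0.20, CD3_CD16a = 0.15)) {
  list(anchor = anchor, composition = composition, radius = radius,
       cell_count = cell_count, n_per_core = n_per_core)
}

#' Simulation configuration for a synthetic TMA cohort
#'
#' Defaults describe a plausible HGSC TMA: duplicate 0.6 mm-diameter cores
#' per patient, a few epithelial nests per core, denser cellularity in
#' epithelium than stroma, one CD16a hotspot spec at nest boundaries, and
#' exponential survival (baseline hazard 1/36 per month, uniform censoring
#' on [0, 120] months) with a protective effect of above-mean planted
#' hotspot coverage (hazard ratio 0.7).
#'
#' @param n_patients number of patients.
#' @param cores_per_patient cores per patient (>= 1; default duplicate cores).
#' @param core_radius core radius in mm.
#' @param n_nests epithelial nests per core.
#' @param nest_radius_range nest radius interval in mm.
#' @param cell_intensity_epithelium,cell_intensity_stroma Poisson
#'   intensities, cells/mm^2.
#' @param phenotype_mixture list with \code{epithelium} and \code{stroma}
#'   named probability vectors (each sums to 1).
#' @param hotspot_spec list of \code{\link{hotspotSpec}} entries (possibly
#'   empty).
#' @param covariate_spec clinical covariate distributions: \code{age_mean},
#'   \code{age_sd}, \code{stage_high_p}, \code{grade3_p}, \code{debulking_p},
#'   \code{chemo_sensitivity_p}.
#' @param survival_spec list: \code{baseline_hazard_os},
#'   \code{baseline_hazard_pfs} (per month), \code{censoring_window}
#'   (months, length 2), \code{age_center}, \code{betas} (named log-hazard
#'   coefficients over clinical covariates), \code{coverage_terms} (list of
#'   \code{list(hotspot=, coding="above_mean"|"linear", beta=)} on planted
#'   coverage).
#' @param emit which cell-level columns to write: any of
#'   \code{"phenotype"}, \code{"pos"} (binary calls), \code{"intensity"}
#'   (two-component lognormal marker signals).
#' @param marker_noise lognormal intensity parameters for
#'   \code{emit="intensity"}: \code{pos_meanlog}, \code{neg_meanlog},
#'   \code{sdlog}.
#' @param seed master seed; all per-core substreams derive from it.
#' @return validated config list (class \code{"SimulationConfig"}).
#' @export
simulationConfig <- function(n_patients = 20L,
                             cores_per_patient = 2L,
                             core_radius = 0.3,
                             n_nests = 3L,
                             nest_radius_range = c(0.04, 0.08),
                             cell_intensity_epithelium = 2000,
                             cell_intensity_stroma = 1000,
                             phenotype_mixture = list(
                               epithelium = .defaultEpitheliumMix(),
                               stroma = .defaultStromaMix()),
                             hotspot_spec = list(hotspotSpec()),
                             covariate_spec = list(
                               age_mean = 60, age_sd = 10,
                               stage_high_p = 0.6, grade3_p = 0.7,
                               debulking_p = 0.5, chemo_sensitivity_p = 0.7),
                             survival_spec = list(
                               baseline_hazard_os = 1 / 36,
                               baseline_hazard_pfs = 1 / 18,
                               censoring_window = c(0, 120),
                               age_center = 60,
                               betas = c(age = 0.02, stage = 0.3, grade = 0.1,
                                         debulking = -0.3,
                                         chemo_sensitivity = -0.5),
                               coverage_terms = list(
                                 list(hotspot = 1L, coding = "above_mean",
                                      beta = log(0.7)))),
                             emit = "phenotype",
                             marker_noise = list(pos_meanlog = 2.0,
                                                 neg_meanlog = 0.0,
                                                 sdlog = 0.25),
                             seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              cores_per_patient = as.integer(cores_per_patient),
              core_radius = core_radius, n_nests = as.integer(n_nests),
              nest_radius_range = nest_radius_range,
              cell_intensity_epithelium = cell_intensity_epithelium,
              cell_intensity_stroma = cell_intensity_stroma,
              phenotype_mixture = phenotype_mixture,
              hotspot_spec = hotspot_spec,
              covariate_spec = covariate_spec,
              survival_spec = survival_spec,
              emit = emit, marker_noise = marker_noise,
              seed = as.integer(seed))
  # coverage terms can only refer to hotspots that exist
  cfg$survival_spec$coverage_terms <-
    Filter(function(t) t$hotspot <= length(cfg$hotspot_spec),
           cfg$survival_spec$coverage_terms %||% list())
  class(cfg) <- "SimulationConfig"
  .validateSimulationConfig(cfg)
  cfg
}

.validateSimulationConfig <- function(cfg) {
  stopifnot(cfg$n_patients >= 0L, cfg$cores_per_patient >= 1L)
  if (cfg$core_radius <= 0) stop("core_radius must be > 0")
  if (cfg$n_nests > 0L) {
    if (any(cfg$nest_radius_range <= 0)) stop("nest radii must be > 0")
    if (max(cfg$nest_radius_range) >= cfg$core_radius)
      stop("nest radius must be smaller than the core radius")
  }
  if (cfg$cell_intensity_epithelium < 0 || cfg$cell_intensity_stroma < 0)
    stop("cell intensities must be >= 0")
  if (cfg$cell_intensity_epithelium + cfg$cell_intensity_stroma <= 0 &&
      !length(cfg$hotspot_spec))
    stop("zero total cell intensity and no hotspots: empty cores")
  for (region in c("epithelium", "stroma")) {
    mix <- cfg$phenotype_mixture[[region]]
    if (is.null(mix)) stop("phenotype_mixture lacks region ", region)
    if (abs(sum(mix) - 1) > 1e-9)
      stop("phenotype mixture for ", region, " does not sum to 1")
    if (any(mix < 0)) stop("negative mixture probability in ", region)
  }
  for (h in cfg$hotspot_spec) {
    if (abs(sum(h$composition) - 1) > 1e-9)
      stop("hotspot composition does not sum to 1")
    if (h$radius <= 0 || h$cell_count < 0 || h$n_per_core < 0)
      stop("invalid hotspot geometry")
    if (!h$anchor %in% c("nest-boundary", "stroma", "epithelium"))
      stop("unknown hotspot anchor: ", h$anchor)
  }
  sv <- cfg$survival_spec
  if (sv$baseline_hazard_os <= 0 || sv$baseline_hazard_pfs <= 0)
    stop("baseline hazard must be > 0")
  if (length(sv$censoring_window) != 2L ||
      sv$censoring_window[1] > sv$censoring_window[2] ||
      any(sv$censoring_window < 0))
    stop("censoring_window must be a nondecreasing nonnegative pair")
  invisible(TRUE)
}

# Deterministic 31-bit substream seed from the master seed and a label.
# Polynomial string hash; all arithmetic stays exact in doubles.
.stableHash <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  h
}

.coreSeed <- function(seed, patient_id, core_index) {
  h <- .stableHash(paste(patient_id, core_index, sep = ":"))
  as.integer((seed %% 2147483647 + (h * 1103515) %% 2147483647) %% 2147483647)
}

# uniform point in a disc (centre cx,cy radius r); vectorized
.runifDisc <- function(n, cx = 0, cy = 0, r = 1) {
  rr <- r * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(x = cx + rr * cos(th), y = cy + rr * sin(th))
}

# minimal binary marker representative of a phenotype label
.phenotypeToCalls <- function(labels, markers) {
  base2marker <- c(PanCK = "panCK", CD68 = "CD68", CD3 = "CD3",
                   CD94 = "CD94", CD16a = "CD16a", CD8 = "CD8",
                   CD163 = "CD163", Other = NA_character_)
  P <- matrix(0L, length(labels), length(markers),
              dimnames = list(NULL, markers))
  uniq <- unique(labels)
  for (lab in uniq) {
    toks <- strsplit(lab, "_", fixed = TRUE)[[1L]]
    mks <- character()
    if (!toks[1L] %in% names(base2marker))
      stop("cannot derive marker calls for phenotype label: ", lab)
    if (!is.na(base2marker[[toks[1L]]])) mks <- base2marker[[toks[1L]]]
    extra <- toks[-1L]
    bad <- setdiff(extra, markers)
    if (length(bad))
      stop("cannot derive marker calls for phenotype label: ", lab)
    mks <- c(mks, extra)
    P[labels == lab, intersect(mks, markers)] <- 1L
  }
  P
}

#' Simulate one TMA core
#'
#' Places epithelial nests in the core disc (non-overlapping; rejection
#' sampled), draws Poisson cell counts per compartment, samples cell
#' positions uniformly within their region, assigns phenotypes from the
#' compartment mixtures, then appends hotspot cells at their anchors. The
#' compartment of every cell, hotspot cells included, is determined purely
#' by its position (inside a nest = epithelium). Compartment areas are
#' analytic: nests sum for epithelium, disc minus nests for stroma.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param patient_id patient identifier.
#' @param core_index core index within patient (1-based).
#' @return list with \code{cells} (canonical columns plus emitted marker
#'   columns), \code{area} (one-row data.frame) and \code{truth} (per-cell
#'   true phenotype and planted hotspot id, NA if background).
#' @export
simulateCore <- function(config, patient_id, core_index) {
  .validateSimulationConfig(config)
  set.seed(.coreSeed(config$seed, patient_id, core_index))
  R <- config$core_radius
  core_id <- sprintf("%s_core%d", patient_id, core_index)

  # --- nest geometry (non-overlapping discs fully inside the core) ---
  nests <- matrix(numeric(0), 0L, 3L, dimnames = list(NULL, c("x", "y", "r")))
  for (i in seq_len(config$n_nests)) {
    placed <- FALSE
    for (try in seq_len(200L)) {
      r <- runif(1, config$nest_radius_range[1], config$nest_radius_range[2])
      ctr <- .runifDisc(1, 0, 0, R - r)
      if (nrow(nests) == 0 ||
          all(sqrt((nests[, "x"] - ctr[1, "x"])^2 +
                   (nests[, "y"] - ctr[1, "y"])^2) >= nests[, "r"] + r)) {
        nests <- rbind(nests, c(ctr[1, "x"], ctr[1, "y"], r))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place ", config$n_nests, " non-overlapping nests in core")
  }
  areaEpi <- if (nrow(nests)) sum(pi * nests[, "r"]^2) else 0
  areaStr <- pi * R^2 - areaEpi

  .inNest <- function(x, y) {
    if (nrow(nests) == 0L) return(rep(FALSE, length(x)))
    inside <- rep(FALSE, length(x))
    for (i in seq_len(nrow(nests)))
      inside <- inside | ((x - nests[i, "x"])^2 + (y - nests[i, "y"])^2 <=
                            nests[i, "r"]^2)
    inside
  }

  xs <- numeric(0); ys <- numeric(0); phen <- character(0); hot <- integer(0)

  # --- background epithelial cells (uniform within nests) ---
  nE <- if (areaEpi > 0) rpois(1, config$cell_intensity_epithelium * areaEpi) else 0L
  if (nE > 0) {
    nestPick <- sample.int(nrow(nests), nE, replace = TRUE,
                           prob = nests[, "r"]^2)
    pts <- .runifDisc(nE, 0, 0, 1)  # unit disc, rescaled per nest
    xs <- c(xs, nests[nestPick, "x"] + pts[, "x"] * nests[nestPick, "r"])
    ys <- c(ys, nests[nestPick, "y"] + pts[, "y"] * nests[nestPick, "r"])
    mix <- config$phenotype_mixture$epithelium
    phen <- c(phen, sample(names(mix), nE, replace = TRUE, prob = mix))
    hot <- c(hot, rep(NA_integer_, nE))
  }

  # --- background stromal cells (uniform in disc minus nests; rejection) ---
  nS <- if (areaStr > 0) rpois(1, config$cell_intensity_stroma * areaStr) else 0L
  if (nS > 0) {
    got <- 0L; sx <- numeric(nS); sy <- numeric(nS)
    while (got < nS) {
      m <- max(2L * (nS - got), 16L)
      pts <- .runifDisc(m, 0, 0, R)
      keep <- !.inNest(pts[, "x"], pts[, "y"])
      keep <- which(keep)[seq_len(min(sum(keep), nS - got))]
      if (length(keep)) {
        sx[got + seq_along(keep)] <- pts[keep, "x"]
        sy[got + seq_along(keep)] <- pts[keep, "y"]
        got <- got + length(keep)
      }
    }
    xs <- c(xs, sx); ys <- c(ys, sy)
    mix <- config$phenotype_mixture$stroma
    phen <- c(phen, sample(names(mix), nS, replace = TRUE, prob = mix))
    hot <- c(hot, rep(NA_integer_, nS))
  }

  # --- hotspot cells appended at their anchors ---
  for (hIdx in seq_along(config$hotspot_spec)) {
    h <- config$hotspot_spec[[hIdx]]
    nInst <- rpois(1, h$n_per_core)
    for (inst in seq_len(nInst)) {
      anchor <- switch(h$anchor,
        "nest-boundary" = {
          if (nrow(nests) == 0L) {
            # no nests to anchor at: fall back to a stromal anchor
            pt <- .runifDisc(1, 0, 0, R); c(pt[1, "x"], pt[1, "y"])
          } else {
            i <- sample.int(nrow(nests), 1L)
            th <- runif(1, 0, 2 * pi)
            c(nests[i, "x"] + nests[i, "r"] * cos(th),
              nests[i, "y"] + nests[i, "r"] * sin(th))
          }
        },
        "stroma" = {
          repeat {
            pt <- .runifDisc(1, 0, 0, R)
            if (!.inNest(pt[1, "x"], pt[1, "y"])) break
          }
          c(pt[1, "x"], pt[1, "y"])
        },
        "epithelium" = {
          if (nrow(nests) == 0L) stop("epithelium hotspot anchor with no nests")
          i <- sample.int(nrow(nests), 1L, prob = nests[, "r"]^2)
          pt <- .runifDisc(1, nests[i, "x"], nests[i, "y"], nests[i, "r"])
          c(pt[1, "x"], pt[1, "y"])
        })
      nc <- h$cell_count
      if (nc < 1) next
      # sample within the hotspot disc, clipped to the core by rejection
      got <- 0L; hx <- numeric(nc); hy <- numeric(nc)
      while (got < nc) {
        pts <- .runifDisc(max(2L * (nc - got), 8L), anchor[1], anchor[2],
                          h$radius)
        keep <- which(pts[, "x"]^2 + pts[, "y"]^2 <= R^2)
        keep <- keep[seq_len(min(length(keep), nc - got))]
        if (length(keep)) {
          hx[got + seq_along(keep)] <- pts[keep, "x"]
          hy[got + seq_along(keep)] <- pts[keep, "y"]
          got <- got + length(keep)
        }
      }
      xs <- c(xs, hx); ys <- c(ys, hy)
      phen <- c(phen, sample(names(h$composition), nc, replace = TRUE,
                             prob = h$composition))
      hot <- c(hot, rep(hIdx, nc))
    }
  }

  n <- length(xs)
  comp <- if (n) ifelse(.inNest(xs, ys), "epithelium", "stroma")
          else character(0)
  cells <- data.frame(
    cell_id = sprintf("%s_%06d", core_id, seq_len(n)),
    core_id = if (n) core_id else character(0),
    patient_id = if (n) patient_id else character(0),
    x_um = xs * 1000, y_um = ys * 1000,
    compartment = comp, stringsAsFactors = FALSE)
  if ("phenotype" %in% config$emit) cells$phenotype <- phen
  if (any(c("pos", "intensity") %in% config$emit)) {
    mk <- markerPanel("panel1")
    P <- .phenotypeToCalls(phen, mk)
    if ("pos" %in% config$emit)
      for (m in mk) cells[[paste0("pos_", m)]] <- P[, m]
    if ("intensity" %in% config$emit) {
      mn <- config$marker_noise
      for (m in mk) {
        mu <- ifelse(P[, m] == 1L, mn$pos_meanlog, mn$neg_meanlog)
        cells[[paste0("marker_", m)]] <- rlnorm(n, mu, mn$sdlog)
      }
    }
  }
  list(
    cells = cells,
    area = data.frame(core_id = core_id, patient_id = patient_id,
                      area_epithelium_mm2 = areaEpi,
                      area_stroma_mm2 = areaStr, stringsAsFactors = FALSE),
    truth = data.frame(cell_id = cells$cell_id,
                       core_id = if (n) core_id else character(0),
                       true_phenotype = phen, hotspot = hot,
                       stringsAsFactors = FALSE))
}

#' Simulate survival endpoints under a proportional-hazards model
#'
#' Event times are exponential with hazard \eqn{h_0 \exp(X\beta)}; the
#' linear predictor combines clinical covariates (age centered at
#' \code{age_center}) and planted-coverage terms. Censoring is uniform on
#' the configured window; times beyond any analysis horizon are recorded
#' as-is (truncation belongs to the analysis stage).
#'
#' @param patients clinical data.frame; must carry the covariates named in
#'   \code{survival_spec$betas} and, for coverage terms, the
#'   \code{gt_coverage_h<i>} columns.
#' @param survival_spec see \code{\link{simulationConfig}}.
#' @param seed integer seed.
#' @return \code{patients} with \code{os_months}, \code{os_event},
#'   \code{pfs_months}, \code{pfs_event} and \code{gt_lp} (true linear
#'   predictor) appended. A zero-width censoring window yields an
#'   all-censored, zero-time table flagged with
#'   \code{attr(, "degenerate")}.
#' @export
simulateSurvival <- function(patients, survival_spec, seed = 1L) {
  sv <- survival_spec
  if (sv$baseline_hazard_os <= 0 || sv$baseline_hazard_pfs <= 0)
    stop("baseline hazard must be > 0")
  n <- nrow(patients)
  lp <- rep(0, n)
  for (nm in names(sv$betas)) {
    if (!nm %in% names(patients))
      stop("survival covariate absent from patient table: ", nm)
    v <- patients[[nm]]
    if (nm == "age") v <- v - (sv$age_center %||% 60)
    if (nm == "grade") v <- as.numeric(v == 3)
    lp <- lp + sv$betas[[nm]] * as.numeric(v)
  }
  for (term in sv$coverage_terms %||% list()) {
    cn <- paste0("gt_coverage_h", term$hotspot)
    if (!cn %in% names(patients))
      stop("coverage term refers to absent column: ", cn)
    v <- patients[[cn]]
    x <- switch(term$coding,
                above_mean = as.numeric(v > mean(v)),
                linear = v,
                stop("unknown coverage coding: ", term$coding))
    lp <- lp + term$beta * x
  }
  set.seed(seed)
  out <- patients
  out$gt_lp <- lp
  cw <- sv$censoring_window
  degenerate <- diff(cw) == 0 && cw[1] == 0
  for (ep in c("os", "pfs")) {
    h0 <- if (ep == "os") sv$baseline_hazard_os else sv$baseline_hazard_pfs
    t_event <- rexp(n, rate = h0 * exp(lp))
    t_cens <- if (degenerate) rep(0, n) else runif(n, cw[1], cw[2])
    out[[paste0(ep, "_months")]] <- pmin(t_event, t_cens)
    out[[paste0(ep, "_event")]] <- as.integer(t_event <= t_cens & !degenerate)
  }
  if (degenerate) {
    warning("zero-width censoring window: all observations censored at 0")
    attr(out, "degenerate") <- TRUE
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full TMA cohort
#'
#' \code{n_patients} patients, each with \code{cores_per_patient} cores
#' from \code{\link{simulateCore}}; clinical covariates drawn from
#' \code{covariate_spec}; survival from \code{\link{simulateSurvival}}.
#' Deterministic given \code{config$seed}: per-core substreams are derived
#' by stable hashing of (patient_id, core_index), so the output is
#' invariant to core evaluation order.
#'
#' Ground truth: the returned cohort's \code{groundTruth} slot holds the
#' per-cell true phenotype and planted hotspot id; the clinical table
#' carries \code{gt_coverage_h<i>} (patient mean over cores of the
#' per-core planted-cell fraction) and \code{gt_lp}.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return a \code{\linkS4class{TmaCohort}}.
#' @export
simulateCohort <- function(config) {
  .validateSimulationConfig(config)
  np <- config$n_patients
  pid <- sprintf("P%04d", seq_len(np))
  if (np == 0L)
    return(new("TmaCohort", cells = data.frame(), clinical = data.frame(),
               areas = data.frame(), groundTruth = data.frame()))

  cellsL <- list(); areasL <- list(); truthL <- list()
  for (p in pid) for (ci in seq_len(config$cores_per_patient)) {
    sim <- simulateCore(config, p, ci)
    key <- paste(p, ci)
    cellsL[[key]] <- sim$cells
    areasL[[key]] <- sim$area
    truthL[[key]] <- sim$truth
  }
  cells <- do.call(rbind, cellsL)
  areas <- do.call(rbind, areasL)
  truth <- do.call(rbind, truthL)
  rownames(cells) <- rownames(areas) <- rownames(truth) <- NULL

  cs <- config$covariate_spec
  set.seed(.coreSeed(config$seed, "__clinical__", 0L))
  clin <- data.frame(
    patient_id = pid,
    age = round(rnorm(np, cs$age_mean, cs$age_sd), 1),
    stage = rbinom(np, 1, cs$stage_high_p),
    grade = 2L + rbinom(np, 1, cs$grade3_p),
    debulking = rbinom(np, 1, cs$debulking_p),
    chemo_sensitivity = rbinom(np, 1, cs$chemo_sensitivity_p),
    stringsAsFactors = FALSE)

  # planted coverage: per-core fraction of hotspot cells, patient mean
  coreTot <- tapply(rep(1L, nrow(truth)), truth$core_id, sum)
  corePat <- areas$patient_id[match(names(coreTot), areas$core_id)]
  for (hIdx in seq_along(config$hotspot_spec)) {
    isH <- !is.na(truth$hotspot) & truth$hotspot == hIdx
    coreH <- tapply(as.numeric(isH), truth$core_id, sum)
    frac <- as.numeric(coreH / coreTot)
    patMean <- tapply(frac, corePat, mean)
    clin[[paste0("gt_coverage_h", hIdx)]] <-
      as.numeric(patMean[match(clin$patient_id, names(patMean))])
  }
  clin <- simulateSurvival(clin, config$survival_spec,
                           seed = .coreSeed(config$seed, "__survival__", 0L))
  new("TmaCohort", cells = cells, clinical = clin, areas = areas,
      groundTruth = truth)
}
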