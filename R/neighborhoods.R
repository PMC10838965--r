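# Cellular neighborhoods: per-cell k-nearest-neighbor phenotype profiles,
# unsupervised clustering of the profiles, k/n selection diagnostics, and
# the coverage / co-localization / ratio metrics derived from a fitted
# model.

.categoryOf <- function(compartment, phenotype,
                        mode = c("phenotype_compartment", "phenotype")) {
  mode <- match.arg(mode)
  if (mode == "phenotype") return(phenotype)
  paste0(ifelse(compartment == "epithelium", "E_", "S_"), phenotype)
}

#' Per-cell k-nearest-neighbor phenotype profiles
#'
#' For every cell, counts the phenotype-by-compartment categories of its k
#' Euclidean nearest neighbors within the same core (self excluded, never
#' across cores). Ties at equal distance are broken by ascending
#' \code{cell_id} for determinism. Cores with fewer than k+1 cells are
#' excluded entirely, with a warning.
#'
#' @param cellTable cells with \code{cell_id}, \code{core_id},
#'   \code{patient_id}, \code{x_um}, \code{y_um}, \code{compartment},
#'   \code{phenotype}.
#' @param k neighbors per cell (default 15).
#' @param mode \code{"phenotype_compartment"} (default; categories like
#'   \code{S_CD16a}) or \code{"phenotype"}.
#' @param categories optional fixed category column set; defaults to all
#'   categories observed in \code{cellTable}.
#' @return data.frame: \code{cell_id}, \code{core_id}, \code{patient_id},
#'   one integer count column per category (each row sums to k).
#'   Attributes: \code{k}, \code{categories}, \code{mode},
#'   \code{excluded_cores}.
#' @export
neighborProfiles <- function(cellTable, k = 15L,
                             mode = c("phenotype_compartment", "phenotype"),
                             categories = NULL) {
  mode <- match.arg(mode)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  need <- c("cell_id", "core_id", "patient_id", "x_um", "y_um",
            "compartment", "phenotype")
  miss <- setdiff(need, names(cellTable))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(cellTable$x_um)) || any(!is.finite(cellTable$y_um)))
    stop("non-finite coordinates")
  cat_all <- .categoryOf(cellTable$compartment, cellTable$phenotype, mode)
  if (is.null(categories)) categories <- sort(unique(cat_all))
  unk <- setdiff(unique(cat_all), categories)
  if (length(unk))
    stop("categories in data but not in supplied set: ",
         paste(unk, collapse = ", "))

  allCode <- match(cat_all, categories)
  idxByCore <- split(seq_len(nrow(cellTable)), cellTable$core_id)
  excluded <- character(0)
  keepIdx <- vector("list", length(idxByCore))
  cnts <- vector("list", length(idxByCore))
  for (ci in seq_along(idxByCore)) {
    idx <- idxByCore[[ci]]
    ids <- cellTable$cell_id[idx]
    if (anyDuplicated(ids))
      stop("duplicate cell_id within core ", names(idxByCore)[ci])
    if (length(idx) < k + 1L) {
      excluded <- c(excluded, names(idxByCore)[ci])
      next
    }
    idx <- idx[order(ids)]
    nbr <- .knn_indices_cpp(cellTable$x_um[idx], cellTable$y_um[idx], k)
    code <- allCode[idx]
    n <- length(idx)
    cnt <- matrix(tabulate(as.vector((matrix(code[nbr], n, k) - 1L) * n +
                                       rep(seq_len(n), times = k)),
                           nbins = n * length(categories)),
                  n, length(categories))
    keepIdx[[ci]] <- idx
    cnts[[ci]] <- cnt
  }
  if (length(excluded))
    warning(length(excluded), " core(s) with < k+1 = ", k + 1L,
            " cells excluded from spatial analysis: ",
            paste(utils::head(excluded, 5L), collapse = ", "),
            if (length(excluded) > 5L) ", ..." else "")
  keep <- unlist(keepIdx)
  if (is.null(keep) || !length(keep))
    stop("no core has enough cells for k = ", k)
  out <- data.frame(cell_id = cellTable$cell_id[keep],
                    core_id = cellTable$core_id[keep],
                    patient_id = cellTable$patient_id[keep],
                    stringsAsFactors = FALSE)
  cnt <- do.call(rbind, cnts[!vapply(cnts, is.null, logical(1))])
  for (j in seq_along(categories)) out[[categories[j]]] <- cnt[, j]
  attr(out, "k") <- k
  attr(out, "categories") <- categories
  attr(out, "mode") <- mode
  attr(out, "excluded_cores") <- excluded
  out
}

.profileMatrix <- function(profiles) {
  cats <- attr(profiles, "categories")
  as.matrix(profiles[cats])
}

#' Phenotype co-localization matrix
#'
#' For each focal phenotype, sums neighbor counts over all its profiled
#' cells across all cores and normalizes each row to percent. Neighbor
#' categories are collapsed to phenotype level (epithelial and stromal
#' variants summed) so the matrix is phenotype-by-phenotype.
#'
#' @param profiles output of \code{\link{neighborProfiles}}.
#' @param cellTable the cell table the profiles came from (source of each
#'   focal cell's phenotype).
#' @return square matrix, rows focal phenotype, columns neighbor
#'   phenotype, rows summing to 100; rows for phenotypes with no profiled
#'   cells are NA.
#' @export
colocalizationMatrix <- function(profiles, cellTable) {
  X <- .profileMatrix(profiles)
  if (nrow(X) == 0L) stop("no profiled cells")
  # collapse E_/S_ compartment prefixes to phenotype level
  cats <- colnames(X)
  phenOfCat <- sub("^[ES]_", "", cats)
  phenCols <- sort(unique(phenOfCat))
  Xp <- matrix(0, nrow(X), length(phenCols),
               dimnames = list(NULL, phenCols))
  for (j in seq_along(cats))
    Xp[, phenOfCat[j]] <- Xp[, phenOfCat[j]] + X[, j]
  focal <- cellTable$phenotype[match(paste(profiles$core_id, profiles$cell_id),
                                     paste(cellTable$core_id, cellTable$cell_id))]
  allPhen <- sort(unique(c(focal, phenCols, unique(cellTable$phenotype))))
  M <- matrix(NA_real_, length(allPhen), length(phenCols),
              dimnames = list(allPhen, phenCols))
  for (p in allPhen) {
    rows <- which(focal == p)
    if (!length(rows)) next
    s <- colSums(Xp[rows, , drop = FALSE])
    M[p, ] <- 100 * s / sum(s)
  }
  M
}

#' Cluster neighbor profiles into cellular neighborhoods
#'
#' k-means on the raw (unscaled) count vectors, pooled across all cores of
#' the cohort: one model per cohort so neighborhood definitions are
#' comparable across patients. k-means++ seeding, 10 restarts, best
#' inertia kept; deterministic given the seed. Final neighborhood ids are
#' 0-based and ordered by decreasing size.
#'
#' @param profiles output of \code{\link{neighborProfiles}}.
#' @param n number of neighborhoods (typical sweep 5-10). \code{n < 2} is
#'   permitted but flagged as degenerate with a warning.
#' @param seed integer seed.
#' @param nstart restarts (default 10).
#' @return a \code{\linkS4class{NeighborhoodModel}}.
#' @export
clusterNeighborhoods <- function(profiles, n, seed = 1L, nstart = 10L) {
  n <- as.integer(n)
  X <- .profileMatrix(profiles)
  if (n > nrow(X))
    stop("more neighborhoods (", n, ") than profiled cells (", nrow(X), ")")
  if (n < 2L) warning("n < 2 neighborhoods is degenerate")
  fit <- .kmeansFit(X, n, nstart = nstart, seed = seed)
  sizes <- tabulate(fit$cluster, n)
  ord <- order(-sizes)
  relabel <- integer(n); relabel[ord] <- seq_len(n)
  cl0 <- relabel[fit$cluster] - 1L  # 0-based, largest first
  ctr <- matrix(0, n, ncol(X), dimnames = list(as.character(0:(n - 1L)),
                                               colnames(X)))
  for (i in 0:(n - 1L))
    ctr[i + 1L, ] <- colMeans(X[cl0 == i, , drop = FALSE])
  labels <- data.frame(cell_id = profiles$cell_id,
                       core_id = profiles$core_id,
                       patient_id = profiles$patient_id,
                       neighborhood = cl0, stringsAsFactors = FALSE)
  new("NeighborhoodModel", k = attr(profiles, "k"), n = n, centroids = ctr,
      labels = labels, categories = colnames(X),
      inertia = fit$tot.withinss, seed = as.integer(seed),
      nbhdNames = paste0("N", 0:(n - 1L)))
}

#' Neighborhood composition (enrichment) matrix
#'
#' Mean neighbor count per category within each neighborhood (the model
#' centroids), z-scored per category across neighborhoods — the matrix
#' behind a composition heatmap. With a single neighborhood z-scores are
#' undefined; raw means are returned flagged degenerate.
#'
#' @param model a \code{\linkS4class{NeighborhoodModel}}.
#' @return matrix (neighborhood x category) of z-scores, with the raw mean
#'   counts in \code{attr(, "raw")}; \code{attr(, "degenerate")} is TRUE
#'   when n = 1.
#' @export
neighborhoodComposition <- function(model) {
  stopifnot(is(model, "NeighborhoodModel"))
  raw <- model@centroids
  if (model@n == 1L) {
    out <- raw
    attr(out, "raw") <- raw
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  mu <- colMeans(raw)
  sdv <- apply(raw, 2L, sd)
  Z <- sweep(raw, 2L, mu)
  nz <- sdv > 0
  Z[, nz] <- sweep(Z[, nz, drop = FALSE], 2L, sdv[nz], "/")
  Z[, !nz] <- 0
  attr(Z, "raw") <- raw
  attr(Z, "degenerate") <- FALSE
  Z
}

#' Pairwise cosine similarity of neighborhood centroids
#'
#' Flags pairs at or above the similarity threshold as "highly similar" —
#' the over-fitting diagnostic used when choosing k and n.
#'
#' @param model a \code{\linkS4class{NeighborhoodModel}}.
#' @param threshold flag threshold (default 0.95).
#' @return list: \code{similarity} (n x n matrix, NA against zero
#'   centroids), \code{flagged} (data.frame i, j, similarity for flagged
#'   pairs, 0-based ids), \code{threshold}.
#' @export
neighborhoodSimilarity <- function(model, threshold = 0.95) {
  stopifnot(is(model, "NeighborhoodModel"))
  C <- model@centroids
  nrm <- sqrt(rowSums(C^2))
  S <- (C %*% t(C)) / outer(nrm, nrm)
  S[nrm == 0, ] <- NA_real_
  S[, nrm == 0] <- NA_real_
  diag(S) <- ifelse(nrm == 0, NA_real_, 1)
  flagged <- data.frame(i = integer(), j = integer(), similarity = numeric())
  if (model@n >= 2L) {
    for (a in seq_len(model@n - 1L)) for (b in (a + 1L):model@n) {
      if (!is.na(S[a, b]) && S[a, b] >= threshold)
        flagged <- rbind(flagged,
                         data.frame(i = a - 1L, j = b - 1L,
                                    similarity = S[a, b]))
    }
  }
  list(similarity = S, flagged = flagged, threshold = threshold)
}

#' Sweep k and n and recommend a combination
#'
#' Fits a neighborhood model for every (k, n) on the grids (plus the
#' adjacent n-1 and n+1 fits needed for the diagnostics), flags highly
#' similar centroid pairs in each, and recommends the (k, n) at the
#' boundary between under- and over-fitting: the largest n (smallest k at
#' that n) whose model has no flagged pair, whose (k, n+1) model
#' introduces a flagged (redundant) split, and whose (k, n-1) model
#' merges two previously distinct neighborhoods (two centroids of the
#' n-model matching, by maximal cosine similarity, the same centroid of
#' the (n-1)-model). The recommendation is advisory; the chosen (k, n)
#' remains a configuration value.
#'
#' @param cellTable phenotyped cell table.
#' @param kGrid,nGrid grids (defaults k in 5,10,15,20; n in 5..10).
#' @param seed integer seed.
#' @param threshold similarity flag threshold.
#' @param mode profile category mode.
#' @return list: \code{diagnostics} (data.frame k, n, inertia,
#'   n_flagged, flagged_at_n_plus_1, merged_at_n_minus_1),
#'   \code{recommended} (named vector or NULL), \code{models} (list keyed
#'   "k<k>_n<n>").
#' @export
selectKN <- function(cellTable, kGrid = c(5L, 10L, 15L, 20L), nGrid = 5:10,
                     seed = 1L, threshold = 0.95,
                     mode = c("phenotype_compartment", "phenotype")) {
  mode <- match.arg(mode)
  if (!length(kGrid) || !length(nGrid)) stop("empty k or n grid")
  kGrid <- sort(unique(as.integer(kGrid)))
  nGrid <- sort(unique(as.integer(nGrid)))
  nAll <- sort(unique(c(nGrid, pmax(nGrid - 1L, 2L), nGrid + 1L)))
  models <- list()
  diag <- NULL
  for (k in kGrid) {
    prof <- neighborProfiles(cellTable, k = k, mode = mode)
    for (n in nAll) {
      m <- clusterNeighborhoods(prof, n = n, seed = seed)
      models[[sprintf("k%d_n%d", k, n)]] <- m
    }
  }
  .merged <- function(k, n) {
    if (n - 1L < 2L) return(NA)
    big <- models[[sprintf("k%d_n%d", k, n)]]
    small <- models[[sprintf("k%d_n%d", k, n - 1L)]]
    if (is.null(small)) return(NA)
    Cb <- big@centroids; Cs <- small@centroids
    # ignore degenerate (empty-cluster) centroids
    Cb <- Cb[apply(Cb, 1, function(v) all(is.finite(v)) && any(v != 0)), ,
             drop = FALSE]
    ok <- apply(Cs, 1, function(v) all(is.finite(v)) && any(v != 0))
    if (nrow(Cb) < 2L || sum(ok) < 1L) return(NA)
    sim <- function(a, b) sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
    best <- vapply(seq_len(nrow(Cb)), function(i) {
      s <- vapply(which(ok), function(j) sim(Cb[i, ], Cs[j, ]), numeric(1))
      which(ok)[which.max(s)]
    }, integer(1))
    anyDuplicated(best) > 0L
  }
  nFlags <- function(k, n) {
    m <- models[[sprintf("k%d_n%d", k, n)]]
    if (is.null(m)) return(NA_integer_)
    nrow(neighborhoodSimilarity(m, threshold)$flagged)
  }
  for (k in kGrid) for (n in nGrid) {
    m <- models[[sprintf("k%d_n%d", k, n)]]
    diag <- rbind(diag, data.frame(
      k = k, n = n, inertia = m@inertia, n_flagged = nFlags(k, n),
      flagged_at_n_plus_1 = nFlags(k, n + 1L) > 0L,
      merged_at_n_minus_1 = .merged(k, n)))
  }
  rec <- NULL
  ordered <- diag[order(-diag$n, diag$k), ]
  for (i in seq_len(nrow(ordered))) {
    r <- ordered[i, ]
    if (r$n_flagged == 0L && isTRUE(r$flagged_at_n_plus_1) &&
        isTRUE(r$merged_at_n_minus_1)) {
      rec <- c(k = r$k, n = r$n)
      break
    }
  }
  if (is.null(rec))
    message("selectKN: no (k, n) combination satisfies the heuristic; ",
            "diagnostics only")
  list(diagnostics = diag, recommended = rec, models = models)
}

#' Per-core and per-patient neighborhood coverage
#'
#' Per-core coverage is the fraction of the core's labeled cells in each
#' neighborhood (rows sum to 1); patient coverage averages over that
#' patient's non-excluded cores (the duplicate-core design).
#'
#' @param model a \code{\linkS4class{NeighborhoodModel}}.
#' @param patients optional patient table; patients present there but with
#'   no labeled core are reported missing with a message.
#' @return list of two data.frames, \code{core} (core_id, patient_id, one
#'   column per neighborhood name) and \code{patient}.
#' @export
neighborhoodCoverage <- function(model, patients = NULL) {
  stopifnot(is(model, "NeighborhoodModel"))
  lab <- model@labels
  nms <- model@nbhdNames
  cores <- unique(lab[c("core_id", "patient_id")])
  cnt <- matrix(0, nrow(cores), model@n,
                dimnames = list(cores$core_id, nms))
  tab <- table(lab$core_id, factor(lab$neighborhood, levels = 0:(model@n - 1L)))
  cnt[rownames(tab), ] <- as.matrix(tab)
  frac <- cnt / rowSums(cnt)
  core <- data.frame(core_id = cores$core_id, patient_id = cores$patient_id,
                     stringsAsFactors = FALSE)
  core <- cbind(core, as.data.frame(frac[core$core_id, , drop = FALSE],
                                    row.names = NULL))
  patMean <- aggregate(core[nms], by = list(patient_id = core$patient_id),
                       FUN = mean)
  if (!is.null(patients)) {
    missing <- setdiff(unique(patients$patient_id), patMean$patient_id)
    if (length(missing))
      message(length(missing), " patient(s) with no non-excluded core: ",
              paste(utils::head(missing, 5L), collapse = ", "))
  }
  list(core = core, patient = patMean)
}

#' Per-patient coverage ratio between two neighborhoods
#'
#' @param coverage output of \code{\link{neighborhoodCoverage}}.
#' @param numerator,denominator neighborhood names (columns of the patient
#'   coverage table).
#' @return data.frame patient_id, ratio (NA where the denominator is 0,
#'   reported with a message).
#' @export
coverageRatio <- function(coverage, numerator, denominator) {
  pt <- coverage$patient
  for (nm in c(numerator, denominator))
    if (!nm %in% names(pt)) stop("unknown neighborhood: ", nm)
  num <- pt[[numerator]]
  den <- pt[[denominator]]
  ratio <- ifelse(den > 0, num / den, NA_real_)
  nz <- sum(den == 0)
  if (nz > 0)
    message(nz, " patient(s) with zero denominator coverage: ratio missing")
  data.frame(patient_id = pt$patient_id, ratio = ratio,
             stringsAsFactors = FALSE)
}

#' Rule-based neighborhood naming
#'
#' Names each neighborhood from its composition: immune-poor
#' neighborhoods become "cold epithelium"/"cold stroma" by dominant
#' compartment; neighborhoods whose top-enriched category is a CD16a
#' class become "CD16a enriched <compartment>"; remaining immune
#' neighborhoods are ranked by total immune content into "immune-rich"
#' and "immune-moderate". Without compartment-resolved categories
#' (phenotype-only profiles), immune-poor non-epithelial neighborhoods
#' cannot be resolved and keep their fallback id name ("N<i>"). Manual
#' overrides always win. Names are made unique.
#'
#' @param model a \code{\linkS4class{NeighborhoodModel}}.
#' @param immuneThreshold immune neighbor fraction below which a
#'   neighborhood is "cold" (default 0.1).
#' @param overrides optional named character: names(overrides) are 0-based
#'   neighborhood ids as character, values the names to force.
#' @return the model with \code{nbhdNames} replaced.
#' @export
annotateNeighborhoods <- function(model, immuneThreshold = 0.1,
                                  overrides = NULL) {
  stopifnot(is(model, "NeighborhoodModel"))
  raw <- model@centroids
  cats <- model@categories
  hasComp <- all(grepl("^[ES]_", cats))
  phen <- sub("^[ES]_", "", cats)
  immune <- !(phen %in% c("PanCK", "Other"))
  tot <- rowSums(raw)
  tot[tot == 0] <- NA
  immuneFrac <- rowSums(raw[, immune, drop = FALSE]) / tot
  epiFrac <- if (hasComp)
    rowSums(raw[, grepl("^E_", cats), drop = FALSE]) / tot else NA
  panckFrac <- rowSums(raw[, phen == "PanCK", drop = FALSE]) / tot
  Z <- neighborhoodComposition(model)
  nms <- rep(NA_character_, model@n)
  for (i in seq_len(model@n)) {
    if (is.na(tot[i])) next
    if (immuneFrac[i] < immuneThreshold) {
      if (hasComp) {
        nms[i] <- if (epiFrac[i] >= 0.5) "cold epithelium" else "cold stroma"
      } else if (panckFrac[i] >= 0.5) nms[i] <- "cold epithelium"
      next
    }
    top <- cats[which.max(Z[i, ])]
    if (grepl("CD16a", top)) {
      nms[i] <- if (!hasComp) "CD16a enriched"
        else paste("CD16a enriched",
                   if (grepl("^E_", top)) "epithelium" else "stroma")
      next
    }
  }
  rest <- which(is.na(nms) & !is.na(tot) & immuneFrac >= immuneThreshold)
  if (length(rest)) {
    richest <- rest[which.max(immuneFrac[rest])]
    nms[richest] <- "immune-rich"
    nms[setdiff(rest, richest)] <- "immune-moderate"
  }
  fallback <- paste0("N", 0:(model@n - 1L))
  nms[is.na(nms)] <- fallback[is.na(nms)]
  if (!is.null(overrides))
    for (id in names(overrides)) nms[as.integer(id) + 1L] <- overrides[[id]]
  neighborhoodNames(model) <- make.unique(nms, sep = " ")
  model
}
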