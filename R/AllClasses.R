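#' @import methods
#' @importFrom stats aggregate aov as.formula cor kmeans median na.omit
#'   p.adjust pchisq quantile rbinom rexp rlnorm rnorm rpois runif sd
#'   setNames var
#' @importFrom utils read.csv write.csv
#' @useDynLib spatialTMA, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

REQUIRED_CELL_COLS <- c("cell_id", "core_id", "patient_id",
                        "x_um", "y_um", "compartment")
COMPARTMENTS <- c("epithelium", "stroma")

#' TmaCohort: a multi-patient TMA cohort at single-cell resolution
#'
#' Holds the canonical per-cell table of a tissue-microarray cohort together
#' with the patient-level clinical table, per-core compartment areas, and
#' (for simulated cohorts) a ground-truth sidecar.
#'
#' The cell table always carries \code{cell_id}, \code{core_id},
#' \code{patient_id}, \code{x_um}, \code{y_um} (micrometres, origin per core,
#' y increasing downward) and \code{compartment} (\code{"epithelium"} or
#' \code{"stroma"}); marker information is carried either as intensity
#' columns (\code{marker_<name>}), positivity calls (\code{pos_<name>},
#' 0/1) or a ready-made \code{phenotype} column.
#'
#' @slot cells data.frame, one row per segmented cell.
#' @slot clinical data.frame, one row per patient (age, stage, grade,
#'   debulking, chemo_sensitivity, survival columns when simulated/known).
#' @slot areas data.frame with \code{core_id}, \code{patient_id},
#'   \code{area_epithelium_mm2}, \code{area_stroma_mm2}.
#' @slot groundTruth data.frame keyed by \code{cell_id}/\code{core_id}
#'   (simulated cohorts only; zero rows otherwise).
#'
#' @export
setClass("TmaCohort",
  representation(cells = "data.frame", clinical = "data.frame",
                 areas = "data.frame", groundTruth = "data.frame"),
  prototype(cells = data.frame(), clinical = data.frame(),
            areas = data.frame(), groundTruth = data.frame()))

setValidity("TmaCohort", function(object) {
  cells <- object@cells
  if (nrow(cells) == 0L) return(TRUE)
  missing <- setdiff(REQUIRED_CELL_COLS, names(cells))
  if (length(missing))
    return(paste("cell table missing required column(s):",
                 paste(missing, collapse = ", ")))
  if (!is.numeric(cells$x_um) || !is.numeric(cells$y_um))
    return("x_um / y_um must be numeric")
  if (any(!is.finite(cells$x_um)) || any(!is.finite(cells$y_um)))
    return("non-finite coordinates")
  key <- paste(cells$core_id, cells$cell_id, sep = "\r")
  if (anyDuplicated(key))
    return("duplicate (core_id, cell_id) in cell table")
  bad <- setdiff(unique(cells$compartment), COMPARTMENTS)
  if (length(bad))
    return(paste("unknown compartment value(s):", paste(bad, collapse = ", ")))
  TRUE
})

#' GatingHierarchy: ordered first-match-wins phenotype gating rules
#'
#' Each rule names the markers that must be positive, the markers that must
#' be negative, the phenotype label it emits, marker(s) whose positivity
#' splits the emitted class (recorded as a \code{_<marker>} label suffix,
#' e.g. \code{CD68_CD16a}), and marker(s) recorded only as boolean
#' attribute columns (\code{mod_<marker>}).
#'
#' Validity requires the rules to partition marker space: every binary
#' marker combination must match at least one rule (first-match-wins then
#' guarantees exactly one label).
#'
#' @slot markers ordered marker names of the panel.
#' @slot rules list of rules, each a list with elements \code{label},
#'   \code{positive}, \code{negative}, \code{splits}, \code{attrs}.
#' @export
setClass("GatingHierarchy",
  representation(markers = "character", rules = "list"))

setValidity("GatingHierarchy", function(object) {
  if (anyDuplicated(object@markers)) return("duplicate marker names")
  if (length(object@rules) == 0L) return("no rules")
  for (r in object@rules) {
    need <- c("label", "positive", "negative", "splits", "attrs")
    if (!all(need %in% names(r))) return("malformed rule")
    unk <- setdiff(c(r$positive, r$negative, r$splits, r$attrs), object@markers)
    if (length(unk))
      return(paste("rule refers to unknown marker(s):",
                   paste(unk, collapse = ", ")))
  }
  # partition check: every binary combination matches some rule
  m <- length(object@markers)
  combos <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  colnames(combos) <- object@markers
  for (i in seq_len(nrow(combos))) {
    v <- combos[i, ]
    hit <- FALSE
    for (r in object@rules) {
      if (all(v[r$positive] == 1) && all(v[r$negative] == 0)) { hit <- TRUE; break }
    }
    if (!hit)
      return(paste("marker combination not covered by any rule:",
                   paste(object@markers[v == 1], collapse = "+")))
  }
  TRUE
})

#' ExpressionClusterModel: unsupervised clustering of normalized signals
#'
#' @slot nClusters chosen cluster count.
#' @slot centers matrix (cluster x marker) of mean normalized signals.
#' @slot clusterIds integer cluster id (1-based) per cell.
#' @slot elbow data.frame with \code{k} and \code{withinss} (the elbow
#'   curve over the candidate cluster counts).
#' @slot markers marker names, column order of \code{centers}.
#' @slot seed integer seed used for the k-means restarts.
#' @export
setClass("ExpressionClusterModel",
  representation(nClusters = "integer", centers = "matrix",
                 clusterIds = "integer", elbow = "data.frame",
                 markers = "character", seed = "integer"))

setValidity("ExpressionClusterModel", function(object) {
  if (object@nClusters < 1L) return("nClusters must be >= 1")
  if (nrow(object@centers) != object@nClusters)
    return("centers rows != nClusters")
  if (length(object@clusterIds) &&
      (min(object@clusterIds) < 1L || max(object@clusterIds) > object@nClusters))
    return("cluster ids out of range")
  TRUE
})

#' NeighborhoodModel: fitted cellular-neighborhood clustering
#'
#' A k-means model over per-cell k-nearest-neighbor phenotype-count
#' profiles, pooled across all cores of a cohort. Neighborhood ids are
#' 0-based (\code{0 .. n-1}), matching the conventional N0..Nn-1 naming.
#'
#' @slot k number of nearest neighbors profiled per cell.
#' @slot n number of neighborhoods.
#' @slot centroids matrix (n x category) of mean neighbor counts; rownames
#'   are neighborhood ids as character.
#' @slot labels data.frame: \code{cell_id}, \code{core_id},
#'   \code{patient_id}, \code{neighborhood} (0-based id).
#' @slot categories phenotype-by-compartment category names (column order
#'   of \code{centroids}).
#' @slot inertia total within-cluster sum of squares of the kept fit.
#' @slot seed integer seed.
#' @slot nbhdNames character names per neighborhood (default
#'   \code{"N0"..}); set by \code{\link{annotateNeighborhoods}} or manually.
#' @export
setClass("NeighborhoodModel",
  representation(k = "integer", n = "integer", centroids = "matrix",
                 labels = "data.frame", categories = "character",
                 inertia = "numeric", seed = "integer",
                 nbhdNames = "character"))

setValidity("NeighborhoodModel", function(object) {
  if (object@n < 1L) return("n must be >= 1")
  if (nrow(object@centroids) != object@n) return("centroids rows != n")
  if (ncol(object@centroids) != length(object@categories))
    return("centroid columns != categories")
  if (length(object@nbhdNames) != object@n)
    return("nbhdNames length != n")
  if (nrow(object@labels) &&
      (min(object@labels$neighborhood) < 0L ||
       max(object@labels$neighborhood) >= object@n))
    return("neighborhood labels out of [0, n)")
  TRUE
})

# ---- accessors ----

#' @describeIn TmaCohort per-cell table
#' @param x,object a \code{TmaCohort}
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))
#' @export
setMethod("cells", "TmaCohort", function(x) x@cells)

#' @describeIn TmaCohort patient-level clinical table
#' @export
setGeneric("clinical", function(x) standardGeneric("clinical"))
#' @export
setMethod("clinical", "TmaCohort", function(x) x@clinical)

#' @describeIn TmaCohort per-core compartment areas (mm^2)
#' @export
setGeneric("coreAreas", function(x) standardGeneric("coreAreas"))
#' @export
setMethod("coreAreas", "TmaCohort", function(x) x@areas)

#' @describeIn TmaCohort simulation ground truth (empty for real data)
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @export
setMethod("groundTruth", "TmaCohort", function(x) x@groundTruth)

#' @describeIn NeighborhoodModel centroid matrix (n x category)
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))
#' @export
setMethod("centroids", "NeighborhoodModel", function(x) x@centroids)

#' @describeIn NeighborhoodModel per-cell neighborhood labels
#' @export
setGeneric("neighborhoodLabels", function(x) standardGeneric("neighborhoodLabels"))
#' @export
setMethod("neighborhoodLabels", "NeighborhoodModel", function(x) x@labels)

#' @describeIn NeighborhoodModel human-readable neighborhood names
#' @export
setGeneric("neighborhoodNames", function(x) standardGeneric("neighborhoodNames"))
#' @export
setMethod("neighborhoodNames", "NeighborhoodModel", function(x) x@nbhdNames)

#' Replace neighborhood names
#' @param x a \code{NeighborhoodModel}
#' @param value character of length \code{n}
#' @export
setGeneric("neighborhoodNames<-",
           function(x, value) standardGeneric("neighborhoodNames<-"))
#' @export
setMethod("neighborhoodNames<-", "NeighborhoodModel", function(x, value) {
  stopifnot(length(value) == x@n)
  x@nbhdNames <- as.character(value)
  validObject(x)
  x
})

# ---- show ----

setMethod("show", "TmaCohort", function(object) {
  cat("TmaCohort:", nrow(object@cells), "cells,",
      length(unique(object@cells$core_id)), "cores,",
      nrow(object@clinical), "patients\n")
  if (nrow(object@groundTruth)) cat("  with simulation ground truth\n")
  extra <- setdiff(names(object@cells), REQUIRED_CELL_COLS)
  if (length(extra))
    cat("  cell columns beyond schema:", paste(extra, collapse = ", "), "\n")
})

setMethod("show", "GatingHierarchy", function(object) {
  cat("GatingHierarchy over markers:",
      paste(object@markers, collapse = ", "), "\n")
  for (i in seq_along(object@rules)) {
    r <- object@rules[[i]]
    cat(sprintf("  %d. %s%s%s -> %s%s\n", i,
        if (length(r$positive)) paste0(r$positive, "+", collapse = "") else "",
        if (length(r$negative)) paste0(r$negative, "-", collapse = "") else "",
        if (!length(c(r$positive, r$negative))) "(any)" else "",
        r$label,
        if (length(r$splits)) paste0(" (+/-", paste(r$splits, collapse = " +/-"), ")")
        else ""))
  }
})

setMethod("show", "ExpressionClusterModel", function(object) {
  cat("ExpressionClusterModel:", object@nClusters, "clusters over",
      length(object@markers), "markers,",
      length(object@clusterIds), "cells\n")
})

setMethod("show", "NeighborhoodModel", function(object) {
  cat(sprintf("NeighborhoodModel: k=%d, n=%d, %d labeled cells\n",
              object@k, object@n, nrow(object@labels)))
  cat("  neighborhoods:", paste(object@nbhdNames, collapse = ", "), "\n")
})
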