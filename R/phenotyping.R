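# Phenotyping: marker signals -> phenotype labels, either directly from
# positivity calls via hierarchical gating, or via log normalization ->
# unsupervised expression clustering -> per-cluster gating.

#' Marker panels
#'
#' The immunofluorescence panels supported out of the box. Panel 1 carries
#' panCK (epithelial lineage), CD68 (macrophage), CD3 (T cell), CD94
#' (NK cell) and CD16a (Fc-gamma receptor IIIa); panel 2 adds CD8 and
#' CD163.
#'
#' @param panel `"panel1"` or `"panel2"`.
#' @return character vector of ordered marker names.
#' @export
markerPanel <- function(panel = c("panel1", "panel2")) {
  panel <- match.arg(panel)
  base <- c("panCK", "CD68", "CD3", "CD94", "CD16a")
  if (panel == "panel1") base else c(base, "CD8", "CD163")
}

.mkRule <- function(label, positive = character(), negative = character(),
                    splits = character(), attrs = character()) {
  list(label = label, positive = positive, negative = negative,
       splits = splits, attrs = attrs)
}

#' Construct a gating hierarchy
#'
#' @param markers ordered marker names of the panel.
#' @param rules list of rules as produced by internal rule constructors or
#'   supplied directly: each a list with \code{label}, \code{positive},
#'   \code{negative}, \code{splits} (markers whose positivity is appended
#'   to the label as \code{_<marker>}), \code{attrs} (markers recorded as
#'   \code{mod_<marker>} attribute columns only).
#' @return a validated \code{\linkS4class{GatingHierarchy}}.
#' @export
gatingHierarchy <- function(markers, rules) {
  rules <- lapply(rules, function(r) {
    for (f in c("positive", "negative", "splits", "attrs"))
      if (is.null(r[[f]])) r[[f]] <- character()
    r
  })
  new("GatingHierarchy", markers = markers, rules = rules)
}

#' Default gating hierarchies
#'
#' Lineage markers are gated in strict priority order: panCK dominates
#' (an epithelial call regardless of any other marker), then CD68
#' (myeloid), CD3 (T cell), CD94 (NK cell), CD16a alone, and all-negative
#' cells are "Other". CD16a positivity splits the myeloid, T and NK
#' classes into \code{_CD16a} variants; CD94 on T cells is kept as a
#' boolean attribute only. Panel 2 adds CD163 as a myeloid split and CD8
#' as a T-cell split, with CD163-only and CD8-only fallback classes; the
#' panel-2 rule order below CD68 is a configurable default.
#'
#' @param panel `"panel1"` or `"panel2"`.
#' @return a \code{\linkS4class{GatingHierarchy}}.
#' @export
defaultHierarchy <- function(panel = c("panel1", "panel2")) {
  panel <- match.arg(panel)
  m <- markerPanel(panel)
  if (panel == "panel1") {
    rules <- list(
      .mkRule("PanCK", positive = "panCK"),
      .mkRule("CD68", positive = "CD68", negative = "panCK", splits = "CD16a"),
      .mkRule("CD3", positive = "CD3", negative = c("panCK", "CD68"),
              splits = "CD16a", attrs = "CD94"),
      .mkRule("CD94", positive = "CD94", negative = c("panCK", "CD68", "CD3"),
              splits = "CD16a"),
      .mkRule("CD16a", positive = "CD16a",
              negative = c("panCK", "CD68", "CD3", "CD94")),
      .mkRule("Other", negative = c("panCK", "CD68", "CD3", "CD94", "CD16a")))
  } else {
    rules <- list(
      .mkRule("PanCK", positive = "panCK"),
      .mkRule("CD68", positive = "CD68", negative = "panCK",
              splits = c("CD163", "CD16a")),
      .mkRule("CD163", positive = "CD163", negative = c("panCK", "CD68"),
              splits = "CD16a"),
      .mkRule("CD3", positive = "CD3",
              negative = c("panCK", "CD68", "CD163"),
              splits = c("CD8", "CD16a"), attrs = "CD94"),
      .mkRule("CD8", positive = "CD8",
              negative = c("panCK", "CD68", "CD163", "CD3"),
              splits = "CD16a"),
      .mkRule("CD94", positive = "CD94",
              negative = c("panCK", "CD68", "CD163", "CD3", "CD8"),
              splits = "CD16a"),
      .mkRule("CD16a", positive = "CD16a",
              negative = c("panCK", "CD68", "CD163", "CD3", "CD8", "CD94")),
      .mkRule("Other", negative = m))
  }
  gatingHierarchy(m, rules)
}

#' All phenotype labels a hierarchy can emit
#'
#' @param hierarchy a \code{\linkS4class{GatingHierarchy}}.
#' @return character vector of labels, in rule order with split variants
#'   expanded (e.g. panel 1: PanCK, CD68, CD68_CD16a, CD3, CD3_CD16a,
#'   CD94, CD94_CD16a, CD16a, Other).
#' @export
phenotypeLevels <- function(hierarchy) {
  stopifnot(is(hierarchy, "GatingHierarchy"))
  unique(unlist(lapply(hierarchy@rules, function(r) {
    if (!length(r$splits)) return(r$label)
    on <- expand.grid(rep(list(c(FALSE, TRUE)), length(r$splits)))
    apply(on, 1L, function(b)
      paste(c(r$label, r$splits[as.logical(b)]), collapse = "_"))
  })))
}

# Gate one binary marker vector (named 0/1) through the hierarchy.
# Returns list(label, attrs = named 0/1 over the rule's attr markers).
.gateVector <- function(v, hierarchy) {
  for (r in hierarchy@rules) {
    if (all(v[r$positive] == 1) && all(v[r$negative] == 0)) {
      label <- r$label
      if (length(r$splits)) {
        on <- r$splits[v[r$splits] == 1]
        if (length(on)) label <- paste(c(label, on), collapse = "_")
      }
      attrs <- if (length(r$attrs)) setNames(as.integer(v[r$attrs]), r$attrs)
               else integer()
      return(list(label = label, attrs = attrs))
    }
  }
  stop("marker vector matched no gating rule")  # unreachable for valid hierarchy
}

#' Assign phenotypes from binary marker calls
#'
#' First-match-wins evaluation of the ordered gating hierarchy over the
#' \code{pos_<marker>} columns.
#'
#' @param cellTable data.frame with one \code{pos_<marker>} column (0/1)
#'   per hierarchy marker.
#' @param hierarchy a \code{\linkS4class{GatingHierarchy}}.
#' @return the input with a \code{phenotype} column appended, plus one
#'   \code{mod_<marker>} column per attribute marker (NA outside the rule
#'   that records it).
#' @export
assignPhenotypes <- function(cellTable, hierarchy) {
  stopifnot(is(hierarchy, "GatingHierarchy"), is.data.frame(cellTable))
  mk <- hierarchy@markers
  cols <- paste0("pos_", mk)
  miss <- setdiff(cols, names(cellTable))
  if (length(miss))
    stop("missing positivity call column(s): ", paste(miss, collapse = ", "))
  P <- as.matrix(cellTable[cols])
  colnames(P) <- mk
  if (anyNA(P)) {
    bad <- which(rowSums(is.na(P)) > 0)[1L]
    stop("missing marker call at row ", bad,
         if ("cell_id" %in% names(cellTable))
           paste0(" (cell_id ", cellTable$cell_id[bad], ")") else "")
  }
  if (!all(P %in% c(0, 1))) stop("positivity calls must be 0/1")
  n <- nrow(P)
  phen <- rep(NA_character_, n)
  attrCols <- unique(unlist(lapply(hierarchy@rules, `[[`, "attrs")))
  attrs <- matrix(NA_integer_, n, length(attrCols),
                  dimnames = list(NULL, attrCols))
  open <- rep(TRUE, n)
  for (r in hierarchy@rules) {
    hit <- open
    for (p in r$positive) hit <- hit & P[, p] == 1
    for (q in r$negative) hit <- hit & P[, q] == 0
    if (!any(hit)) next
    lab <- rep(r$label, sum(hit))
    for (s in r$splits)
      lab <- ifelse(P[hit, s] == 1, paste0(lab, "_", s), lab)
    # suffix order must follow the rule's splits order, not positivity order:
    if (length(r$splits) > 1L) {
      sub <- P[hit, r$splits, drop = FALSE]
      lab <- apply(sub, 1L, function(b)
        paste(c(r$label, r$splits[b == 1]), collapse = "_"))
    }
    phen[hit] <- lab
    for (a in r$attrs) attrs[hit, a] <- as.integer(P[hit, a])
    open <- open & !hit
  }
  stopifnot(!anyNA(phen))
  out <- cellTable
  out$phenotype <- phen
  for (a in attrCols) out[[paste0("mod_", a)]] <- attrs[, a]
  out
}

#' Log-normalize marker signals
#'
#' Elementwise \code{log(1 + x)}; monotone, preserves cell order.
#'
#' @param signals numeric vector, matrix or data.frame of nonnegative
#'   marker signals.
#' @return same shape, log1p-transformed.
#' @export
logNormalize <- function(signals) {
  x <- if (is.data.frame(signals)) as.matrix(signals) else signals
  if (!is.numeric(x)) stop("signals must be numeric")
  neg <- which(x < 0)
  if (length(neg))
    stop("negative signal at position ", neg[1L],
         " (value ", x[neg[1L]], "); signals must be >= 0")
  out <- log1p(x)
  if (is.data.frame(signals)) as.data.frame(out) else out
}

#' Otsu positivity threshold
#'
#' Histogram-based two-class threshold maximizing between-class variance;
#' the default way positivity cutoffs are derived on the normalized scale
#' when none are supplied.
#'
#' @param x numeric signal vector.
#' @param nbins histogram bins (default 256).
#' @return threshold value; values strictly above it are called positive.
#' @export
otsuThreshold <- function(x, nbins = 256L) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  r <- range(x)
  if (diff(r) == 0) return(r[1L])
  breaks <- seq(r[1L], r[2L], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins)
  mids <- (breaks[-1L] + breaks[-(nbins + 1L)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  muT <- mu[nbins]; n <- w[nbins]
  w0 <- w[-nbins]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bc <- rep(-Inf, nbins - 1L)
  bc[valid] <- (muT * w0[valid] / n - mu[-nbins][valid])^2 /
    (w0[valid] / n * w1[valid] / n)
  breaks[which.max(bc) + 1L]
}

#' Cluster normalized expression and pick the cluster count at the elbow
#'
#' k-means (k-means++ seeding, 10 restarts, best inertia) on the unscaled
#' normalized signal matrix, over a set of candidate cluster counts; the
#' kept count is the knee of the within-cluster-dispersion curve (maximum
#' perpendicular distance to the chord, ties to the smallest count).
#'
#' @param normalized numeric matrix/data.frame (cells x markers) of
#'   log-normalized signals.
#' @param candidates integer vector of candidate cluster counts.
#' @param seed integer seed.
#' @param nstart restarts per candidate (default 10).
#' @return an \code{\linkS4class{ExpressionClusterModel}}.
#' @export
clusterExpression <- function(normalized, candidates = 2:15, seed = 1L,
                              nstart = 10L) {
  X <- as.matrix(normalized)
  if (nrow(X) < 2L) stop("need at least 2 cells")
  candidates <- sort(unique(as.integer(candidates)))
  if (any(candidates < 1L)) stop("candidate cluster counts must be >= 1")
  if (max(candidates) > nrow(X))
    stop("more clusters (", max(candidates), ") than cells (", nrow(X), ")")
  fits <- lapply(candidates, function(k)
    .kmeansFit(X, k, nstart = nstart, seed = seed + k))
  wss <- vapply(fits, `[[`, numeric(1), "tot.withinss")
  kbest <- .elbowKnee(candidates, wss)
  fit <- fits[[match(kbest, candidates)]]
  mk <- colnames(X)
  if (is.null(mk)) mk <- paste0("V", seq_len(ncol(X)))
  colnames(fit$centers) <- mk
  new("ExpressionClusterModel", nClusters = as.integer(kbest),
      centers = fit$centers, clusterIds = fit$cluster,
      elbow = data.frame(k = candidates, withinss = wss),
      markers = mk, seed = as.integer(seed))
}

#' Map expression clusters to phenotypes
#'
#' Each cluster's mean normalized signal is thresholded into a binary
#' marker vector and gated through the hierarchy; member cells inherit the
#' cluster's phenotype.
#'
#' @param model an \code{\linkS4class{ExpressionClusterModel}}.
#' @param hierarchy a \code{\linkS4class{GatingHierarchy}}.
#' @param thresholds named numeric, one positivity threshold per panel
#'   marker on the normalized scale (strictly-above is positive).
#' @return data.frame: \code{cluster}, \code{phenotype}, and one
#'   \code{mod_<marker>} column per attribute marker.
#' @export
clusterToPhenotype <- function(model, hierarchy, thresholds) {
  stopifnot(is(model, "ExpressionClusterModel"),
            is(hierarchy, "GatingHierarchy"))
  mk <- hierarchy@markers
  miss <- setdiff(mk, names(thresholds))
  if (length(miss))
    stop("missing threshold for marker(s): ", paste(miss, collapse = ", "))
  miss2 <- setdiff(mk, colnames(model@centers))
  if (length(miss2))
    stop("model lacks marker(s): ", paste(miss2, collapse = ", "))
  attrCols <- unique(unlist(lapply(hierarchy@rules, `[[`, "attrs")))
  out <- data.frame(cluster = seq_len(model@nClusters),
                    phenotype = NA_character_)
  for (a in attrCols) out[[paste0("mod_", a)]] <- NA_integer_
  for (i in seq_len(model@nClusters)) {
    v <- setNames(as.numeric(model@centers[i, mk] > thresholds[mk]), mk)
    g <- .gateVector(v, hierarchy)
    out$phenotype[i] <- g$label
    for (a in names(g$attrs)) out[[paste0("mod_", a)]][i] <- g$attrs[[a]]
  }
  out
}

#' Phenotype a cell table end to end
#'
#' Dispatches on available columns: a \code{phenotype} column is taken
#' as-is; otherwise \code{pos_<marker>} calls are gated directly; otherwise
#' \code{marker_<name>} intensities are log-normalized, clustered, and the
#' clusters gated via per-marker thresholds (Otsu on the normalized signal
#' unless supplied).
#'
#' @param cellTable canonical cell table.
#' @param hierarchy a \code{\linkS4class{GatingHierarchy}}.
#' @param thresholds optional named per-marker thresholds (normalized scale).
#' @param candidates candidate cluster counts for the clustering route.
#' @param seed integer seed for the clustering route.
#' @return the table with \code{phenotype} (and any \code{mod_} columns).
#' @export
phenotypeCells <- function(cellTable, hierarchy = defaultHierarchy("panel1"),
                           thresholds = NULL, candidates = 2:15, seed = 1L) {
  if ("phenotype" %in% names(cellTable)) return(cellTable)
  mk <- hierarchy@markers
  if (all(paste0("pos_", mk) %in% names(cellTable)))
    return(assignPhenotypes(cellTable, hierarchy))
  intCols <- paste0("marker_", mk)
  miss <- setdiff(intCols, names(cellTable))
  if (length(miss))
    stop("cell table has neither phenotype, pos_, nor full marker_ columns; ",
         "missing: ", paste(miss, collapse = ", "))
  X <- logNormalize(as.matrix(cellTable[intCols]))
  colnames(X) <- mk
  model <- clusterExpression(X, candidates = candidates, seed = seed)
  if (is.null(thresholds))
    thresholds <- vapply(mk, function(m) otsuThreshold(X[, m]), numeric(1))
  map <- clusterToPhenotype(model, hierarchy, thresholds)
  idx <- match(model@clusterIds, map$cluster)
  out <- cellTable
  out$phenotype <- map$phenotype[idx]
  for (cn in grep("^mod_", names(map), value = TRUE))
    out[[cn]] <- map[[cn]][idx]
  out
}
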