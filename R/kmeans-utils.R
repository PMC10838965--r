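# Shared k-means machinery: k-means++ seeding, multiple restarts, best
# inertia kept. Lloyd iterations delegate to stats::kmeans.

# k-means++ initial centers: first uniform, then proportional to squared
# distance from the nearest chosen center. Distances via the expansion
# ||x-c||^2 = ||x||^2 - 2<x,c> + ||c||^2 (one BLAS mat-vec per center).
.kmeansPP <- function(X, k) {
  n <- nrow(X)
  rx2 <- rowSums(X * X)
  d2to <- function(j)
    pmax(rx2 - 2 * drop(X %*% X[j, ]) + sum(X[j, ]^2), 0)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  mind2 <- d2to(idx[1L])
  for (j in seq_len(k)[-1L]) {
    tot <- sum(mind2)
    idx[j] <- if (tot > 0) sample.int(n, 1L, prob = mind2) else sample.int(n, 1L)
    mind2 <- pmin(mind2, d2to(idx[j]))
  }
  X[idx, , drop = FALSE]
}

# Best-of-nstart k-means fit. Deterministic given seed. Returns a list with
# cluster (1-based), centers, tot.withinss.
.kmeansFit <- function(X, k, nstart = 10L, seed = 1L, iter.max = 100L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (k > nrow(X)) stop("more clusters (", k, ") than observations (", nrow(X), ")")
  if (k == 1L) {
    ctr <- matrix(colMeans(X), 1L, ncol(X), dimnames = list(NULL, colnames(X)))
    return(list(cluster = rep(1L, nrow(X)), centers = ctr,
                tot.withinss = sum(sweep(X, 2L, ctr[1L, ])^2)))
  }
  set.seed(seed)
  best <- NULL
  for (s in seq_len(nstart)) {
    init <- .kmeansPP(X, k)
    if (anyDuplicated(init)) {
      # degenerate data (fewer distinct rows than k): nudge duplicates apart
      dup <- duplicated(init)
      init[dup, ] <- init[dup, , drop = FALSE] +
        matrix(rnorm(sum(dup) * ncol(init), 0, 1e-8 + 1e-8 * sd(X)),
               sum(dup), ncol(init))
    }
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(X, centers = init, iter.max = iter.max,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed on all restarts")
  list(cluster = as.integer(best$cluster), centers = best$centers,
       tot.withinss = best$tot.withinss)
}

# Knee of a dispersion curve: the point with maximum perpendicular distance
# to the chord joining the curve's endpoints, after scaling both axes to
# [0, 1] so the choice is invariant to units. Ties go to the smallest k.
.elbowKnee <- function(k, withinss) {
  stopifnot(length(k) == length(withinss))
  if (length(k) == 1L) return(k)
  o <- order(k)
  k <- k[o]; w <- withinss[o]
  kx <- (k - k[1L]) / max(k[length(k)] - k[1L], .Machine$double.eps)
  rw <- max(w) - min(w)
  wy <- if (rw > 0) (w - min(w)) / rw else rep(0, length(w))
  # distance from (kx, wy) to the chord from first to last point
  x1 <- kx[1L]; y1 <- wy[1L]; x2 <- kx[length(kx)]; y2 <- wy[length(wy)]
  d <- abs((y2 - y1) * kx - (x2 - x1) * wy + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  k[which.max(d)]
}
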