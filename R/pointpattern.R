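# Spatial clustering statistics for membrane point patterns:
# nearest-neighbour distances of EM gold particles and oligomer counting
# of PALM localizations with the 50-nm association / 10-nm deduplication
# rules.

# pairwise Euclidean distance matrix, optionally on the torus defined by
# the window (toroidal mode exists solely for closed-form CSR checks)
.pairDist <- function(coords, window = NULL, toroidal = FALSE) {
  if (!toroidal) return(as.matrix(stats::dist(coords)))
  wx <- window[3L] - window[1L]
  wy <- window[4L] - window[2L]
  dx <- abs(outer(coords[, 1L], coords[, 1L], "-"))
  dy <- abs(outer(coords[, 2L], coords[, 2L], "-"))
  dx <- pmin(dx, wx - dx)
  dy <- pmin(dy, wy - dy)
  sqrt(dx * dx + dy * dy)
}

#' Nearest-neighbour distances of a point pattern
#'
#' For each point, the distance to its closest other point; the mean NND
#' is the headline clustering statistic for gold-particle maps. No edge
#' correction is applied (matching direct measurement on images); a
#' toroidal metric is available for closed-form calibration checks, where
#' the CSR expectation is `1 / (2 sqrt(lambda))`.
#'
#' @param pattern a [PointPattern-class] with at least 2 points.
#' @param toroidal use the wrapped distance on the window torus.
#' @return list with `distances` (per-point NND, input order) and `mean`.
#' @examples
#' p <- PointPattern(rbind(c(0, 0), c(80, 0)), c(0, 0, 500, 500))
#' nearestNeighborDistances(p)
#' @export
nearestNeighborDistances <- function(pattern, toroidal = FALSE) {
  stopifnot(is(pattern, "PointPattern"))
  n <- nPoints(pattern)
  if (n < 2L)
    stop("nearest-neighbour analysis needs at least 2 points")
  d <- .pairDist(coords(pattern), observationWindow(pattern), toroidal)
  diag(d) <- Inf
  nnd <- apply(d, 1L, min)
  list(distances = unname(nnd), mean = mean(nnd))
}

#' Monte-Carlo CSR null for the mean nearest-neighbour distance
#'
#' Simulates `nSims` completely random (binomial) patterns with the same
#' number of points and window as the observed pattern and compares mean
#' NNDs. The p-value tests the clustering direction (observed mean NND
#' smaller than the null), with the standard Monte-Carlo correction
#' `p = (1 + #{null <= observed}) / (nSims + 1)`.
#'
#' @param pattern a [PointPattern-class] with >= 2 points.
#' @param nSims number of null simulations (>= 19 for p resolution at the
#'   5% level).
#' @param seed integer seed; the null distribution is reproducible.
#' @param toroidal forwarded to [nearestNeighborDistances()].
#' @return list with `observedMean`, `nullMeans` (length `nSims`) and `p`.
#' @export
csrNull <- function(pattern, nSims = 199L, seed, toroidal = FALSE) {
  stopifnot(is(pattern, "PointPattern"))
  nSims <- .assertCount(nSims, "nSims", 19L)
  n <- nPoints(pattern)
  if (n < 2L) stop("need at least 2 points")
  w <- observationWindow(pattern)
  obs <- nearestNeighborDistances(pattern, toroidal)$mean
  nullMeans <- .withSeed(seed, vapply(seq_len(nSims), function(i) {
    pts <- cbind(stats::runif(n, w[1L], w[3L]),
                 stats::runif(n, w[2L], w[4L]))
    nearestNeighborDistances(PointPattern(pts, w), toroidal)$mean
  }, numeric(1L)))
  list(observedMean = obs, nullMeans = nullMeans,
       p = (1 + sum(nullMeans <= obs)) / (nSims + 1))
}

#' Oligomer-counting configuration
#'
#' @param assocRadius association radius in nm (default 50): molecules
#'   within this distance of a localization count toward its cluster size.
#' @param dedupRadius deduplication radius in nm (default 10): repeat
#'   activations within this distance of an already-retained localization
#'   are discounted to avoid overestimating oligomer sizes.
#' @return validated configuration list for [countOligomers()].
#' @export
clusterConfig <- function(assocRadius = 50, dedupRadius = 10) {
  .assertNumber(assocRadius, "assocRadius", lower = 0, closedLower = FALSE)
  .assertNumber(dedupRadius, "dedupRadius", lower = 0)
  if (dedupRadius >= assocRadius)
    stop("'dedupRadius' must be smaller than 'assocRadius'")
  list(assocRadius = assocRadius, dedupRadius = dedupRadius)
}

#' Count receptor oligomers from localization coordinates
#'
#' Two steps. Deduplication: points are taken in a deterministic order
#' (sorted by x, then y) and greedily retained; any point within
#' `dedupRadius` of an already-retained point is discarded, so the
#' retained set has all pairwise distances above the deduplication
#' radius. Counting: each retained molecule's cluster size is the number
#' of retained molecules within `assocRadius` of it, inclusive of itself
#' (a per-molecule neighbourhood count; an isolated molecule has size 1).
#'
#' @param localizations a [PointPattern-class] with >= 1 point (nm).
#' @param config see [clusterConfig()].
#' @return list with `sizes` (per retained molecule), `meanSize`,
#'   `nRetained` and `nDiscarded`.
#' @examples
#' pts <- rbind(c(0, 0), c(3, 0), c(40, 0))  # first two are one blinking
#' p <- PointPattern(pts, c(-100, -100, 100, 100))
#' countOligomers(p)
#' @export
countOligomers <- function(localizations, config = clusterConfig()) {
  stopifnot(is(localizations, "PointPattern"))
  n <- nPoints(localizations)
  if (n < 1L) stop("need at least 1 localization")
  cc <- coords(localizations)
  ord <- order(cc[, 1L], cc[, 2L])
  cc <- cc[ord, , drop = FALSE]
  keptIdx <- integer(0L)
  r2 <- config$dedupRadius^2
  for (i in seq_len(n)) {
    if (length(keptIdx)) {
      dx <- cc[keptIdx, 1L] - cc[i, 1L]
      dy <- cc[keptIdx, 2L] - cc[i, 2L]
      if (min(dx * dx + dy * dy) <= r2) next
    }
    keptIdx <- c(keptIdx, i)
  }
  kept <- cc[keptIdx, , drop = FALSE]
  m <- nrow(kept)
  if (m == 1L) {
    sizes <- 1L
  } else {
    d <- as.matrix(stats::dist(kept))
    sizes <- as.integer(rowSums(d <= config$assocRadius))  # diag 0 counts self
  }
  list(sizes = sizes, meanSize = mean(sizes), nRetained = m,
       nDiscarded = n - m)
}
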