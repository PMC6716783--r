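# Independent brute-force oracles. These deliberately re-derive each
# statistic by direct enumeration, sharing no code with the package's
# implementations.

# TA-MSD by direct enumeration of observed frame pairs
bruteTAMSD <- function(coords, frameIdx, maxLagAbs) {
  rows <- NULL
  for (lag in seq_len(maxLagAbs)) {
    j <- match(frameIdx + lag, frameIdx)
    ok <- which(!is.na(j))
    if (length(ok)) {
      d <- coords[j[ok], , drop = FALSE] - coords[ok, , drop = FALSE]
      rows <- rbind(rows, c(lag = lag, msd = mean(rowSums(d^2)),
                            n = length(ok)))
    }
  }
  rows
}

# per-point nearest-neighbour distances by double loop
bruteNND <- function(pts) {
  n <- nrow(pts)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (j == i) next
      d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# greedy dedup + per-molecule neighbourhood count, O(n^2) enumeration
bruteOligomers <- function(pts, assocRadius = 50, dedupRadius = 10) {
  ord <- order(pts[, 1], pts[, 2])
  pts <- pts[ord, , drop = FALSE]
  kept <- NULL
  for (i in seq_len(nrow(pts))) {
    discard <- FALSE
    if (!is.null(kept)) {
      dd <- sqrt((kept[, 1] - pts[i, 1])^2 + (kept[, 2] - pts[i, 2])^2)
      discard <- any(dd <= dedupRadius)
    }
    if (!discard) kept <- rbind(kept, pts[i, , drop = FALSE])
  }
  m <- nrow(kept)
  sizes <- integer(m)
  for (i in seq_len(m)) {
    dd <- sqrt((kept[, 1] - kept[i, 1])^2 + (kept[, 2] - kept[i, 2])^2)
    sizes[i] <- sum(dd <= assocRadius)
  }
  list(sizes = sizes, meanSize = mean(sizes), nRetained = m, kept = kept)
}

# random test trajectory (possibly gapped) as plain coords + frame index
randomTrackFixture <- function(n, gapped = FALSE) {
  coords <- cbind(cumsum(rnorm(n, sd = 0.1)), cumsum(rnorm(n, sd = 0.1)))
  fr <- seq_len(n) - 1L
  if (gapped && n > 6L) {
    drop <- sample(2:(n - 1L), size = max(1L, floor(n / 10)))
    coords <- coords[-drop, , drop = FALSE]
    fr <- fr[-drop]
  }
  list(coords = coords, frames = fr)
}
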