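#' Simulate a spatial point pattern
#'
#' Generates either complete spatial randomness (CSR, homogeneous Poisson)
#' or a Thomas cluster process in a rectangular window, emulating EM
#' gold-particle maps and PALM localization fields. The Thomas process
#' draws Poisson parents at rate `intensity`, gives each parent a
#' Poisson(`meanOffspring`) number of offspring, and displaces offspring
#' isotropically with Gaussian SD `clusterSd`; offspring falling outside
#' the window are discarded (imaged membrane sheets have hard edges)
#' unless `toroidal = TRUE`, which wraps them for closed-form checks.
#'
#' @param window numeric `c(xmin, ymin, xmax, ymax)` in nm, positive area.
#' @param process `"CSR"` or `"Thomas"`.
#' @param intensity points per nm^2 (CSR) or parents per nm^2 (Thomas),
#'   > 0 (an intensity small enough to yield zero points gives an empty
#'   pattern, not an error).
#' @param meanOffspring mean offspring per parent (Thomas only).
#' @param clusterSd offspring displacement SD in nm (Thomas only; 0
#'   collapses offspring onto their parents).
#' @param seed integer seed.
#' @param toroidal wrap offspring around the window edges instead of
#'   discarding them.
#' @return A [PointPattern-class].
#' @examples
#' csr <- simulatePointPattern(c(0, 0, 2000, 2000), "CSR",
#'                             intensity = 1e-4, seed = 1)
#' nPoints(csr)
#' @export
simulatePointPattern <- function(window, process = c("CSR", "Thomas"),
                                 intensity, meanOffspring = NULL,
                                 clusterSd = NULL, seed,
                                 toroidal = FALSE) {
  process <- match.arg(process)
  window <- as.numeric(window)
  if (length(window) != 4L || window[3L] <= window[1L] ||
      window[4L] <= window[2L])
    stop("'window' must be c(xmin, ymin, xmax, ymax) with positive area")
  .assertNumber(intensity, "intensity", lower = 0, closedLower = FALSE)
  wx <- window[3L] - window[1L]
  wy <- window[4L] - window[2L]
  area <- wx * wy
  .withSeed(seed, {
    if (process == "CSR") {
      n <- stats::rpois(1L, intensity * area)
      pts <- cbind(stats::runif(n, window[1L], window[3L]),
                   stats::runif(n, window[2L], window[4L]))
    } else {
      .assertNumber(meanOffspring, "meanOffspring", lower = 0,
                    closedLower = FALSE)
      .assertNumber(clusterSd, "clusterSd", lower = 0)
      nParents <- stats::rpois(1L, intensity * area)
      px <- stats::runif(nParents, window[1L], window[3L])
      py <- stats::runif(nParents, window[2L], window[4L])
      nOff <- stats::rpois(nParents, meanOffspring)
      parent <- rep.int(seq_len(nParents), nOff)
      total <- sum(nOff)
      pts <- cbind(px[parent] + stats::rnorm(total, sd = clusterSd),
                   py[parent] + stats::rnorm(total, sd = clusterSd))
      if (toroidal && total) {
        pts[, 1L] <- window[1L] + (pts[, 1L] - window[1L]) %% wx
        pts[, 2L] <- window[2L] + (pts[, 2L] - window[2L]) %% wy
      } else if (total) {
        keep <- pts[, 1L] >= window[1L] & pts[, 1L] <= window[3L] &
                pts[, 2L] >= window[2L] & pts[, 2L] <= window[4L]
        pts <- pts[keep, , drop = FALSE]
      }
    }
    PointPattern(pts, window)
  })
}
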