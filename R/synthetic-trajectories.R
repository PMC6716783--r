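# Fractional-Brownian-motion trajectory generator.
#
# Each coordinate of a simulated molecule is fractional Brownian motion
# with Hurst exponent H = alpha / 2 and Var[x(t) - x(0)] = 2 D t^alpha,
# so the 2D ensemble MSD is 4 D t^alpha; iid Gaussian localization noise
# of SD sigmaErr per coordinate per frame adds the constant 4 sigmaErr^2
# offset of the TA-MSD model. Increments are sampled from the exact
# fractional-Gaussian-noise covariance (Cholesky factorization for short
# tracks, Davies-Harte circulant embedding for long ones), never from an
# Euler-type approximation, so the generator can serve as an exact oracle
# for the downstream fit.

# autocovariance of unit-variance fGn at integer lag k
.fgnAutocov <- function(k, H) {
  0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

.fgnCholFactor <- function(nInc, H) {
  G <- stats::toeplitz(.fgnAutocov(seq_len(nInc) - 1, H))
  # fGn covariance is PD for H < 1; a hair of ridge guards roundoff near H = 1
  tryCatch(chol(G), error = function(e) chol(G + diag(1e-10, nInc)))
}

.fgnCircEigen <- function(nInc, H) {
  m <- 2^ceiling(log2(2 * nInc))
  g <- .fgnAutocov(0:(m / 2), H)
  row <- c(g, rev(g[2:(m / 2)]))
  lam <- Re(stats::fft(row))
  tol <- 1e-8 * max(lam)
  lam[lam < 0 & lam > -tol] <- 0
  if (any(lam < 0))
    stop("circulant embedding of the fGn covariance is not nonnegative ",
         "definite at H = ", H)
  lam
}

.fgnCircSample <- function(lam, nInc) {
  m <- length(lam)
  half <- m / 2
  W <- complex(m)
  W[1L] <- sqrt(lam[1L]) * stats::rnorm(1L)
  W[half + 1L] <- sqrt(lam[half + 1L]) * stats::rnorm(1L)
  j <- 2:half
  W[j] <- sqrt(lam[j] / 2) *
    complex(real = stats::rnorm(half - 1L),
            imaginary = stats::rnorm(half - 1L))
  W[m - j + 2L] <- Conj(W[j])
  Re(stats::fft(W))[seq_len(nInc)] / sqrt(m)
}

# returns function(k) producing an nInc x k matrix of unit-variance fGn
.fgnGenerator <- function(nInc, H, method = c("auto", "cholesky",
                                              "circulant")) {
  method <- match.arg(method)
  if (H == 1) {
    # perfectly correlated increments: ballistic limit alpha = 2
    return(function(k) matrix(stats::rnorm(k), nrow = nInc, ncol = k,
                              byrow = TRUE))
  }
  if (method == "auto")
    method <- if (nInc <= 2048L) "cholesky" else "circulant"
  if (method == "cholesky") {
    R <- .fgnCholFactor(nInc, H)
    function(k) crossprod(R, matrix(stats::rnorm(nInc * k), nrow = nInc))
  } else {
    lam <- .fgnCircEigen(nInc, H)
    function(k) vapply(seq_len(k), function(i) .fgnCircSample(lam, nInc),
                       numeric(nInc))
  }
}

.checkTrajectoryParams <- function(nFrames, D, alpha, sigmaErr, dt) {
  nFrames <- .assertCount(nFrames, "nFrames", 2L)
  .assertNumber(D, "D", lower = 0)
  .assertNumber(alpha, "alpha", lower = 0, upper = 2, closedLower = FALSE)
  .assertNumber(sigmaErr, "sigmaErr", lower = 0)
  .assertNumber(dt, "dt", lower = 0, closedLower = FALSE)
  nFrames
}

# draws count trajectories from an already-seeded RNG stream
.drawTrajectories <- function(count, nFrames, D, alpha, sigmaErr, dt,
                              method = "auto") {
  nInc <- nFrames - 1L
  s <- sqrt(2 * D * dt^alpha)
  gen <- .fgnGenerator(nInc, alpha / 2, method)
  inc <- gen(2L * count) * s
  lapply(seq_len(count), function(k) {
    pos <- cbind(cumsum(c(0, inc[, 2L * k - 1L])),
                 cumsum(c(0, inc[, 2L * k])))
    if (sigmaErr > 0)
      pos <- pos + matrix(stats::rnorm(2L * nFrames, sd = sigmaErr),
                          ncol = 2L)
    Trajectory(pos, dt)
  })
}

#' Simulate a single anomalous-diffusion trajectory
#'
#' Generates one 2D trajectory whose per-coordinate path is fractional
#' Brownian motion with Hurst exponent `alpha / 2` and
#' `Var[x(t) - x(0)] = 2 D t^alpha`, plus iid Gaussian localization noise
#' of SD `sigmaErr` per coordinate per frame. The ensemble-mean squared
#' displacement is therefore `4 D t^alpha + 4 sigmaErr^2`, the model fitted
#' by [fitMSD()]. Increments are drawn from the exact fGn covariance.
#'
#' @param nFrames number of frames (>= 2).
#' @param D generalized diffusion coefficient, um^2 s^-alpha, >= 0.
#' @param alpha anomalous diffusion exponent in (0, 2]; `alpha = 1` is the
#'   Brownian special case with iid increments.
#' @param sigmaErr per-coordinate localization error SD in um.
#' @param dt frame interval in seconds (default 0.03, i.e. 30-ms
#'   single-molecule TIRF acquisition).
#' @param seed integer seed; required. The caller's RNG state is left
#'   untouched.
#' @param method `"cholesky"` (exact triangular factor, default for tracks
#'   up to 2,048 increments), `"circulant"` (Davies-Harte embedding, exact
#'   as well, used for longer tracks) or `"auto"`.
#' @return A [Trajectory-class].
#' @examples
#' traj <- simulateTrajectory(100, D = 0.1, alpha = 1, sigmaErr = 0.02,
#'                            seed = 1)
#' traj
#' @export
simulateTrajectory <- function(nFrames, D, alpha, sigmaErr = 0, dt = 0.03,
                               seed, method = c("auto", "cholesky",
                                                "circulant")) {
  nFrames <- .checkTrajectoryParams(nFrames, D, alpha, sigmaErr, dt)
  method <- match.arg(method)
  .withSeed(seed,
    .drawTrajectories(1L, nFrames, D, alpha, sigmaErr, dt, method)[[1L]])
}

#' Describe one motion component of a synthetic cohort
#'
#' @param label component label (e.g. `"immobile"`); must be unique within
#'   a cohort.
#' @param count number of trajectories (>= 1).
#' @param nFrames,D,alpha,sigmaErr,dt as in [simulateTrajectory()].
#' @return A validated component description for [simulateCohort()].
#' @export
trajectoryComponent <- function(label, count, nFrames, D, alpha,
                                sigmaErr = 0, dt = 0.03) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  count <- .assertCount(count, "count", 1L)
  nFrames <- .checkTrajectoryParams(nFrames, D, alpha, sigmaErr, dt)
  list(label = label, count = count, nFrames = nFrames, D = D,
       alpha = alpha, sigmaErr = sigmaErr, dt = dt)
}

#' Simulate a labelled cohort of trajectories
#'
#' Generates a mixture of motion components with known ground-truth labels,
#' emulating the pooled trajectory groups of single-molecule tracking
#' experiments. Output order is deterministic (components in the order
#' given, trajectories in generation order) and bitwise-reproducible from
#' the seed.
#'
#' @param components list of [trajectoryComponent()] descriptions.
#' @param seed integer seed.
#' @return A list with elements `trajectories` (list of
#'   [Trajectory-class]) and `labels` (character vector aligned 1:1).
#' @examples
#' cohort <- simulateCohort(list(
#'   trajectoryComponent("immobile", 5, nFrames = 120, D = 0.001, alpha = 1),
#'   trajectoryComponent("normal", 5, nFrames = 120, D = 0.05, alpha = 1)
#' ), seed = 7)
#' table(cohort$labels)
#' @export
simulateCohort <- function(components, seed) {
  if (!is.list(components) || length(components) == 0L)
    stop("'components' must be a non-empty list of trajectoryComponent()s")
  components <- lapply(components, function(cmp)
    do.call(trajectoryComponent, cmp))
  labels <- vapply(components, `[[`, character(1L), "label")
  if (anyDuplicated(labels))
    stop("component labels must be unique")
  .withSeed(seed, {
    trajs <- list()
    lab <- character()
    for (cmp in components) {
      trajs <- c(trajs, .drawTrajectories(cmp$count, cmp$nFrames, cmp$D,
                                          cmp$alpha, cmp$sigmaErr, cmp$dt))
      lab <- c(lab, rep(cmp$label, cmp$count))
    }
    list(trajectories = trajs, labels = lab)
  })
}

#' The four benchmark motion regimes
#'
#' Convenience cohort description with one component per motion class at
#' the parameter combinations used throughout the package's recovery
#' experiments: immobile (D = 0.001 um^2/s, alpha = 1), subdiffusive
#' (D = 0.05, alpha = 0.4), normal (D = 0.05, alpha = 1) and
#' superdiffusive (D = 0.05, alpha = 1.6), all with 0.02-um localization
#' error at 30-ms frames.
#'
#' @param count trajectories per class.
#' @param nFrames frames per trajectory (default 150, comfortably above
#'   the 100-frame analysis filter).
#' @param sigmaErr localization error SD in um.
#' @param dt frame interval in seconds.
#' @return list of [trajectoryComponent()]s for [simulateCohort()].
#' @export
benchmarkRegimes <- function(count = 250L, nFrames = 150L, sigmaErr = 0.02,
                             dt = 0.03) {
  list(
    trajectoryComponent("immobile", count, nFrames, D = 0.001, alpha = 1,
                        sigmaErr = sigmaErr, dt = dt),
    trajectoryComponent("subdiffusion", count, nFrames, D = 0.05,
                        alpha = 0.4, sigmaErr = sigmaErr, dt = dt),
    trajectoryComponent("normal", count, nFrames, D = 0.05, alpha = 1,
                        sigmaErr = sigmaErr, dt = dt),
    trajectoryComponent("superdiffusion", count, nFrames, D = 0.05,
                        alpha = 1.6, sigmaErr = sigmaErr, dt = dt)
  )
}
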