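# Single-molecule motion analysis: TA-MSD computation, power-law model
# fit and four-class motion classification.
#
# The fitted model is TA-MSD(t) = 4 D t^alpha + 4 sigmaErr^2, where t is
# the lag time, alpha the anomalous diffusion exponent and sigmaErr a
# constant localization-error offset. Classification uses the generalized
# diffusion coefficient and exponent jointly: D < 0.01 um^2 s^-alpha is
# immobile; mobile particles are subdiffusive (alpha < 0.75), normal
# (0.75 <= alpha <= 1.25) or superdiffusive (alpha > 1.25).

#' Time-averaged mean squared displacement
#'
#' For each frame lag n, averages |r(i+n) - r(i)|^2 over every observed
#' displacement pair of the track. Gapped frames (tracker gap-closing)
#' simply contribute no pairs: lags are counted in true frame units, so a
#' track observed at frames 1, 2, 4 contributes pairs (1,2) at lag 1,
#' (2,4) at lag 2 and (1,4) at lag 3.
#'
#' @param traj a [Trajectory-class].
#' @param maxLagFraction largest lag as a fraction of the track's frame
#'   span (default 0.25: long-lag TA-MSD estimates average few pairs and
#'   are noise-dominated).
#' @param maxLag absolute cap on the lag (default 50 frames).
#' @param minLags floor on the number of lags (useful to guarantee enough
#'   points for the three-parameter fit on short tracks).
#' @return An [MSDCurve-class]; lags with no observed pair are omitted.
#' @examples
#' traj <- simulateTrajectory(100, D = 0.1, alpha = 1, seed = 1)
#' timeAveragedMSD(traj)
#' @export
timeAveragedMSD <- function(traj, maxLagFraction = 0.25, maxLag = 50L,
                            minLags = 1L) {
  stopifnot(is(traj, "Trajectory"))
  .assertNumber(maxLagFraction, "maxLagFraction", 0, 1, closedLower = FALSE)
  n <- nFrames(traj)
  fr <- frames(traj)
  span <- fr[length(fr)] - fr[1L]
  lagMax <- min(max(as.integer(minLags), floor(maxLagFraction * span)),
                as.integer(maxLag), span)
  # scatter positions onto the full frame axis; gaps stay NA
  x <- rep(NA_real_, span + 1L)
  y <- rep(NA_real_, span + 1L)
  idx <- fr - fr[1L] + 1L
  cc <- coords(traj)
  x[idx] <- cc[, 1L]
  y[idx] <- cc[, 2L]
  lags <- integer()
  msd <- numeric()
  nPairs <- integer()
  for (lag in seq_len(lagMax)) {
    dx <- x[(1L + lag):(span + 1L)] - x[1L:(span + 1L - lag)]
    dy <- y[(1L + lag):(span + 1L)] - y[1L:(span + 1L - lag)]
    sq <- dx * dx + dy * dy
    ok <- !is.na(sq)
    if (any(ok)) {
      lags <- c(lags, lag)
      msd <- c(msd, mean(sq[ok]))
      nPairs <- c(nPairs, sum(ok))
    }
  }
  if (length(lags) == 0L)
    stop("no observed displacement pair at any lag; cannot form an MSD curve")
  new("MSDCurve", lags = lags, times = lags * frameInterval(traj),
      msd = msd, nPairs = nPairs, dt = frameInterval(traj))
}

#' Fit the anomalous-diffusion model to a TA-MSD curve
#'
#' Bounded nonlinear least squares of
#' `msd(t) = 4 D t^alpha + 4 sigmaErr^2` with `D >= 0`,
#' `alpha` in `[0, 2]`, `sigmaErr >= 0`, on the linear (not log) scale so
#' that the additive localization-error offset enters the objective the
#' way it enters the model. Initialization comes from a log-log linear
#' regression of the offset-corrected curve. Optimizer failure is reported
#' through the `converged` flag, never silently coerced.
#'
#' @param curve an [MSDCurve-class] with at least 5 lags (4 when
#'   `fixSigma` removes one parameter).
#' @param weighting `"none"` (default) for unweighted least squares, or
#'   `"npairs"` to weight each lag by the number of averaged pairs.
#' @param fixSigma optional known localization error SD (um). When given,
#'   only D and alpha are fitted; this removes the offset-versus-exponent
#'   degeneracy that limits per-trajectory exponent precision (see
#'   [summarizeCohort()], which estimates a cohort-shared sigma this way).
#' @param nFramesUsed optional integer recorded in the result (number of
#'   observed frames of the originating track).
#' @return A [MotionFit-class].
#' @examples
#' traj <- simulateTrajectory(150, D = 0.05, alpha = 1, sigmaErr = 0.02,
#'                            seed = 2)
#' fitMSD(timeAveragedMSD(traj))
#' @export
fitMSD <- function(curve, weighting = c("none", "npairs"),
                   fixSigma = NULL, nFramesUsed = NA_integer_) {
  stopifnot(is(curve, "MSDCurve"))
  weighting <- match.arg(weighting)
  nMin <- if (is.null(fixSigma)) 5L else 4L
  if (length(curve@lags) < nMin)
    stop("need at least ", nMin, " lags to fit the MSD model")
  if (!is.null(fixSigma)) .assertNumber(fixSigma, "fixSigma", lower = 0)
  t <- curve@times
  m <- curve@msd
  w <- if (weighting == "npairs") sqrt(curve@nPairs) else rep(1, length(m))

  # the objective has local minima in alpha, so the optimizer is started
  # from several log-log-regression-based guesses and the best converged
  # solution wins
  loglogStart <- function(mm, s0) {
    keep <- mm > 0
    if (sum(keep) < 2L) return(NULL)
    ll <- stats::lm(log(mm[keep]) ~ log(t[keep]))
    c(max(exp(stats::coef(ll)[[1L]]) / 4, 1e-12),
      min(max(stats::coef(ll)[[2L]], 0.05), 2), s0)
  }
  if (is.null(fixSigma)) {
    off <- min(m)
    starts <- Filter(Negate(is.null), list(
      loglogStart(m, 0),                                  # no-offset guess
      loglogStart(pmax(m - off, .Machine$double.eps),
                  sqrt(max(off, 0)) / 2),                 # offset-corrected
      c(max(m[1L] / (4 * t[1L]), 1e-12), 1, 0)            # Brownian guess
    ))
    resid <- function(p) w * (m - (4 * p[1L] * t^p[2L] + 4 * p[3L]^2))
    lower <- c(0, 0, 0); upper <- c(Inf, 2, Inf)
  } else {
    off <- 4 * fixSigma^2
    starts <- Filter(Negate(is.null), list(
      loglogStart(pmax(m - off, .Machine$double.eps), NULL)[1:2],
      c(max((m[1L] - off) / (4 * t[1L]), 1e-12), 1)
    ))
    resid <- function(p) w * (m - (4 * p[1L] * t^p[2L] + off))
    lower <- c(0, 0); upper <- c(Inf, 2)
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$info %in% 1:3 &&
        (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  # degenerate constant curves: alpha -> 0 makes D and the offset
  # interchangeable, so an exactly-constant MSD is resolved to the pure
  # localization-error solution (D = 0) whenever it fits as well
  if (!is.null(best)) {
    if (is.null(fixSigma)) {
      s2hat <- max(sum(w^2 * m) / sum(w^2), 0)
      flatDev <- sum((w * (m - s2hat))^2)
      if (flatDev <= best$deviance * (1 + 1e-8) + 1e-300) {
        best$par <- c(0, 1, sqrt(s2hat) / 2)
        best$deviance <- flatDev
      }
    } else {
      flatDev <- sum((w * (m - off))^2)
      if (flatDev <= best$deviance * (1 + 1e-8) + 1e-300) {
        best$par <- c(0, 1)
        best$deviance <- flatDev
      }
    }
  }
  sigmaOf <- function(p) if (is.null(fixSigma)) p[3L] else fixSigma
  if (is.null(best)) {
    p <- starts[[1L]]
    return(new("MotionFit", D = p[1L], alpha = p[2L],
               sigmaErr = sigmaOf(p), residualNorm = NA_real_,
               converged = FALSE, nFramesUsed = as.integer(nFramesUsed)))
  }
  fit <- best
  p <- fit$par
  new("MotionFit", D = p[1L], alpha = p[2L], sigmaErr = sigmaOf(p),
      residualNorm = fit$deviance, converged = TRUE,
      nFramesUsed = as.integer(nFramesUsed))
}

#' Motion-classifier thresholds
#'
#' Defaults are the standard single-molecule criteria: particles with
#' D < 0.01 um^2 s^-alpha are immobile; mobile particles with
#' 0.75 <= alpha <= 1.25 are normal, alpha < 0.75 subdiffusive,
#' alpha > 1.25 superdiffusive; only tracks lasting at least 100 frames
#' are analyzed.
#'
#' @param dImmobile immobility threshold on D (um^2 s^-alpha). D equal to
#'   the threshold counts as mobile.
#' @param alphaLow,alphaHigh normal-diffusion band on alpha; both
#'   boundaries are inclusive (alpha = 0.75 and alpha = 1.25 are normal).
#' @param minFrames minimum observed track length.
#' @return validated list of thresholds for [classifyMotion()] and
#'   [summarizeCohort()].
#' @export
motionThresholds <- function(dImmobile = 0.01, alphaLow = 0.75,
                             alphaHigh = 1.25, minFrames = 100L) {
  .assertNumber(dImmobile, "dImmobile", lower = 0, closedLower = FALSE)
  .assertNumber(alphaLow, "alphaLow", lower = 0, closedLower = FALSE)
  .assertNumber(alphaHigh, "alphaHigh", lower = alphaLow,
                closedLower = FALSE)
  minFrames <- .assertCount(minFrames, "minFrames", 2L)
  list(dImmobile = dImmobile, alphaLow = alphaLow, alphaHigh = alphaHigh,
       minFrames = minFrames)
}

#' Motion class labels
#' @return character vector of the four exhaustive, mutually exclusive
#'   classes.
#' @export
motionClasses <- function() {
  c("immobile", "subdiffusion", "normal", "superdiffusion")
}

#' Classify a fitted trajectory into one of four motion classes
#'
#' @param fit a converged [MotionFit-class]; non-converged fits are
#'   refused (the caller must filter them, they are never coerced into a
#'   class).
#' @param thresholds see [motionThresholds()].
#' @return one of `"immobile"`, `"subdiffusion"`, `"normal"`,
#'   `"superdiffusion"`.
#' @examples
#' fit <- new("MotionFit", D = 0.02, alpha = 0.5, sigmaErr = 0,
#'            residualNorm = 0, converged = TRUE, nFramesUsed = 150L)
#' classifyMotion(fit)
#' @export
classifyMotion <- function(fit, thresholds = motionThresholds()) {
  stopifnot(is(fit, "MotionFit"))
  if (!fit@converged)
    stop("refusing to classify a non-converged fit")
  if (fit@D < thresholds$dImmobile) return("immobile")
  if (fit@alpha < thresholds$alphaLow) return("subdiffusion")
  if (fit@alpha > thresholds$alphaHigh) return("superdiffusion")
  "normal"
}

#' Fit and classify a trajectory cohort
#'
#' Applies the track-length filter, the gap-fraction filter, the TA-MSD
#' fit and the four-class classifier to every trajectory, and reports
#' pooled class fractions per condition (pooled over trajectories, not
#' averaged per cell, matching how single-molecule class frequencies are
#' normally reported). Exclusions are counted, never silent.
#'
#' By default the localization error is estimated cohort-wide: a first
#' pass fits every trajectory with sigmaErr free, the cohort sigma is
#' taken as the median of the converged estimates (the static
#' localization error is a property of the instrument and label, not of
#' the individual molecule), and a second pass refits D and alpha per
#' trajectory with that shared offset. This removes the per-trajectory
#' degeneracy between the constant offset and a sublinear exponent, which
#' otherwise dominates exponent misclassification. Set
#' `sharedSigma = FALSE` for fully independent per-trajectory fits.
#'
#' The fit uses only the short-lag portion of the TA-MSD
#' (`maxLagFraction = 0.05` of the track, at least 5 lags): long-lag
#' TA-MSD values average few, strongly correlated pairs and mainly add
#' noise to the exponent estimate.
#'
#' @param trajectories list of [Trajectory-class].
#' @param conditions character vector of condition labels aligned with
#'   `trajectories` (default: one pooled condition).
#' @param thresholds see [motionThresholds()].
#' @param maxGapFraction tracks missing more than this fraction of frames
#'   within their span are excluded (default 0.2).
#' @param maxLagFraction,maxLag,weighting forwarded to
#'   [timeAveragedMSD()] / [fitMSD()].
#' @param sharedSigma estimate one localization error per cohort (two-pass
#'   fit, default) instead of per trajectory.
#' @return list with elements:
#'   `summary` (data.frame: condition, class, n, fraction; fractions sum
#'   to 1 over analyzed trajectories within each condition),
#'   `counts` (data.frame of input/analyzed/excluded tallies),
#'   `fits` (per-analyzed-trajectory data.frame with D, alpha, sigmaErr,
#'   class), and `cohortSigma` (the shared estimate, NA when
#'   `sharedSigma = FALSE`).
#' @export
summarizeCohort <- function(trajectories, conditions = NULL,
                            thresholds = motionThresholds(),
                            maxGapFraction = 0.2, maxLagFraction = 0.05,
                            maxLag = 50L,
                            weighting = c("none", "npairs"),
                            sharedSigma = TRUE) {
  weighting <- match.arg(weighting)
  stopifnot(is.list(trajectories), length(trajectories) >= 1L)
  if (is.null(conditions)) conditions <- rep("pooled", length(trajectories))
  stopifnot(length(conditions) == length(trajectories))

  # first pass over all conditions: curves, filters and free-sigma fits
  keep <- logical(length(trajectories))
  shortMask <- logical(length(trajectories))
  gapMask <- logical(length(trajectories))
  curves <- vector("list", length(trajectories))
  freeFits <- vector("list", length(trajectories))
  for (i in seq_along(trajectories)) {
    tr <- trajectories[[i]]
    if (nFrames(tr) < thresholds$minFrames) { shortMask[i] <- TRUE; next }
    if (gapFraction(tr) > maxGapFraction) { gapMask[i] <- TRUE; next }
    curves[[i]] <- timeAveragedMSD(tr, maxLagFraction, maxLag,
                                   minLags = 5L)
    freeFits[[i]] <- fitMSD(curves[[i]], weighting = weighting,
                            nFramesUsed = nFrames(tr))
    keep[i] <- TRUE
  }
  cohortSigma <- NA_real_
  if (sharedSigma && any(keep)) {
    sigmas <- vapply(freeFits[keep], function(f)
      if (f@converged) f@sigmaErr else NA_real_, numeric(1L))
    if (any(!is.na(sigmas))) {
      cohortSigma <- stats::median(sigmas, na.rm = TRUE)
      for (i in which(keep))
        freeFits[[i]] <- fitMSD(curves[[i]], weighting = weighting,
                                fixSigma = cohortSigma,
                                nFramesUsed = freeFits[[i]]@nFramesUsed)
    }
  }

  rows <- list()
  counts <- list()
  fitsList <- list()
  for (cond in unique(conditions)) {
    inCond <- conditions == cond
    trs <- trajectories[inCond]
    nShort <- sum(shortMask[inCond])
    nGapped <- sum(gapMask[inCond])
    fitsAllCond <- freeFits[inCond & keep]
    convMask <- vapply(fitsAllCond, slot, logical(1L), "converged")
    nNonConverged <- sum(!convMask)
    fits <- fitsAllCond[convMask]
    if (length(fits) == 0L)
      stop("condition '", cond, "': every trajectory was excluded (",
           nShort, " short, ", nGapped, " gapped, ", nNonConverged,
           " non-converged)")
    cls <- vapply(fits, classifyMotion, character(1L),
                  thresholds = thresholds)
    tab <- table(factor(cls, levels = motionClasses()))
    rows[[cond]] <- data.frame(
      condition = cond, class = names(tab), n = as.integer(tab),
      fraction = as.numeric(tab) / length(cls), row.names = NULL)
    counts[[cond]] <- data.frame(
      condition = cond, nInput = length(trs), nAnalyzed = length(cls),
      nShort = nShort, nGapped = nGapped, nNonConverged = nNonConverged)
    fitsList[[cond]] <- data.frame(
      condition = cond,
      D = vapply(fits, slot, numeric(1L), "D"),
      alpha = vapply(fits, slot, numeric(1L), "alpha"),
      sigmaErr = vapply(fits, slot, numeric(1L), "sigmaErr"),
      nFramesUsed = vapply(fits, slot, integer(1L), "nFramesUsed"),
      class = cls)
  }
  out <- list(summary = do.call(rbind, rows),
              counts = do.call(rbind, counts),
              fits = do.call(rbind, fitsList),
              cohortSigma = cohortSigma)
  rownames(out$summary) <- rownames(out$counts) <- rownames(out$fits) <- NULL
  out
}
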