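# Plate-reader pharmacology shared by the clustering, internalization,
# binding and signaling readouts: ratiometric kinetic traces, baseline
# normalization, AUC responses, logistic dose-response fits, saturation
# and kinetic binding fits, and the membrane-profile internalization
# readout.

#' Four-parameter logistic model
#'
#' `y = bottom + (top - bottom) / (1 + 10^((logEC50 - log10(dose)) * hill))`.
#' Vehicle (dose 0) evaluates to `bottom`, its log-axis limit.
#'
#' @param dose concentrations in M (>= 0).
#' @param bottom,top,logEC50,hill model parameters.
#' @return predicted responses.
#' @export
logisticModel <- function(dose, bottom, top, logEC50, hill = 1) {
  y <- rep(bottom, length(dose))
  pos <- dose > 0
  y[pos] <- bottom + (top - bottom) /
    (1 + 10^((logEC50 - log10(dose[pos])) * hill))
  y
}

#' Mono-exponential association binding model
#'
#' Specific binding at ligand concentration L:
#' `Y(t) = Bmax * L / (L + koff/kon) * (1 - exp(-(kon * L + koff) * t))`,
#' i.e. observed rate `kobs = kon * L + koff` and equilibrium plateau at
#' the one-site occupancy.
#'
#' @param time seconds.
#' @param conc ligand concentration in M (recycled against `time`).
#' @param kon,koff,bmax model parameters.
#' @return predicted specific binding.
#' @export
associationModel <- function(time, conc, kon, koff, bmax) {
  kobs <- kon * conc + koff
  plateau <- if (kon > 0) bmax * conc / (conc + koff / kon) else 0 * conc
  plateau * (1 - exp(-kobs * time))
}

#' Blank-subtracted ratiometric trace
#'
#' `r(t) = (num(t) - blank_num) / (den(t) - blank_den)` for a channel
#' pair of a kinetic trace, e.g. 665/616 (receptor clustering TR-FRET),
#' 620/520 (internalization by DERET), 520/620 (ligand binding) or
#' 535/485 (FRET biosensors).
#'
#' @param trace a [KineticTrace-class].
#' @param numerator,denominator channel wavelengths in nm.
#' @return numeric ratio series aligned with `traceTimes(trace)`.
#' @export
ratiometricTrace <- function(trace, numerator, denominator) {
  stopifnot(is(trace, "KineticTrace"))
  num <- channelSignal(trace, numerator)
  den <- channelSignal(trace, denominator)
  bad <- den == 0
  if (any(bad))
    stop("blank-subtracted denominator channel is zero at t = ",
         paste(signif(traceTimes(trace)[bad], 4L), collapse = ", "),
         " s; ratio undefined")
  num / den
}

#' Normalize a series to its pre-stimulation baseline
#'
#' Divides the series by the mean of the points whose times fall inside
#' the baseline window, turning responses into fold change from baseline
#' (1 = no change). The baseline mean is stored as an attribute.
#'
#' @param times time stamps (s).
#' @param series response values aligned with `times`.
#' @param baselineWindow `c(t0, tStim)`; at least 2 points must fall in
#'   it.
#' @return the normalized series with attribute `baselineMean`.
#' @export
normalizeToBaseline <- function(times, series, baselineWindow) {
  stopifnot(length(times) == length(series), length(baselineWindow) == 2L)
  inBase <- times >= baselineWindow[1L] & times <= baselineWindow[2L]
  if (sum(inBase) < 2L)
    stop("baseline window contains fewer than 2 points")
  b <- mean(series[inBase])
  if (b <= 0)
    stop("baseline mean is not positive; fold-from-baseline undefined")
  out <- series / b
  attr(out, "baselineMean") <- b
  out
}

#' Area under a kinetic response curve
#'
#' Trapezoidal integral of the response over time. In `"above_baseline"`
#' mode the input is a baseline-normalized series and the integrand is
#' `series - 1`, so a flat trace at 1 has zero AUC; `"raw"` integrates
#' the series as given.
#'
#' @param times time stamps (s), >= 2 points.
#' @param series response values.
#' @param mode `"above_baseline"` (default) or `"raw"`.
#' @return scalar AUC (response units x seconds).
#' @export
aucResponse <- function(times, series, mode = c("above_baseline", "raw")) {
  mode <- match.arg(mode)
  stopifnot(length(times) == length(series), length(times) >= 2L)
  y <- if (mode == "above_baseline") series - 1 else series
  pracma::trapz(times, y)
}

#' Fit a logistic dose-response curve
#'
#' Least-squares fit of the [logisticModel()] on the log-dose axis.
#' Four-parameter mode fits bottom, top, logEC50 and hill (hill kept
#' positive by a bound); three-parameter mode fixes hill = 1. Vehicle
#' observations (dose 0) anchor the bottom asymptote rather than being
#' placed on the log axis. Standard errors come from the curvature
#' (Jacobian) at the optimum. A non-monotone dose-response beyond what
#' noise explains triggers a warning, not an error.
#'
#' @param dose concentrations in M (0 allowed for vehicle rows).
#' @param response measured responses aligned with `dose`.
#' @param nParams 3 or 4.
#' @param fixBottom optional numeric to constrain the bottom asymptote
#'   (e.g. 0 for baseline-corrected responses).
#' @return A [DoseResponseFit-class].
#' @examples
#' d <- 10^seq(-11, -7, length.out = 8)
#' y <- logisticModel(d, 0, 100, -9, 1)
#' fitLogistic(d, y)
#' @export
fitLogistic <- function(dose, response, nParams = 4L, fixBottom = NULL) {
  stopifnot(length(dose) == length(response), all(dose >= 0))
  nParams <- .assertCount(nParams, "nParams", 3L)
  if (!nParams %in% c(3L, 4L)) stop("'nParams' must be 3 or 4")
  nFree <- nParams - (!is.null(fixBottom))
  if (length(unique(dose)) < nFree + 1L)
    stop("need at least ", nFree + 1L, " distinct doses for a ", nParams,
         "-parameter fit", if (!is.null(fixBottom)) " (bottom fixed)")
  posDose <- dose[dose > 0]
  b0 <- if (is.null(fixBottom)) min(response) else fixBottom
  t0 <- max(response)
  e0 <- log10(stats::median(posDose))
  # parameter vector: bottom (unless fixed), top, logEC50, hill (4P only)
  build <- function(p) {
    i <- 1L
    bottom <- if (is.null(fixBottom)) { v <- p[i]; i <- i + 1L; v } else fixBottom
    top <- p[i]; i <- i + 1L
    logEC50 <- p[i]; i <- i + 1L
    hill <- if (nParams == 4L) p[i] else 1
    list(bottom = bottom, top = top, logEC50 = logEC50, hill = hill)
  }
  start <- c(if (is.null(fixBottom)) b0, t0, e0, if (nParams == 4L) 1)
  lower <- c(if (is.null(fixBottom)) -Inf, -Inf, -Inf,
             if (nParams == 4L) 1e-3)
  upper <- rep(Inf, length(start))
  resid <- function(p) {
    q <- build(p)
    response - logisticModel(dose, q$bottom, q$top, q$logEC50, q$hill)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid, lower = lower,
                       upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  conv <- !is.null(fit) && fit$info %in% 1:3
  p <- if (is.null(fit)) start else fit$par
  q <- build(p)
  # SEs from the curvature at the optimum
  seNames <- c(if (is.null(fixBottom)) "bottom", "top", "logEC50",
               if (nParams == 4L) "hill")
  se <- rep(NA_real_, length(seNames))
  names(se) <- seNames
  if (conv && length(response) > length(p)) {
    dof <- length(response) - length(p)
    s2 <- fit$deviance / dof
    vc <- tryCatch(s2 * solve(fit$hessian / 2), error = function(e) NULL)
    if (!is.null(vc) && all(diag(vc) >= 0)) se[] <- sqrt(diag(vc))
  }
  seFull <- c(bottom = unname(se["bottom"] %||% NA_real_),
              top = unname(se["top"] %||% NA_real_),
              logEC50 = unname(se["logEC50"] %||% NA_real_),
              hill = if (nParams == 4L) unname(se["hill"]) else NA_real_)
  # flag clearly non-monotone data (beyond 3 residual SDs between
  # adjacent dose means)
  ord <- order(dose)
  mu <- tapply(response[ord], dose[ord], mean)
  if (length(mu) >= 3L) {
    overall <- sign(mu[[length(mu)]] - mu[[1L]])
    reversal <- max(-overall * diff(mu), 0)
    rs <- stats::sd(resid(p))
    if (reversal > 3 * max(rs, .Machine$double.eps))
      warning("dose-response is non-monotone beyond the noise level")
  }
  if (!is.null(fixBottom)) seFull["bottom"] <- NA_real_
  new("DoseResponseFit", logEC50 = q$logEC50, top = q$top,
      bottom = q$bottom, hill = q$hill, nParams = nParams, se = seFull,
      converged = conv)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

#' Fit one-site saturation binding
#'
#' Least-squares fit of `B = Bmax * L / (Kd + L)` (one site, specific
#' binding) with both parameters constrained non-negative.
#'
#' @param conc ligand concentrations in M (>= 3 distinct values spanning
#'   Kd).
#' @param signal specific binding at each concentration.
#' @return A [BindingFit-class] with `mode = "saturation"`. A flat signal
#'   yields `converged = FALSE` (Kd not identifiable).
#' @export
fitSaturationBinding <- function(conc, signal) {
  stopifnot(length(conc) == length(signal), all(conc > 0))
  if (length(unique(conc)) < 3L)
    stop("need at least 3 distinct concentrations")
  if (stats::sd(signal) == 0)
    return(new("BindingFit", kon = NA_real_, koff = NA_real_,
               kd = NA_real_, bmax = signal[1L], mode = "saturation",
               converged = FALSE))
  start <- c(max(signal), stats::median(conc))
  resid <- function(p) signal - p[1L] * conc / (p[2L] + conc)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid, lower = c(0, 0),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  conv <- !is.null(fit) && fit$info %in% 1:3
  p <- if (is.null(fit)) start else fit$par
  new("BindingFit", kon = NA_real_, koff = NA_real_, kd = p[2L],
      bmax = p[1L], mode = "saturation", converged = conv)
}

#' Globally fit association kinetics at two or more ligand concentrations
#'
#' Fits the [associationModel()] jointly across all traces, sharing kon,
#' koff and Bmax ("association kinetics with two or more concentrations
#' of hot ligand"). A single concentration cannot separate kon from koff
#' and is rejected. Kd is derived as koff/kon.
#'
#' @param data data.frame with columns `conc_M`, `time_s`, `signal`
#'   (baseline-subtracted specific binding).
#' @return A [BindingFit-class] with `mode = "kinetic"`.
#' @examples
#' tr <- simulateBindingTraces(seq(0, 3600, 60), c(1e-9, 1e-8),
#'                             kon = 1e6, koff = 1e-3, bmax = 100,
#'                             seed = 1)
#' fitAssociationKinetics(tr)
#' @export
fitAssociationKinetics <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("conc_M", "time_s", "signal") %in% names(data)))
  concs <- sort(unique(data$conc_M))
  if (length(concs) < 2L)
    stop("kon and koff are not separable from a single ligand ",
         "concentration; provide two or more")
  # initialize from per-trace mono-exponential fits: kobs is affine in L
  perTrace <- lapply(concs, function(L) {
    d <- data[data$conc_M == L, ]
    fitOnePhaseAssociation(d$time_s, d$signal)
  })
  kobs <- vapply(perTrace, `[[`, numeric(1L), "rate")
  plateaus <- vapply(perTrace, `[[`, numeric(1L), "plateau")
  lf <- stats::lm(kobs ~ concs)
  kon0 <- max(stats::coef(lf)[[2L]], 1)
  koff0 <- max(stats::coef(lf)[[1L]], 1e-8)
  bmax0 <- max(plateaus) * (max(concs) + koff0 / kon0) / max(concs)
  resid <- function(p)
    data$signal - associationModel(data$time_s, data$conc_M,
                                   p[1L], p[2L], p[3L])
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(kon0, koff0, bmax0), fn = resid,
                       lower = c(0, 0, 0),
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  conv <- !is.null(fit) && fit$info %in% 1:3
  p <- if (is.null(fit)) c(kon0, koff0, bmax0) else fit$par
  kd <- if (p[1L] > 0) p[2L] / p[1L] else NA_real_
  new("BindingFit", kon = p[1L], koff = p[2L], kd = kd, bmax = p[3L],
      mode = "kinetic", converged = conv)
}

#' Fit a one-phase association curve
#'
#' `Y(t) = Y0 + (plateau - Y0) * (1 - exp(-rate * t))`, the standard
#' single-trace association model used e.g. to read plateaus off kinetic
#' Lo/Ld ratio traces.
#'
#' @param time seconds.
#' @param y response.
#' @param y0 fixed starting value (default 0 for baseline-subtracted
#'   data; use 1 for baseline-normalized fold traces).
#' @return list with `plateau`, `rate`, `converged`.
#' @export
fitOnePhaseAssociation <- function(time, y, y0 = 0) {
  stopifnot(length(time) == length(y), length(y) >= 3L)
  plat0 <- y[which.max(time)]
  span0 <- plat0 - y0
  halfIdx <- which(abs(y - (y0 + span0 / 2)) ==
                     min(abs(y - (y0 + span0 / 2))))[1L]
  rate0 <- if (time[halfIdx] > 0) log(2) / time[halfIdx] else 1
  resid <- function(p) y - (y0 + (p[1L] - y0) * (1 - exp(-p[2L] * time)))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(plat0, rate0), fn = resid,
                       lower = c(-Inf, 1e-12),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  conv <- !is.null(fit) && fit$info %in% 1:3
  p <- if (is.null(fit)) c(plat0, rate0) else fit$par
  list(plateau = p[1L], rate = p[2L], converged = conv)
}

#' Surface-signal trace from membrane intensity profiles
#'
#' Implements the time-lapse confocal internalization readout: for each
#' frame, 1D intensity profiles are drawn across the plasma membrane in
#' several segments; the per-segment peak intensities are averaged, the
#' resulting surface-signal series is normalized to its value at time 0,
#' and the response is summarized as AUC. A decaying trace (AUC < 0 in
#' above-baseline mode) indicates internalization.
#'
#' @param profiles list (one element per frame) of lists of numeric 1D
#'   intensity segments (>= 1 segment per frame).
#' @param times frame times in seconds, aligned with `profiles`.
#' @param aucMode forwarded to [aucResponse()].
#' @return list with `times`, `series` (fold of t = 0) and `auc`.
#' @export
membraneProfileSeries <- function(profiles, times,
                                  aucMode = c("above_baseline", "raw")) {
  aucMode <- match.arg(aucMode)
  stopifnot(is.list(profiles), length(profiles) == length(times),
            length(times) >= 2L)
  surface <- vapply(profiles, function(segs) {
    stopifnot(is.list(segs), length(segs) >= 1L)
    mean(vapply(segs, max, numeric(1L)))
  }, numeric(1L))
  if (surface[1L] <= 0)
    stop("surface signal at time 0 is not positive; cannot normalize")
  series <- surface / surface[1L]
  list(times = times, series = series,
       auc = aucResponse(times, series, aucMode))
}
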