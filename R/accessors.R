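#' Construct a Trajectory
#'
#' @param coords two-column matrix or data.frame of x/y positions in
#'   micrometres.
#' @param dt frame interval in seconds.
#' @param frames observed frame indices (0-based). Defaults to contiguous
#'   frames `0:(n-1)`.
#' @return A [Trajectory-class] object.
#' @export
Trajectory <- function(coords, dt, frames = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y")
  if (is.null(frames)) frames <- seq_len(nrow(coords)) - 1L
  new("Trajectory", coords = coords, frames = as.integer(frames),
      dt = as.numeric(dt))
}

#' Construct a PointPattern
#'
#' @param coords two-column matrix of x/y positions in nanometres (may
#'   have zero rows).
#' @param window numeric `c(xmin, ymin, xmax, ymax)` in nanometres.
#' @return A [PointPattern-class] object.
#' @export
PointPattern <- function(coords, window) {
  coords <- as.matrix(coords)
  if (length(coords) == 0L) coords <- matrix(numeric(0), ncol = 2L)
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y")
  new("PointPattern", coords = coords, window = as.numeric(window))
}

#' Construct an EmissionSpectrum
#'
#' @param wavelengths wavelength grid in nm.
#' @param intensity signal per wavelength.
#' @return An [EmissionSpectrum-class] object.
#' @export
EmissionSpectrum <- function(wavelengths, intensity) {
  new("EmissionSpectrum", wavelengths = as.numeric(wavelengths),
      intensity = as.numeric(intensity))
}

#' Construct a KineticTrace
#'
#' @param times acquisition times (s).
#' @param channels matrix of intensities, columns named by emission
#'   wavelength in nm, or a named list of equal-length vectors.
#' @param blanks named per-channel blank values; defaults to 0 for every
#'   channel (already blank-subtracted data).
#' @param baselineWindow `c(t0, tStim)` in seconds; defaults to the full
#'   time range (no stimulation).
#' @param well,condition identifying labels.
#' @return A [KineticTrace-class] object.
#' @export
KineticTrace <- function(times, channels, blanks = NULL,
                         baselineWindow = NULL, well = "well",
                         condition = "condition") {
  if (is.list(channels) && !is.matrix(channels))
    channels <- do.call(cbind, channels)
  channels <- as.matrix(channels)
  storage.mode(channels) <- "double"
  if (is.null(blanks)) {
    blanks <- rep(0, ncol(channels))
    names(blanks) <- colnames(channels)
  }
  if (is.null(baselineWindow)) baselineWindow <- range(times)
  new("KineticTrace", times = as.numeric(times), channels = channels,
      blanks = blanks, baselineWindow = as.numeric(baselineWindow),
      well = well, condition = condition)
}

# ---- generics ---------------------------------------------------------

#' Coordinates of a trajectory or point pattern
#' @param object a [Trajectory-class] or [PointPattern-class].
#' @return numeric matrix with columns `x`, `y`.
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "Trajectory", function(object) object@coords)

#' @rdname coords
#' @export
setMethod("coords", "PointPattern", function(object) object@coords)

#' Observed frame indices of a trajectory (0-based)
#' @param object a [Trajectory-class].
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @rdname frames
#' @export
setMethod("frames", "Trajectory", function(object) object@frames)

#' Frame interval in seconds
#' @param object a [Trajectory-class] or [MSDCurve-class].
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))

#' @rdname frameInterval
#' @export
setMethod("frameInterval", "Trajectory", function(object) object@dt)

#' @rdname frameInterval
#' @export
setMethod("frameInterval", "MSDCurve", function(object) object@dt)

#' Number of observed frames of a trajectory
#' @param object a [Trajectory-class].
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "Trajectory", function(object) nrow(object@coords))

#' Fraction of frames missing within a trajectory's observed span
#'
#' A track observed at frames 0..span with `n` observed frames is missing
#' `1 - n / (span + 1)` of its frames (tracker gap-closing).
#' @param object a [Trajectory-class].
#' @export
setGeneric("gapFraction", function(object) standardGeneric("gapFraction"))

#' @rdname gapFraction
#' @export
setMethod("gapFraction", "Trajectory", function(object) {
  span <- diff(range(object@frames))
  1 - nrow(object@coords) / (span + 1)
})

#' Observation window of a point pattern
#' @param object a [PointPattern-class].
#' @return numeric `c(xmin, ymin, xmax, ymax)` (nm).
#' @export
setGeneric("observationWindow",
           function(object) standardGeneric("observationWindow"))

#' @rdname observationWindow
#' @export
setMethod("observationWindow", "PointPattern", function(object) object@window)

#' Number of points in a pattern
#' @param object a [PointPattern-class].
#' @export
setGeneric("nPoints", function(object) standardGeneric("nPoints"))

#' @rdname nPoints
#' @export
setMethod("nPoints", "PointPattern", function(object) nrow(object@coords))

#' Empirical intensity (points per unit area) of a pattern
#' @param object a [PointPattern-class].
#' @return points per square nanometre.
#' @export
setGeneric("patternIntensity",
           function(object) standardGeneric("patternIntensity"))

#' @rdname patternIntensity
#' @export
setMethod("patternIntensity", "PointPattern", function(object) {
  w <- object@window
  nrow(object@coords) / ((w[3L] - w[1L]) * (w[4L] - w[2L]))
})

#' Wavelength grid of a spectrum
#' @param object an [EmissionSpectrum-class].
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "EmissionSpectrum", function(object)
  object@wavelengths)

#' Signal values of a spectrum
#' @param object an [EmissionSpectrum-class].
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname intensities
#' @export
setMethod("intensities", "EmissionSpectrum", function(object)
  object@intensity)

#' Intensity at a single wavelength
#' @param object an [EmissionSpectrum-class].
#' @param wavelength a wavelength on the grid (nm).
#' @export
setGeneric("intensityAt",
           function(object, wavelength) standardGeneric("intensityAt"))

#' @rdname intensityAt
#' @export
setMethod("intensityAt", "EmissionSpectrum", function(object, wavelength) {
  i <- match(wavelength, object@wavelengths)
  if (is.na(i))
    stop("wavelength ", wavelength, " nm is not on the acquisition grid")
  object@intensity[i]
})

#' Acquisition times of a kinetic trace
#' @param object a [KineticTrace-class].
#' @export
setGeneric("traceTimes", function(object) standardGeneric("traceTimes"))

#' @rdname traceTimes
#' @export
setMethod("traceTimes", "KineticTrace", function(object) object@times)

#' Blank-subtracted intensities of one channel
#' @param object a [KineticTrace-class].
#' @param wavelength channel wavelength in nm (number or name).
#' @export
setGeneric("channelSignal",
           function(object, wavelength) standardGeneric("channelSignal"))

#' @rdname channelSignal
#' @export
setMethod("channelSignal", "KineticTrace", function(object, wavelength) {
  nm <- as.character(wavelength)
  if (!nm %in% colnames(object@channels))
    stop("channel ", nm, " nm not present; available: ",
         paste(colnames(object@channels), collapse = ", "))
  object@channels[, nm] - object@blanks[[nm]]
})

# ---- show methods -----------------------------------------------------

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames (%d..%d), dt = %g s, gap fraction %.1f%%\n",
              nrow(object@coords), min(object@frames), max(object@frames),
              object@dt, 100 * gapFraction(object)))
})

setMethod("show", "MSDCurve", function(object) {
  cat(sprintf("MSDCurve: %d lags (%.3g..%.3g s), msd %.3g..%.3g um^2\n",
              length(object@lags), min(object@times), max(object@times),
              min(object@msd), max(object@msd)))
})

setMethod("show", "MotionFit", function(object) {
  cat(sprintf(
    "MotionFit: D = %.4g um^2 s^-alpha, alpha = %.3f, sigmaErr = %.4g um (%s)\n",
    object@D, object@alpha, object@sigmaErr,
    if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "PointPattern", function(object) {
  w <- object@window
  cat(sprintf("PointPattern: %d points in [%g, %g] x [%g, %g] nm (lambda = %.3g nm^-2)\n",
              nrow(object@coords), w[1L], w[3L], w[2L], w[4L],
              patternIntensity(object)))
})

setMethod("show", "EmissionSpectrum", function(object) {
  cat(sprintf("EmissionSpectrum: %d wavelengths, %g..%g nm\n",
              length(object@wavelengths), min(object@wavelengths),
              max(object@wavelengths)))
})

setMethod("show", "KineticTrace", function(object) {
  cat(sprintf("KineticTrace [%s/%s]: %d time points, channels %s nm, baseline [%g, %g] s\n",
              object@well, object@condition, length(object@times),
              paste(colnames(object@channels), collapse = "/"),
              object@baselineWindow[1L], object@baselineWindow[2L]))
})

setMethod("show", "DoseResponseFit", function(object) {
  cat(sprintf(
    "%d-parameter logistic fit: logEC50 = %.3f, top = %.3g, bottom = %.3g, hill = %.3g (%s)\n",
    object@nParams, object@logEC50, object@top, object@bottom, object@hill,
    if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "BindingFit", function(object) {
  if (object@mode == "kinetic")
    cat(sprintf(
      "Kinetic binding fit: kon = %.3g M^-1 s^-1, koff = %.3g s^-1, Kd = %.3g M, Bmax = %.3g\n",
      object@kon, object@koff, object@kd, object@bmax))
  else
    cat(sprintf("Saturation binding fit: Kd = %.3g M, Bmax = %.3g\n",
                object@kd, object@bmax))
})

setMethod("show", "BiasEstimate", function(object) {
  cat(sprintf(
    "BiasEstimate (reference agonist %s; delta = reference pathway %s minus test pathway %s):\n",
    object@referenceAgonist, object@referencePathway, object@testPathway))
  print(object@summary, row.names = FALSE)
})
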