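#' @import methods
NULL

#' Single-molecule trajectory
#'
#' Time-ordered 2D positions of one tracked molecule. Coordinates are stored
#' in micrometres; `frames` holds the (0-based) observed frame indices so
#' that gapped tracks (tracker gap-closing) are represented without
#' interpolation. The time of frame *i* is `i * dt` seconds.
#'
#' @slot coords numeric matrix with columns `x`, `y` (micrometres).
#' @slot frames integer vector of observed frame indices, strictly
#'   increasing, 0-based.
#' @slot dt frame interval in seconds.
#' @exportClass Trajectory
setClass("Trajectory",
  representation(coords = "matrix", frames = "integer", dt = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@coords) || ncol(object@coords) != 2L)
      msg <- c(msg, "'coords' must be a numeric matrix with two columns")
    if (nrow(object@coords) < 2L)
      msg <- c(msg, "a trajectory needs at least 2 observed frames")
    if (any(!is.finite(object@coords)))
      msg <- c(msg, "coordinates must be finite")
    if (length(object@frames) != nrow(object@coords))
      msg <- c(msg, "'frames' must align with coordinate rows")
    if (length(object@frames) > 1L && any(diff(object@frames) <= 0L))
      msg <- c(msg, "'frames' must be strictly increasing")
    if (length(object@frames) && any(object@frames < 0L))
      msg <- c(msg, "'frames' must be non-negative")
    if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
      msg <- c(msg, "'dt' must be a single positive number")
    if (length(msg)) msg else TRUE
  }
)

#' Time-averaged MSD curve
#'
#' TA-MSD of a single trajectory as a function of time lag, together with
#' the number of displacement pairs that entered each lag (pairs drop out
#' at long lags and wherever the track is gapped).
#'
#' @slot lags positive integer frame lags.
#' @slot times lag times in seconds (`lags * dt`).
#' @slot msd mean squared displacement per lag (square micrometres).
#' @slot nPairs number of displacement pairs averaged at each lag.
#' @slot dt frame interval in seconds.
#' @exportClass MSDCurve
setClass("MSDCurve",
  representation(lags = "integer", times = "numeric", msd = "numeric",
                 nPairs = "integer", dt = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@lags)
    if (length(object@times) != n || length(object@msd) != n ||
        length(object@nPairs) != n)
      msg <- c(msg, "lags, times, msd and nPairs must have equal length")
    if (n == 0L) msg <- c(msg, "empty MSD curve")
    if (any(object@msd < 0)) msg <- c(msg, "msd values must be non-negative")
    if (any(object@nPairs < 1L))
      msg <- c(msg, "every reported lag needs at least one pair")
    if (length(msg)) msg else TRUE
  }
)

#' Fitted anomalous-diffusion model for one trajectory
#'
#' Parameters of the power-law model MSD(t) = 4 D t^alpha + 4 sigmaErr^2:
#' generalized diffusion coefficient `D` (um^2 s^-alpha), anomalous
#' diffusion exponent `alpha`, and static localization-error SD `sigmaErr`
#' (um), plus fit diagnostics.
#'
#' @slot D generalized diffusion coefficient, >= 0.
#' @slot alpha anomalous diffusion exponent in [0, 2].
#' @slot sigmaErr localization error SD (um), >= 0.
#' @slot residualNorm residual sum of squares at the optimum.
#' @slot converged logical convergence flag (honest: non-converged fits are
#'   excluded from cohort summaries, never coerced).
#' @slot nFramesUsed number of observed frames in the fitted trajectory.
#' @exportClass MotionFit
setClass("MotionFit",
  representation(D = "numeric", alpha = "numeric", sigmaErr = "numeric",
                 residualNorm = "numeric", converged = "logical",
                 nFramesUsed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@D < 0) msg <- c(msg, "'D' must be >= 0")
    if (object@alpha < 0 || object@alpha > 2)
      msg <- c(msg, "'alpha' must lie in [0, 2]")
    if (object@sigmaErr < 0) msg <- c(msg, "'sigmaErr' must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' 2D spatial point pattern
#'
#' A set of points (nanometres) within a rectangular observation window,
#' as obtained from EM gold-particle maps or PALM localization tables.
#'
#' @slot coords numeric matrix with columns `x`, `y` (nm).
#' @slot window numeric vector `c(xmin, ymin, xmax, ymax)` (nm).
#' @exportClass PointPattern
setClass("PointPattern",
  representation(coords = "matrix", window = "numeric"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@coords) != 2L)
      msg <- c(msg, "'coords' must have two columns")
    w <- object@window
    if (length(w) != 4L || any(!is.finite(w)))
      msg <- c(msg, "'window' must be c(xmin, ymin, xmax, ymax)")
    else {
      if (w[3L] <= w[1L] || w[4L] <= w[2L])
        msg <- c(msg, "'window' must have positive area")
      if (nrow(object@coords) &&
          (any(object@coords[, 1L] < w[1L] - 1e-9) ||
           any(object@coords[, 1L] > w[3L] + 1e-9) ||
           any(object@coords[, 2L] < w[2L] - 1e-9) ||
           any(object@coords[, 2L] > w[4L] + 1e-9)))
        msg <- c(msg, "points must lie inside the window")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Emission spectrum
#'
#' Wavelength-indexed plate-reader signal (one read of one well). The
#' standard acquisition grid is 460-650 nm in 5-nm steps. Intensities may
#' be negative after blank subtraction; they are retained, not clipped.
#'
#' @slot wavelengths strictly increasing wavelength grid (nm).
#' @slot intensity signal per wavelength (arbitrary units).
#' @exportClass EmissionSpectrum
setClass("EmissionSpectrum",
  representation(wavelengths = "numeric", intensity = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@wavelengths) != length(object@intensity))
      msg <- c(msg, "wavelengths and intensity must align")
    if (length(object@wavelengths) > 1L && any(diff(object@wavelengths) <= 0))
      msg <- c(msg, "wavelength grid must be strictly increasing")
    if (any(!is.finite(object@wavelengths)))
      msg <- c(msg, "wavelengths must be finite")
    if (length(msg)) msg else TRUE
  }
)

#' Multi-channel kinetic plate-reader trace
#'
#' Time-indexed intensities for one well at one or more emission
#' wavelengths, with per-channel blanks and a baseline window preceding
#' stimulation.
#'
#' @slot times acquisition times in seconds, non-decreasing.
#' @slot channels numeric matrix, one column per emission wavelength;
#'   column names are wavelengths in nm (e.g. `"570"`).
#' @slot blanks named numeric vector of per-channel blank values (same
#'   names as `channels` columns); zero when already blank-subtracted.
#' @slot baselineWindow numeric `c(t0, tStim)` delimiting the pre-stimulation
#'   baseline (seconds).
#' @slot well well identifier.
#' @slot condition condition label.
#' @exportClass KineticTrace
setClass("KineticTrace",
  representation(times = "numeric", channels = "matrix", blanks = "numeric",
                 baselineWindow = "numeric", well = "character",
                 condition = "character"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@channels) != length(object@times))
      msg <- c(msg, "channel rows must align with times")
    if (is.null(colnames(object@channels)))
      msg <- c(msg, "channel columns must be named by wavelength (nm)")
    if (length(object@times) > 1L && any(diff(object@times) < 0))
      msg <- c(msg, "times must be non-decreasing")
    if (length(object@baselineWindow) != 2L ||
        object@baselineWindow[2L] < object@baselineWindow[1L])
      msg <- c(msg, "'baselineWindow' must be c(t0, tStim) with t0 <= tStim")
    if (!all(colnames(object@channels) %in% names(object@blanks)))
      msg <- c(msg, "every channel needs a blank entry")
    if (length(msg)) msg else TRUE
  }
)

#' Logistic dose-response fit
#'
#' Parameters of the three- or four-parameter logistic model
#' y = bottom + (top - bottom) / (1 + 10^((logEC50 - log10(dose)) * hill)).
#' Three-parameter mode fixes hill = 1.
#'
#' @slot logEC50 log10 molar potency.
#' @slot top,bottom response asymptotes (top is the Emax plateau).
#' @slot hill Hill slope (> 0).
#' @slot nParams 3L or 4L.
#' @slot se named numeric vector of standard errors (curvature at the
#'   optimum); `NA` where a parameter was fixed.
#' @slot converged logical convergence flag.
#' @exportClass DoseResponseFit
setClass("DoseResponseFit",
  representation(logEC50 = "numeric", top = "numeric", bottom = "numeric",
                 hill = "numeric", nParams = "integer", se = "numeric",
                 converged = "logical"),
  validity = function(object) {
    msg <- character()
    if (!object@nParams %in% c(3L, 4L))
      msg <- c(msg, "'nParams' must be 3 or 4")
    if (is.finite(object@hill) && object@hill <= 0)
      msg <- c(msg, "'hill' must be positive")
    if (length(msg)) msg else TRUE
  }
)

#' Receptor binding fit
#'
#' Either an equilibrium saturation fit (one-site specific binding,
#' B = Bmax * L / (Kd + L)) or a global kinetic fit across two or more
#' ligand concentrations (Y_L(t) = Beq(L) * (1 - exp(-(kon*L + koff) t)),
#' Kd = koff / kon).
#'
#' @slot kon association rate constant (M^-1 s^-1); `NA` in saturation mode.
#' @slot koff dissociation rate constant (s^-1); `NA` in saturation mode.
#' @slot kd equilibrium dissociation constant (M).
#' @slot bmax maximal specific binding (response units).
#' @slot mode `"kinetic"` or `"saturation"`.
#' @slot converged logical convergence / identifiability flag.
#' @exportClass BindingFit
setClass("BindingFit",
  representation(kon = "numeric", koff = "numeric", kd = "numeric",
                 bmax = "numeric", mode = "character", converged = "logical"),
  validity = function(object) {
    msg <- character()
    if (!object@mode %in% c("kinetic", "saturation"))
      msg <- c(msg, "'mode' must be 'kinetic' or 'saturation'")
    for (s in c("kon", "koff", "kd", "bmax")) {
      v <- slot(object, s)
      if (is.finite(v) && v < 0) msg <- c(msg, paste0("'", s, "' must be >= 0"))
    }
    if (object@mode == "kinetic" && is.finite(object@kon) &&
        is.finite(object@koff) && object@kon > 0 &&
        abs(object@kd - object@koff / object@kon) >
          1e-8 * max(object@kd, .Machine$double.eps))
      msg <- c(msg, "kinetic mode requires kd == koff / kon")
    if (length(msg)) msg else TRUE
  }
)

#' Ligand-bias ledger
#'
#' Experiment-wise normalized potency estimates. Within each experiment,
#' `deltaLogEC50(agonist, pathway)` is the reference agonist's logEC50
#' minus the test agonist's logEC50 in that pathway; the bias estimate
#' `deltaDeltaLogEC50(agonist)` subtracts the test pathway's delta from
#' the reference pathway's delta. The reference agonist is identically
#' zero in every pathway.
#'
#' @slot perExperiment data.frame with columns `experiment`, `agonist`,
#'   `pathway`, `deltaLogEC50` and (per agonist/experiment)
#'   `deltaDeltaLogEC50`.
#' @slot summary data.frame of mean and SEM over experiments per agonist.
#' @slot referenceAgonist,referencePathway,testPathway character labels.
#' @exportClass BiasEstimate
setClass("BiasEstimate",
  representation(perExperiment = "data.frame", summary = "data.frame",
                 referenceAgonist = "character",
                 referencePathway = "character", testPathway = "character"))
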