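# Plate-reader signal generators: emission spectra with tunable
# liquid-ordered / liquid-disordered sensitized-emission weights, kinetic
# two-channel traces, logistic dose-response tables and association
# binding traces. Noise-free outputs lie exactly on the generating model,
# which is what lets the downstream fits be tested for exactness.

#' Standard emission acquisition grid
#'
#' 460-650 nm in 5-nm steps, the spectral-scan grid used throughout the
#' package (39 wavelengths).
#' @return numeric vector of wavelengths (nm).
#' @export
emissionGrid <- function() seq(460, 650, by = 5)

# terbium-donor-like line spectrum: dominant 490-nm line plus minor lines;
# values chosen so the reference wavelength (490 nm) carries strong signal
.donorShape <- function(wl) {
  dnorm(wl, 490, 6) + 0.6 * dnorm(wl, 545, 6) +
    0.25 * dnorm(wl, 585, 6) + 0.15 * dnorm(wl, 620, 6)
}

# sensitized-emission components: Lo-band peak at 570 nm, Ld-band peak at
# 610 nm, both 8-nm SD (narrow enough that each peak sits essentially
# inside its band and the 5-nm trapezoid split matches the analytic one
# to < 0.1%)
.sensitizedShape <- function(wl, loWeight, peakSd = 8) {
  loWeight * dnorm(wl, 570, peakSd) + (1 - loWeight) * dnorm(wl, 610, peakSd)
}

#' Analytic liquid-ordered band fraction of the synthetic spectrum
#'
#' Closed-form counterpart of [loLdFractions()] for spectra generated by
#' [simulateSpectrum()]: the exact integral split of the two Gaussian
#' sensitized-emission components over the 530-590 / 590-650 nm bands.
#'
#' @param loWeight weight of the liquid-ordered component in `[0, 1]`.
#' @param peakSd sensitized-emission peak SD in nm.
#' @return the expected Lo fraction.
#' @export
analyticLoFraction <- function(loWeight, peakSd = 8) {
  bandMass <- function(mu, lo, hi) pnorm(hi, mu, peakSd) - pnorm(lo, mu, peakSd)
  lo <- loWeight * bandMass(570, 530, 590) +
    (1 - loWeight) * bandMass(610, 530, 590)
  ld <- loWeight * bandMass(570, 590, 650) +
    (1 - loWeight) * bandMass(610, 590, 650)
  lo / (lo + ld)
}

#' Simulate a donor-only and probe-loaded emission spectrum pair
#'
#' The donor-only spectrum is a lanthanide-like line spectrum with its
#' dominant line at the 490-nm reference wavelength. The probe-loaded
#' spectrum adds sensitized emission split between a liquid-ordered
#' component (570-nm peak) and a liquid-disordered component (610-nm
#' peak) with weights `loWeight` and `1 - loWeight`, plus iid Gaussian
#' noise. Both spectra share the 460-650 nm, 5-nm grid.
#'
#' @param loWeight fraction of sensitized emission in the liquid-ordered
#'   component, in `[0, 1]`.
#' @param amplitude total sensitized-emission amplitude relative to the
#'   donor 490-nm line (0 gives a probe-free well).
#' @param noiseSd additive Gaussian noise SD (signal units).
#' @param seed integer seed.
#' @param donorLevel peak donor signal at 490 nm (signal units).
#' @return list with elements `donorOnly` and `sample`, both
#'   [EmissionSpectrum-class].
#' @examples
#' sp <- simulateSpectrum(loWeight = 0.7, amplitude = 0.5, noiseSd = 0,
#'                        seed = 1)
#' sp$sample
#' @export
simulateSpectrum <- function(loWeight, amplitude, noiseSd = 0, seed,
                             donorLevel = 1000) {
  .assertNumber(loWeight, "loWeight", 0, 1)
  .assertNumber(amplitude, "amplitude", lower = 0)
  .assertNumber(noiseSd, "noiseSd", lower = 0)
  wl <- emissionGrid()
  donorBase <- .donorShape(wl) / .donorShape(490) * donorLevel
  sens <- amplitude * donorLevel * .sensitizedShape(wl, loWeight) /
    dnorm(570, 570, 8)
  .withSeed(seed, {
    donor <- donorBase + stats::rnorm(length(wl), sd = noiseSd)
    sample <- donorBase + sens + stats::rnorm(length(wl), sd = noiseSd)
    list(donorOnly = EmissionSpectrum(wl, donor),
         sample = EmissionSpectrum(wl, sample))
  })
}

#' Simulate a multi-channel kinetic plate-reader trace
#'
#' Each channel holds a constant baseline level until `tStim`, then an
#' agonist-driven mono-exponential change
#' `baseline * (1 + foldChange_effect * (1 - exp(-rate (t - tStim))))`
#' toward `baseline * (1 + amplitude)`, plus iid Gaussian noise and a
#' per-channel blank offset. With `noiseSd = 0` the trace lies exactly on
#' this model.
#'
#' @param times acquisition times in seconds.
#' @param channels named list: one entry per emission wavelength (name =
#'   nm), each a list with `baseline` (signal units), `amplitude`
#'   (fractional plateau change; 0 for an unresponsive channel) and `rate`
#'   (s^-1).
#' @param tStim stimulation time (s); times `< tStim` form the baseline
#'   window.
#' @param blanks named per-channel blank offsets added to the signal
#'   (default 0).
#' @param noiseSd additive Gaussian noise SD.
#' @param seed integer seed.
#' @param well,condition labels.
#' @return A [KineticTrace-class] with `baselineWindow = c(min(times), tStim)`.
#' @export
simulateKineticTrace <- function(times, channels, tStim, blanks = NULL,
                                 noiseSd = 0, seed, well = "sim",
                                 condition = "synthetic") {
  .assertNumber(noiseSd, "noiseSd", lower = 0)
  .assertNumber(tStim, "tStim", lower = min(times), upper = max(times))
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)))
  if (is.null(blanks)) {
    blanks <- rep(0, length(channels))
    names(blanks) <- names(channels)
  }
  .withSeed(seed, {
    mat <- vapply(names(channels), function(nm) {
      ch <- channels[[nm]]
      rise <- ifelse(times < tStim, 0,
                     1 - exp(-ch$rate * (times - tStim)))
      clean <- ch$baseline * (1 + ch$amplitude * rise)
      clean + blanks[[nm]] + stats::rnorm(length(times), sd = noiseSd)
    }, numeric(length(times)))
    KineticTrace(times, mat, blanks = blanks,
                 baselineWindow = c(min(times), tStim), well = well,
                 condition = condition)
  })
}

#' Simulate a logistic dose-response table
#'
#' Responses follow the four-parameter logistic model exactly (see
#' [fitLogistic()]) with additive Gaussian noise per replicate.
#'
#' @param doses agonist concentrations in M, all > 0 (dose 0 may be added
#'   by the caller as a vehicle row).
#' @param bottom,top,logEC50,hill generating 4PL parameters.
#' @param noiseSd additive response noise SD.
#' @param nReplicates replicates per dose.
#' @param seed integer seed.
#' @return data.frame with columns `dose_M`, `replicate`, `response`.
#' @export
simulateDoseResponse <- function(doses, bottom = 0, top = 100,
                                 logEC50 = -9, hill = 1, noiseSd = 0,
                                 nReplicates = 1L, seed) {
  if (any(doses <= 0)) stop("'doses' must be positive (molar)")
  .assertNumber(noiseSd, "noiseSd", lower = 0)
  nReplicates <- .assertCount(nReplicates, "nReplicates")
  grid <- expand.grid(replicate = seq_len(nReplicates), dose_M = doses)
  mu <- logisticModel(grid$dose_M, bottom, top, logEC50, hill)
  .withSeed(seed, data.frame(
    dose_M = grid$dose_M, replicate = grid$replicate,
    response = mu + stats::rnorm(nrow(grid), sd = noiseSd)))
}

#' Simulate ligand-association binding traces
#'
#' Specific binding at ligand concentration L follows the
#' mono-exponential association model with observed rate
#' `kobs = kon * L + koff` and equilibrium plateau
#' `bmax * L / (L + koff/kon)` (see [fitAssociationKinetics()]), plus
#' additive Gaussian noise.
#'
#' @param times acquisition times in seconds.
#' @param concentrations ligand concentrations in M (>= 1).
#' @param kon association rate constant, M^-1 s^-1.
#' @param koff dissociation rate constant, s^-1.
#' @param bmax maximal binding (response units).
#' @param noiseSd additive noise SD.
#' @param seed integer seed.
#' @return data.frame with columns `conc_M`, `time_s`, `signal`.
#' @export
simulateBindingTraces <- function(times, concentrations, kon, koff, bmax,
                                  noiseSd = 0, seed) {
  if (any(concentrations <= 0)) stop("'concentrations' must be positive")
  .assertNumber(kon, "kon", lower = 0)
  .assertNumber(koff, "koff", lower = 0)
  .assertNumber(bmax, "bmax", lower = 0)
  .assertNumber(noiseSd, "noiseSd", lower = 0)
  grid <- expand.grid(time_s = times, conc_M = concentrations)
  mu <- associationModel(grid$time_s, grid$conc_M, kon, koff, bmax)
  .withSeed(seed, data.frame(
    conc_M = grid$conc_M, time_s = grid$time_s,
    signal = mu + stats::rnorm(nrow(grid), sd = noiseSd)))
}
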