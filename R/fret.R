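# Solvatochromic-probe TR-FRET spectral analysis: isolating the
# probe-specific sensitized emission by 490-nm ratiometric normalization
# and donor-only subtraction, then splitting it into liquid-ordered
# (530-590 nm) and liquid-disordered (590-650 nm) band fractions, or
# expressing the increases at the 570-nm and 610-nm marker wavelengths
# ratiometrically.

#' Spectral band definitions
#'
#' @param refWavelength donor reference line used for ratiometric
#'   normalization (490 nm).
#' @param loBand liquid-ordered band, nm (530-590).
#' @param ldBand liquid-disordered band, nm (590-650); must start where
#'   the Lo band ends so the two trapezoid integrals tile 530-650 without
#'   double counting.
#' @param loPoint,ldPoint marker wavelengths for the point-ratio readout
#'   (570 and 610 nm); each must lie inside its band.
#' @return validated band list.
#' @export
spectralBands <- function(refWavelength = 490, loBand = c(530, 590),
                          ldBand = c(590, 650), loPoint = 570,
                          ldPoint = 610) {
  stopifnot(length(loBand) == 2L, length(ldBand) == 2L,
            loBand[1L] < loBand[2L], ldBand[1L] < ldBand[2L])
  if (loBand[2L] != ldBand[1L])
    stop("Lo and Ld bands must be contiguous (shared boundary)")
  if (loPoint < loBand[1L] || loPoint > loBand[2L])
    stop("'loPoint' must lie inside the Lo band")
  if (ldPoint < ldBand[1L] || ldPoint > ldBand[2L])
    stop("'ldPoint' must lie inside the Ld band")
  list(refWavelength = refWavelength, loBand = loBand, ldBand = ldBand,
       loPoint = loPoint, ldPoint = ldPoint)
}

.checkSharedGrid <- function(a, b) {
  if (!isTRUE(all.equal(wavelengths(a), wavelengths(b))))
    stop("spectra must share the same wavelength grid")
}

#' Probe-specific TR-FRET difference spectrum
#'
#' Each spectrum (already blank-subtracted) is ratiometrically normalized
#' to its own signal at the reference wavelength; the normalized
#' donor-only read is then subtracted from the normalized probe-loaded
#' read, isolating the probe-specific sensitized emission. The output is
#' zero at the reference wavelength by construction and invariant to
#' rescaling either input.
#'
#' @param donorOnly donor-only [EmissionSpectrum-class].
#' @param withProbe probe-loaded [EmissionSpectrum-class] on the same
#'   grid.
#' @param bands see [spectralBands()].
#' @return An [EmissionSpectrum-class] difference spectrum.
#' @examples
#' sp <- simulateSpectrum(0.7, amplitude = 0.5, noiseSd = 0, seed = 1)
#' nr12sFretSpectrum(sp$donorOnly, sp$sample)
#' @export
nr12sFretSpectrum <- function(donorOnly, withProbe,
                              bands = spectralBands()) {
  stopifnot(is(donorOnly, "EmissionSpectrum"),
            is(withProbe, "EmissionSpectrum"))
  .checkSharedGrid(donorOnly, withProbe)
  refD <- intensityAt(donorOnly, bands$refWavelength)
  refP <- intensityAt(withProbe, bands$refWavelength)
  if (refD <= 0 || refP <= 0)
    stop("signal at the ", bands$refWavelength,
         "-nm reference must be positive in both spectra; ",
         "normalization is undefined")
  EmissionSpectrum(wavelengths(donorOnly),
                   intensities(withProbe) / refP -
                     intensities(donorOnly) / refD)
}

.bandAUC <- function(spectrum, band) {
  wl <- wavelengths(spectrum)
  sel <- wl >= band[1L] & wl <= band[2L]
  if (sum(sel) < 2L || !band[1L] %in% wl || !band[2L] %in% wl)
    stop("wavelength grid must cover the band ", band[1L], "-", band[2L],
         " nm including its endpoints")
  pracma::trapz(wl[sel], intensities(spectrum)[sel])
}

#' Liquid-ordered / liquid-disordered band fractions
#'
#' Trapezoidal AUC of the probe-specific spectrum over the Lo band and
#' the Ld band, each expressed relative to the total AUC over their
#' union. The shared boundary wavelength terminates the Lo trapezoid and
#' starts the Ld trapezoid, so no mass is double-counted and the two
#' fractions sum to 1 exactly. Integration stays on the native
#' acquisition grid (no interpolation). Negative post-subtraction
#' intensities are retained, so fractions can fall outside `[0, 1]` on
#' pathological inputs; this is flagged with a warning, never truncated.
#'
#' @param fretSpectrum probe-specific [EmissionSpectrum-class] (output of
#'   [nr12sFretSpectrum()]).
#' @param bands see [spectralBands()].
#' @return named numeric `c(lo = , ld = )`.
#' @export
loLdFractions <- function(fretSpectrum, bands = spectralBands()) {
  stopifnot(is(fretSpectrum, "EmissionSpectrum"))
  lo <- .bandAUC(fretSpectrum, bands$loBand)
  ld <- .bandAUC(fretSpectrum, bands$ldBand)
  total <- lo + ld
  if (total <= 0)
    stop("total band AUC is not positive; fractions are undefined")
  out <- c(lo = lo / total, ld = ld / total)
  if (any(out < 0) || any(out > 1))
    warning("band fractions fall outside [0, 1] ",
            "(negative intensities dominate one band); retained unclipped")
  out
}

#' Ratio of probe-specific increases at the Lo and Ld marker wavelengths
#'
#' The agonist-induced increase of the probe-specific spectrum is read at
#' the liquid-ordered marker (570 nm) and the liquid-disordered marker
#' (610 nm) and expressed as their ratio; values above 1 indicate
#' preferential movement into the ordered phase.
#'
#' @param before,after probe-specific [EmissionSpectrum-class] reads
#'   (before and after agonist) on the same grid.
#' @param bands see [spectralBands()].
#' @param ldFloor smallest |increase| at the Ld marker for which the
#'   ratio is considered defined; below it an error is raised.
#' @return list with `ratio`, `deltaLo`, `deltaLd` and `ldNearFloor`
#'   (TRUE when the Ld increase is within 1000x machine precision of the
#'   floor, i.e. the ratio is dominated by the Lo term).
#' @export
loLdPointRatio <- function(before, after, bands = spectralBands(),
                           ldFloor = .Machine$double.eps) {
  stopifnot(is(before, "EmissionSpectrum"), is(after, "EmissionSpectrum"))
  .checkSharedGrid(before, after)
  dLo <- intensityAt(after, bands$loPoint) -
    intensityAt(before, bands$loPoint)
  dLd <- intensityAt(after, bands$ldPoint) -
    intensityAt(before, bands$ldPoint)
  if (abs(dLd) < ldFloor)
    stop("increase at the ", bands$ldPoint, "-nm marker is zero; ",
         "the Lo/Ld ratio is undefined")
  nearFloor <- abs(dLd) < 1e3 * max(ldFloor, abs(dLo) * 1e-6)
  if (nearFloor)
    warning("Ld-marker increase is near the floor; ratio is ",
            "dominated by the Lo term")
  list(ratio = dLo / dLd, deltaLo = dLo, deltaLd = dLd,
       ldNearFloor = nearFloor)
}

#' Baseline-normalized kinetic Lo and Ld ratio traces
#'
#' From a kinetic trace acquired at the reference (490 nm), Lo marker
#' (570 nm) and Ld marker (610 nm) wavelengths: blank-subtracts each
#' channel, forms the 570/490 and 610/490 ratios, and normalizes each
#' ratio trace to its own pre-stimulation baseline mean, so agonist
#' effects read as fold change from 1. Ratios are invariant to a common
#' multiplicative gain.
#'
#' @param trace a [KineticTrace-class] with channels named `"490"`,
#'   `"570"`, `"610"` whose `baselineWindow` precedes stimulation.
#' @param bands see [spectralBands()].
#' @return data.frame with columns `time_s`, `lo` (normalized 570/490)
#'   and `ld` (normalized 610/490), plus attribute `baselineMeans`.
#' @export
kineticLoRatio <- function(trace, bands = spectralBands()) {
  stopifnot(is(trace, "KineticTrace"))
  ref <- channelSignal(trace, bands$refWavelength)
  if (any(ref == 0))
    stop("reference channel is zero at some time points; ratio undefined")
  rLo <- channelSignal(trace, bands$loPoint) / ref
  rLd <- channelSignal(trace, bands$ldPoint) / ref
  t <- traceTimes(trace)
  lo <- normalizeToBaseline(t, rLo, trace@baselineWindow)
  ld <- normalizeToBaseline(t, rLd, trace@baselineWindow)
  out <- data.frame(time_s = t, lo = lo, ld = ld)
  attr(out, "baselineMeans") <- c(lo = attr(lo, "baselineMean"),
                                  ld = attr(ld, "baselineMean"))
  out
}
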