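---
title: "Quantifying receptor nanodomain clustering and single-molecule dynamics with nanodyn"
author: "nanodyn maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying receptor nanodomain clustering and single-molecule dynamics with nanodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanodyn)
```

# Scope

`nanodyn` quantifies how agonist stimulation reorganizes a cell-surface
receptor within the plasma membrane, combining four measurement families
that are usually analyzed with ad-hoc spreadsheets or instrument
software:

1. **Single-molecule motion analysis** — time-averaged mean squared
   displacement (TA-MSD) of tracked molecules, a power-law fit for the
   generalized diffusion coefficient and anomalous exponent, and a
   four-class motion classification.
2. **Spatial point statistics** — nearest-neighbour distances of EM
   gold-particle maps with a Monte-Carlo CSR null, and oligomer counting
   of PALM localizations with association/deduplication radii.
3. **Membrane-phase spectroscopy** — decomposition of
   solvatochromic-probe TR-FRET emission spectra into liquid-ordered
   (Lo) and liquid-disordered (Ld) band fractions.
4. **Plate-reader pharmacology** — ratiometric kinetic traces, logistic
   dose-response fits, equilibrium and kinetic binding models, and
   pathway-bias (ΔΔlogEC50) estimation.

A synthetic-data module generates inputs for every stage with known
ground truth, so the whole pipeline is testable without instrument data.

# Single-molecule motion

## Model

For a trajectory sampled every `dt` seconds (default 0.03 s, the typical
single-molecule TIRF frame interval), the TA-MSD at lag time $t$ is
fitted with

$$\mathrm{TA\text{-}MSD}(t) = 4 D t^{\alpha} + 4\sigma_{err}^2,$$

where $D$ (µm²·s⁻ᵅ) is the generalized diffusion coefficient, $\alpha$
the anomalous diffusion exponent, and $\sigma_{err}$ (µm) the static
localization error, which enters as a constant offset. Classification
uses the standard thresholds, exposed in `motionThresholds()`:
particles with $D < 0.01$ µm²·s⁻ᵅ are **immobile** regardless of
$\alpha$; mobile particles are **subdiffusive** ($\alpha < 0.75$),
**normal** ($0.75 \le \alpha \le 1.25$) or **superdiffusive**
($\alpha > 1.25$). Both $\alpha$ boundaries are inclusive and $D$ equal
to the threshold counts as mobile. Only tracks lasting at least 100
observed frames are analyzed, and tracks missing more than 20% of the
frames inside their span (tracker gap-closing) are excluded with a
count. Class fractions are pooled over trajectories, not averaged per
cell.

## TA-MSD computation

`timeAveragedMSD()` averages $|r_{i+n} - r_i|^2$ over every *observed*
pair at frame lag $n$; gapped frames simply contribute no pairs, so a
track observed at frames 1, 2, 4 yields one pair each at lags 1, 2
and 3. The default lag range ends at a quarter of the track span
(capped at 50): long-lag TA-MSD values average few, strongly correlated
pairs.

## Fitting and its numerical choices

`fitMSD()` minimizes unweighted least squares on the linear (not log)
scale, which is the scale on which the $4\sigma_{err}^2$ offset is
additive; weighting each lag by its pair count is available as an
option. The parameters are bounded ($D \ge 0$, $\alpha \in [0, 2]$,
$\sigma_{err} \ge 0$) and optimized with Levenberg–Marquardt. The
objective has genuine local minima in $\alpha$, so the optimizer is
started from three guesses — a log–log regression of the raw curve, a
log–log regression after subtracting the apparent offset, and a
Brownian guess — and the lowest converged deviance wins. An exactly
constant curve is a degenerate input: $\alpha \to 0$ makes $D$ and the
offset interchangeable, so whenever the pure-offset solution fits as
well as the best power-law solution the fit resolves to $D = 0$ with
$\sigma_{err}$ carrying the level, i.e. the immobile reading.
Non-converged fits keep an honest `converged = FALSE` flag and are
excluded (and counted) by cohort summaries, never coerced.

## Cohort-level fitting: shared localization error and short lags

Two defaults of `summarizeCohort()` differ deliberately from the
single-trajectory fit:

* **Shared $\sigma_{err}$ (two passes).** The static localization error
  is a property of the microscope, label and exposure — not of the
  individual molecule. A first pass fits every track with
  $\sigma_{err}$ free; the cohort estimate is the median of the
  converged values; a second pass refits $D$ and $\alpha$ per track
  with that shared offset. The per-track free fit is nearly degenerate
  between a sublinear exponent and a positive offset, which is the
  dominant source of exponent misclassification; fixing the offset
  cohort-wide removes it. In simulations at the four benchmark regimes
  (150-frame tracks, 20-nm localization error) this raises per-class
  recovery from roughly 50–85% to 97–100%.
* **Short fit range.** The cohort fit uses lags up to 5% of the track
  span (at least 5 lags), because exponent precision deteriorates
  quickly once long, noise-dominated lags enter the objective.

Both behaviours are options (`sharedSigma = FALSE`,
`maxLagFraction`), and `fitMSD()` itself keeps the fully free
per-trajectory fit as its default.

## The trajectory generator

`simulateTrajectory()` realizes the fitted model exactly: each
coordinate is fractional Brownian motion with Hurst exponent
$H = \alpha/2$ and $\mathrm{Var}[x(t) - x(0)] = 2 D t^{\alpha}$, plus
iid Gaussian localization noise per coordinate per frame (added after
path generation, which is what produces the constant $4\sigma_{err}^2$
offset). Increments are drawn from the exact fractional-Gaussian-noise
covariance — Cholesky factorization up to 2,048 increments, Davies–Harte
circulant embedding beyond — never from an Euler-style approximation,
so the generator can serve as an oracle for the fit. $\alpha = 1$
reduces to iid Brownian increments and $\alpha = 2$ to the perfectly
correlated ballistic limit. Seeds are explicit arguments everywhere and
the caller's RNG state is left untouched.

fBm is a modelling choice, not a claim about mechanism: confined
diffusion, hop diffusion, and transient binding also produce sublinear
TA-MSD, and the classifier cannot distinguish among them. fBm is simply
the minimal stationary Gaussian process exactly consistent with the
fitted power law. The benchmark cohort (`benchmarkRegimes()`) uses one
component per class — immobile $D = 0.001$, $\alpha = 1$; subdiffusive
$D = 0.05$, $\alpha = 0.4$; normal $D = 0.05$, $\alpha = 1$;
superdiffusive $D = 0.05$, $\alpha = 1.6$; all with
$\sigma_{err} = 0.02$ µm — values chosen to sit well away from the
class boundaries, with a realistic 20-nm localization error.

# Spatial point patterns

`nearestNeighborDistances()` reports per-point distances to the closest
other point with **no edge correction**, matching direct measurement on
micrographs; a toroidal metric exists solely so tests can use the CSR
closed form $E[\mathrm{NND}] = 1/(2\sqrt{\lambda})$. The Monte-Carlo
null (`csrNull()`) simulates patterns with the same point count and
window and applies the standard $(1 + k)/(n_{sims} + 1)$ correction,
one-sided in the clustering direction.

`countOligomers()` implements the two PALM rules: repeat activations
within the 10-nm deduplication radius of an already-retained
localization are discounted, then each retained molecule's cluster size
is the number of retained molecules within the 50-nm association
radius, inclusive of itself. The deduplication scan is greedy in a
deterministic order (points sorted by x, then y) because the discount
rule does not define one; the retained set always has pairwise
distances above the radius regardless of order, but individual retained
coordinates can differ, so determinism matters for reproducibility. The
per-molecule neighbourhood count is used rather than connected
components; a component reading would report larger clusters whenever
chains exceed the association radius, and can be obtained from the same
retained coordinates if needed.

The Thomas generator (Poisson parents, Poisson offspring counts,
isotropic Gaussian displacement) discards offspring outside the window,
mimicking an imaged membrane sheet; the toroidal option wraps them
instead so expected counts stay exact for tests.

# Membrane-phase spectral decomposition

Spectral scans cover 460–650 nm in 5-nm steps. Each blank-subtracted
read is normalized to its own 490-nm signal (the dominant donor line),
and the normalized donor-only read is subtracted, isolating the
probe-specific sensitized emission; the result is zero at 490 nm by
construction and invariant to instrument gain. Band fractions integrate
the difference spectrum with the trapezoid rule **on the native grid**
(no interpolation): the Lo band spans 530–590 nm and the Ld band
590–650 nm, with 590 nm terminating one trapezoid and starting the
next, so no mass is double-counted and the two fractions sum to 1
exactly by construction. Negative post-subtraction intensities are
retained — clipping would bias the fractions — so on pathological
inputs a fraction can leave $[0, 1]$; this is flagged with a warning,
never truncated. The alternative point readout takes the probe-specific
increases at 570 nm (Lo marker) and 610 nm (Ld marker) as a ratio, and
kinetic mode forms 570/490 and 610/490 traces normalized to each well's
own pre-stimulation baseline.

The spectrum generator uses a lanthanide-like donor line spectrum and
two Gaussian sensitized-emission components (570 and 610 nm, 8-nm SD)
whose band-integral split has a closed form (`analyticLoFraction()`);
the 8-nm width keeps each component essentially inside its band and the
5-nm trapezoid within 0.1% of the analytic split. Real NR12S spectra
are broader and asymmetric; the generator emulates the *analysis
contract* (grid, normalization, band split), not probe photophysics.

# Plate-reader pharmacology

* **Ratiometric traces.** `ratiometricTrace()` blank-subtracts each
  channel and divides; all published channel pairs (665/616 clustering,
  620/520 internalization, 520/620 binding, 535/485 biosensors) are
  just arguments. Fold-from-baseline normalization divides by the mean
  over the pre-stimulation window and AUC uses the trapezoid rule,
  integrating `series - 1` in above-baseline mode.
* **Logistic fits.** `fitLogistic()` uses
  $y = b + (t - b)/(1 + 10^{(\log EC_{50} - \log_{10} d)\,h})$ with the
  Hill slope kept positive by a bound; 3-parameter mode fixes $h = 1$.
  Vehicle observations (dose 0) anchor the bottom asymptote instead of
  being placed at $-\infty$ on the log axis. Standard errors come from
  the curvature at the optimum. Dose-unit rescaling shifts
  $\log EC_{50}$ by exactly the corresponding decades.
* **Binding.** Saturation mode fits one-site specific binding
  $B = B_{max} L/(K_d + L)$; kinetic mode fits
  $Y_L(t) = B_{max} L/(L + k_{off}/k_{on})\,(1 - e^{-(k_{on} L + k_{off}) t})$
  globally across two or more ligand concentrations (a single
  concentration cannot separate the rate constants and is refused),
  with $K_d = k_{off}/k_{on}$. Initialization regresses per-trace
  observed rates on concentration, using the identity
  $k_{obs} = k_{on} L + k_{off}$.
* **Bias.** `biasEstimate()` forms, within each experiment,
  $\Delta\log EC_{50} = \log EC_{50}(\text{reference agonist}) -
  \log EC_{50}(\text{agonist})$ per pathway, then
  $\Delta\Delta\log EC_{50} = \Delta(\text{reference pathway}) -
  \Delta(\text{test pathway})$, summarized as mean ± SEM over
  experiments with no cross-ratio error propagation (valid because all
  agonists are measured in parallel within an experiment). The
  reference agonist is identically zero, the estimate flips sign under
  pathway swap, and any per-pathway constant cancels. The subtraction
  direction is stated in the output object because conventions vary
  across the bias literature.
* **Membrane profiles.** The time-lapse internalization readout takes,
  per frame, the mean of per-segment peak intensities across several 1D
  profiles drawn over the plasma membrane, normalizes to the value at
  time zero, and summarizes with AUC.

# Problem sizes and test design

The test suite regenerates every fixture in code. Oracle checks use
direct enumeration (double-loop TA-MSD, $O(n^2)$ nearest-neighbour and
oligomer counts up to ~2,000 points); recovery experiments use 250
trajectories per motion class at 150 frames, 200-replicate Monte-Carlo
batteries for closed-form limits, and 50–200-seed simulation studies
for the fits. These sizes give stable pass/fail behaviour at the stated
tolerances while keeping the default suite fast. Passing them shows the
implementation is faithful to its models; it does not certify behaviour
on real data, where motion is not exactly fBm, localization error is
not exactly Gaussian, spectra are broader than two Gaussian bands, and
pipetting artifacts violate the logistic model in structured ways.

# Known limitations

* The classifier is threshold-based on per-trajectory point estimates;
  it propagates no fit uncertainty and will misclassify trajectories
  whose true parameters sit close to a boundary.
* TA-MSD-based exponents on 100–200-frame tracks have irreducible
  spread; the shared-σ default assumes one imaging configuration per
  cohort and should be disabled when conditions mix optics.
* No blinking/photophysics correction is applied to PALM counts beyond
  the deduplication radius; oligomer sizes are upper bounds under heavy
  re-activation.
* Spectral decomposition assumes the 460–650/5-nm grid covers both
  bands; it does not unmix overlapping fluorophores.
* Bias estimation implements the relative-potency (equiactive
  comparison) approach for full agonists only; operational-model bias
  factors are out of scope.
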