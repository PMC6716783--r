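# nanodyn

Quantification of receptor nanodomain clustering and single-molecule
membrane dynamics.

When a G-protein-coupled receptor such as GLP-1R is stimulated, it can
partition into cholesterol-rich membrane nanodomains, cluster, and
change its lateral diffusion — and different agonists of the same
receptor do this to very different degrees. `nanodyn` packages the
quantitative methods needed to measure these behaviours from four kinds
of raw data, for cell biologists and pharmacologists running
single-molecule imaging and plate-reader experiments:

* **Single-particle tracking.** The time-averaged MSD of each
  trajectory is fitted with
  `TA-MSD(t) = 4 D t^α + 4 σ_err²`
  (generalized diffusion coefficient *D* in µm²·s⁻ᵅ, anomalous
  exponent *α*, static localization error *σ_err*), and molecules are
  classified as immobile (*D* < 0.01 µm²·s⁻ᵅ), subdiffusive
  (*α* < 0.75), normal (0.75 ≤ *α* ≤ 1.25) or superdiffusive
  (*α* > 1.25), analyzing only tracks of ≥ 100 frames.
* **Spatial point patterns.** Nearest-neighbour distances of EM
  gold-particle maps with a Monte-Carlo CSR null, and PALM oligomer
  counting with a 50-nm association radius after 10-nm deduplication of
  repeat activations.
* **Membrane-phase TR-FRET spectra.** 490-nm-normalized, donor-only-
  subtracted emission spectra split into liquid-ordered (530–590 nm)
  and liquid-disordered (590–650 nm) band fractions, plus the 570/610
  point-ratio and kinetic readouts.
* **Plate-reader pharmacology.** Blank-subtracted ratiometric kinetic
  traces (665/616, 620/520, 535/485, …), baseline normalization and
  AUC, 3/4-parameter logistic dose-response fits
  (`y = bottom + (top − bottom)/(1 + 10^((logEC50 − log10 d)·hill))`),
  one-site saturation and global association-kinetics binding fits
  (`kobs = kon·L + koff`, `Kd = koff/kon`), and ligand-bias estimation
  (`ΔΔlogEC50`, reference-pathway minus test-pathway differences of
  reference-agonist-normalized potencies).

A synthetic-data module generates every input class with known ground
truth — exact-covariance fractional-Brownian-motion trajectory cohorts,
CSR/Thomas point patterns, two-component emission spectra, logistic and
binding traces — so the entire pipeline is testable end to end.

## Worked example

```r
library(nanodyn)

# a labelled four-regime cohort: 100 molecules per motion class
cohort <- simulateCohort(benchmarkRegimes(100), seed = 1)
res <- summarizeCohort(cohort$trajectories, cohort$labels)
res$summary[res$summary$n > 0, ]
#>       condition          class   n fraction
#>        immobile       immobile 100     1.00
#>    subdiffusion   subdiffusion 100     1.00
#>          normal   subdiffusion   6     0.06
#>          normal         normal  94     0.94
#>  superdiffusion         normal   1     0.01
#>  superdiffusion superdiffusion  99     0.99
res$cohortSigma     # shared localization-error estimate: 0.0194 um
```

Each row gives, per condition, how many analyzed trajectories fell in
each motion class and the pooled fraction; the simulated 20-nm
localization error is recovered as the cohort sigma.

```r
# clustered gold-particle map vs complete spatial randomness
gold <- simulatePointPattern(c(0, 0, 2000, 2000), "Thomas", 2e-5,
                             meanOffspring = 6, clusterSd = 12, seed = 2)
nearestNeighborDistances(gold)$mean          # 11.0 nm
csrNull(gold, nSims = 199, seed = 3)$p       # 0.005
countOligomers(gold)$meanSize                # 4.66 molecules/cluster

# membrane-phase split of a probe-specific TR-FRET spectrum
sp <- simulateSpectrum(loWeight = 0.7, amplitude = 0.5, noiseSd = 0,
                       seed = 4)
loLdFractions(nr12sFretSpectrum(sp$donorOnly, sp$sample))
#>    lo    ld
#> 0.697 0.303

# noisy dose-response and its logistic fit
d <- 10^seq(-11, -7, length.out = 8)
dr <- simulateDoseResponse(d, bottom = 0, top = 100, logEC50 = -9,
                           hill = 1, noiseSd = 2, seed = 5)
fitLogistic(dr$dose_M, dr$response)
#> 4-parameter logistic fit: logEC50 = -9.042, top = 97.5,
#>   bottom = 0.408, hill = 1.1 (converged)
```

The mean nearest-neighbour distance of the clustered map (11 nm) is far
below its CSR null (≈ 50 nm, Monte-Carlo p = 0.005); the spectral Lo
fraction recovers the generator's 0.7 weight; the logistic fit recovers
the generating potency within the noise.

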