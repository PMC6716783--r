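# Ratiometric traces, AUC responses, logistic dose-response, binding
# models and the ligand-bias ledger.

test_that("ratiometric traces blank-subtract and guard the denominator", {
  t <- seq(0, 100, 10)
  tr <- KineticTrace(t, list("665" = rep(50, 11), "616" = rep(50, 11)),
                     blanks = c("665" = 0, "616" = 0))
  expect_equal(ratiometricTrace(tr, 665, 616), rep(1, 11))
  # blanks equal to the signal zero the denominator
  tr2 <- KineticTrace(t, list("665" = rep(50, 11), "616" = rep(50, 11)),
                      blanks = c("665" = 0, "616" = 50))
  expect_error(ratiometricTrace(tr2, 665, 616), "zero")
  # synthetic DERET-style trace reproduces the generator ratio exactly
  kt <- simulateKineticTrace(t, channels = list(
    "620" = list(baseline = 100, amplitude = 1.5, rate = 0.05),
    "520" = list(baseline = 1000, amplitude = 0, rate = 0)),
    tStim = 30, blanks = c("620" = 7, "520" = 11), noiseSd = 0, seed = 1)
  r <- ratiometricTrace(kt, 620, 520)
  clean620 <- 100 * (1 + 1.5 * ifelse(t < 30, 0,
                                      1 - exp(-0.05 * (t - 30))))
  expect_equal(r, clean620 / 1000, tolerance = 1e-12)
})

test_that("baseline normalization gives fold-change traces", {
  t <- 0:20
  expect_equal(as.numeric(normalizeToBaseline(t, rep(4, 21), c(0, 5))),
               rep(1, 21))
  stepped <- ifelse(t < 6, 2, 6)
  nb <- normalizeToBaseline(t, stepped, c(0, 5))
  expect_equal(as.numeric(nb[t >= 6]), rep(3, 15))
  expect_equal(attr(nb, "baselineMean"), 2)
  expect_error(normalizeToBaseline(t, rep(-1, 21), c(0, 5)),
               "not positive")
  expect_error(normalizeToBaseline(t, rep(1, 21), c(0, 0.5)),
               "fewer than 2")
  # noisy baseline mean is unbiased at the 3-SE level
  withr::with_seed(9, {
    vals <- 10 + rnorm(2000, sd = 0.5)
    nb <- normalizeToBaseline(seq_along(vals), vals,
                              c(1, length(vals)))
    expect_lt(abs(attr(nb, "baselineMean") - 10),
              3 * 0.5 / sqrt(2000))
  })
})

test_that("AUC behaves as a rectangle rule on steps and is linear", {
  # flat normalized trace: zero response
  expect_equal(aucResponse(0:10, rep(1, 11)), 0)
  # unit step of duration 10 encoded with a duplicated breakpoint
  expect_equal(aucResponse(c(0, 3, 3, 13), c(1, 1, 2, 2)), 10)
  # linearity in the above-baseline response
  withr::with_seed(10, {
    t <- seq(0, 60, 2)
    s <- 1 + abs(rnorm(length(t)))
    a <- 2.7
    expect_equal(aucResponse(t, a * (s - 1) + 1), a * aucResponse(t, s),
                 tolerance = 1e-12)
  })
  # trapezoid error against a closed-form integral on a smooth curve
  t <- seq(0, 10, 0.25)
  s <- exp(-0.3 * t)
  exact <- (1 - exp(-3)) / 0.3
  expect_equal(aucResponse(t, s, mode = "raw"), exact, tolerance = 1e-3)
})

test_that("logistic fits recover noise-free parameters exactly", {
  d <- 10^seq(-11, -7, length.out = 8)
  y <- logisticModel(d, 0, 100, -9, 1)
  f <- fitLogistic(d, y)
  expect_true(f@converged)
  expect_equal(f@logEC50, -9, tolerance = 1e-6)
  expect_equal(f@top, 100, tolerance = 1e-5)
  expect_equal(f@bottom, 0, tolerance = 1e-4)
  expect_equal(f@hill, 1, tolerance = 1e-6)
  # steeper curve with a floor, 3-parameter mode fixes hill at 1
  y2 <- logisticModel(d, 10, 80, -8.6, 1)
  f3 <- fitLogistic(d, y2, nParams = 3)
  expect_identical(f3@hill, 1)
  expect_equal(f3@logEC50, -8.6, tolerance = 1e-6)
  # bottom constraint
  fb <- fitLogistic(d, y, nParams = 4, fixBottom = 0)
  expect_identical(fb@bottom, 0)
  expect_equal(fb@logEC50, -9, tolerance = 1e-6)
  # vehicle rows (dose 0) anchor the bottom asymptote
  dv <- c(0, 0, d)
  yv <- logisticModel(dv, 12, 90, -9, 1)
  fv <- fitLogistic(dv, yv)
  expect_equal(fv@bottom, 12, tolerance = 1e-5)
  expect_error(fitLogistic(d[1:3], y[1:3]), "distinct doses")
})

test_that("logistic fit shifts logEC50 exactly under dose rescaling", {
  d <- 10^seq(-11, -7, length.out = 8)
  y <- logisticModel(d, 0, 100, -9, 1.2)
  f1 <- fitLogistic(d, y)
  f2 <- fitLogistic(d * 1e3, y)  # e.g. file in mM instead of M
  expect_equal(f2@logEC50 - f1@logEC50, 3, tolerance = 1e-6)
  expect_equal(f2@hill, f1@hill, tolerance = 1e-6)
})

test_that("noisy logistic simulation recovers potency without bias", {
  d <- 10^seq(-11, -7, length.out = 8)
  ests <- ses <- numeric(200)
  for (i in 1:200) {
    dr <- simulateDoseResponse(d, bottom = 0, top = 100, logEC50 = -9,
                               hill = 1, noiseSd = 2, seed = 500 + i)
    f <- fitLogistic(dr$dose_M, dr$response)
    ests[i] <- f@logEC50
    ses[i] <- f@se[["logEC50"]]
  }
  expect_lt(abs(mean(ests) + 9), 0.05)
  covered <- mean(abs(ests + 9) <= 1.96 * ses, na.rm = TRUE)
  expect_gte(covered, 0.90)
  expect_lte(covered, 0.99)
})

test_that("saturation binding recovers Kd and flags flat signals", {
  L <- c(1, 3, 10, 30, 100, 300) * 1e-9
  B <- 100 * L / (1e-8 + L)
  f <- fitSaturationBinding(L, B)
  expect_true(f@converged)
  expect_equal(f@kd, 1e-8, tolerance = 1e-6)
  expect_equal(f@bmax, 100, tolerance = 1e-5)
  # half-maximal occupancy at L = Kd
  expect_equal(100 * 1e-8 / (1e-8 + 1e-8), 50)
  flat <- fitSaturationBinding(L, rep(40, 6))
  expect_false(flat@converged)
})

test_that("association kinetics needs >= 2 concentrations and is exact", {
  t <- seq(0, 3600, 60)
  tr <- simulateBindingTraces(t, c(1e-9, 1e-8), kon = 1e6, koff = 1e-3,
                              bmax = 100, noiseSd = 0, seed = 1)
  f <- fitAssociationKinetics(tr)
  expect_true(f@converged)
  expect_equal(f@kon, 1e6, tolerance = 1e-4)
  expect_equal(f@koff, 1e-3, tolerance = 1e-4)
  expect_equal(f@kd, 1e-9, tolerance = 1e-4)
  expect_equal(f@bmax, 100, tolerance = 1e-4)
  expect_error(fitAssociationKinetics(tr[tr$conc_M == 1e-9, ]),
               "single|two or more")
  # observed rates from per-trace fits are affine in L: kon L + koff
  Ls <- c(0.5, 1, 2, 5, 10) * 1e-9
  tr2 <- simulateBindingTraces(t, Ls, kon = 1e6, koff = 1e-3,
                               bmax = 100, noiseSd = 0, seed = 2)
  kobs <- vapply(Ls, function(L) {
    d <- tr2[tr2$conc_M == L, ]
    fitOnePhaseAssociation(d$time_s, d$signal)$rate
  }, numeric(1))
  expect_equal(kobs, 1e6 * Ls + 1e-3, tolerance = 1e-4)
})

test_that("noisy kinetic binding keeps Kd bias modest", {
  t <- seq(0, 3600, 120)
  kds <- vapply(1:60, function(i) {
    tr <- simulateBindingTraces(t, c(1e-9, 1e-8), kon = 1e6,
                                koff = 1e-3, bmax = 100, noiseSd = 2,
                                seed = 700 + i)
    fitAssociationKinetics(tr)@kd
  }, numeric(1))
  gmean <- exp(mean(log(kds)))
  expect_lt(abs(gmean - 1e-9) / 1e-9, 0.15)
})

test_that("bias ledger honours its conventions on constructed tables", {
  mkTab <- function(shift = 0) {
    tab <- expand.grid(agonist = c("ex4", "phe1", "asp3"),
                       pathway = c("cAMP", "membranePKA"),
                       experiment = 1:4, stringsAsFactors = FALSE)
    tab$logEC50 <- -9
    tab$logEC50[tab$agonist == "phe1" &
                  tab$pathway == "membranePKA"] <- -9 + shift
    tab
  }
  # identical potencies: all deltas zero
  b0 <- biasEstimate(mkTab(0), "ex4", "cAMP", "membranePKA")
  expect_true(all(b0@perExperiment$deltaDeltaLogEC50 == 0))
  # reference agonist is identically zero by construction
  bs <- biasEstimate(mkTab(0.5), "ex4", "cAMP", "membranePKA")
  ref <- bs@perExperiment[bs@perExperiment$agonist == "ex4", ]
  expect_true(all(ref$deltaLogEC50 == 0))
  expect_true(all(ref$deltaDeltaLogEC50 == 0))
  # +0.5 shift (less potent in the test pathway) is recovered exactly:
  # deltaLog(test) = -0.5, so deltaDelta = 0 - (-0.5) = +0.5
  phe <- bs@summary[bs@summary$agonist == "phe1", ]
  expect_equal(phe$deltaDeltaLogEC50, 0.5)
  expect_equal(phe$sem, 0)
  # swapping reference and test pathways flips the sign
  bswap <- biasEstimate(mkTab(0.5), "ex4", "membranePKA", "cAMP")
  expect_equal(
    bswap@summary$deltaDeltaLogEC50[bswap@summary$agonist == "phe1"],
    -0.5)
  # a constant added to one pathway cancels out of every bias estimate
  tab <- mkTab(0.5)
  tab$logEC50[tab$pathway == "cAMP"] <-
    tab$logEC50[tab$pathway == "cAMP"] + 0.3
  bconst <- biasEstimate(tab, "ex4", "cAMP", "membranePKA")
  expect_equal(bconst@summary$deltaDeltaLogEC50,
               bs@summary$deltaDeltaLogEC50)
  # missing cells are named
  expect_error(biasEstimate(mkTab(0)[-1, ], "ex4", "cAMP",
                            "membranePKA"),
               "missing logEC50 cell.*ex4.*cAMP")
})

test_that("membrane profile series normalizes peaks and integrates", {
  t <- seq(0, 90, 30)
  const <- lapply(t, function(i) list(c(1, 8, 2), c(0, 8, 1), c(8, 3)))
  r <- membraneProfileSeries(const, t)
  expect_equal(r$series, rep(1, 4))
  expect_equal(r$auc, 0)
  # peak halving at the second frame steps the trace to 0.5
  half <- c(const[1], lapply(t[-1], function(i) list(c(4, 1), c(2, 4))))
  r <- membraneProfileSeries(half, t)
  expect_equal(r$series, c(1, 0.5, 0.5, 0.5))
  # exponentially decaying peaks match the closed-form integral
  tf <- seq(0, 60, 1)
  prof <- lapply(tf, function(tt) list(10 * exp(-0.05 * tt) * c(0.2, 1)))
  r <- membraneProfileSeries(prof, tf, aucMode = "raw")
  exact <- (1 - exp(-0.05 * 60)) / 0.05
  expect_equal(r$auc, exact, tolerance = 1e-3)
  expect_error(membraneProfileSeries(
    list(list(c(0, 0)), list(c(1, 1))), c(0, 1)), "not positive")
})
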