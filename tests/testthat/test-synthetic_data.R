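# Trajectory, point-pattern and plate-signal generators: determinism,
# degenerate limits, and agreement of ensemble statistics with the
# generating models.

test_that("all generators are bitwise-reproducible from their seed", {
  t1 <- simulateTrajectory(50, D = 0.05, alpha = 0.8, sigmaErr = 0.02,
                           seed = 42)
  t2 <- simulateTrajectory(50, D = 0.05, alpha = 0.8, sigmaErr = 0.02,
                           seed = 42)
  expect_identical(coords(t1), coords(t2))

  c1 <- simulateCohort(benchmarkRegimes(3, nFrames = 110), seed = 5)
  c2 <- simulateCohort(benchmarkRegimes(3, nFrames = 110), seed = 5)
  expect_identical(lapply(c1$trajectories, coords),
                   lapply(c2$trajectories, coords))
  expect_identical(c1$labels, c2$labels)

  p1 <- simulatePointPattern(c(0, 0, 1000, 1000), "Thomas", 1e-5,
                             meanOffspring = 5, clusterSd = 20, seed = 9)
  p2 <- simulatePointPattern(c(0, 0, 1000, 1000), "Thomas", 1e-5,
                             meanOffspring = 5, clusterSd = 20, seed = 9)
  expect_identical(coords(p1), coords(p2))

  s1 <- simulateSpectrum(0.6, 0.5, noiseSd = 3, seed = 11)
  s2 <- simulateSpectrum(0.6, 0.5, noiseSd = 3, seed = 11)
  expect_identical(intensities(s1$sample), intensities(s2$sample))

  d1 <- simulateDoseResponse(10^seq(-11, -7), noiseSd = 2, seed = 3)
  d2 <- simulateDoseResponse(10^seq(-11, -7), noiseSd = 2, seed = 3)
  expect_identical(d1, d2)

  b1 <- simulateBindingTraces(0:10, c(1e-9, 1e-8), 1e6, 1e-3, 100,
                              noiseSd = 1, seed = 8)
  b2 <- simulateBindingTraces(0:10, c(1e-9, 1e-8), 1e6, 1e-3, 100,
                              noiseSd = 1, seed = 8)
  expect_identical(b1, b2)
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulateTrajectory(20, D = 0.1, alpha = 1, seed = 1))
  invisible(simulatePointPattern(c(0, 0, 100, 100), "CSR", 1e-3, seed = 2))
  expect_identical(.Random.seed, before)
})

test_that("trajectory generator rejects invalid parameters", {
  expect_error(simulateTrajectory(1, D = 0.1, alpha = 1, seed = 1),
               "nFrames")
  expect_error(simulateTrajectory(10, D = -1, alpha = 1, seed = 1), "'D'")
  expect_error(simulateTrajectory(10, D = 0.1, alpha = 0, seed = 1),
               "alpha")
  expect_error(simulateTrajectory(10, D = 0.1, alpha = 2.5, seed = 1),
               "alpha")
  expect_error(simulateTrajectory(10, D = 0.1, alpha = 1, sigmaErr = -1,
                                  seed = 1), "sigmaErr")
  expect_error(simulateTrajectory(10, D = 0.1, alpha = 1), "seed")
  expect_error(simulateCohort(list(), seed = 1), "non-empty")
  expect_error(simulateCohort(list(
    trajectoryComponent("a", 2, 10, 0.1, 1),
    trajectoryComponent("a", 2, 10, 0.1, 1)), seed = 1), "unique")
})

test_that("degenerate trajectories behave as the model dictates", {
  # D = 0, no noise: the molecule never moves
  tr <- simulateTrajectory(30, D = 0, alpha = 1, sigmaErr = 0, seed = 4)
  expect_true(all(coords(tr) == 0))
  # alpha = 1: increments are iid Gaussian with variance 2 D dt
  tr <- simulateTrajectory(20000, D = 0.1, alpha = 1, sigmaErr = 0,
                           dt = 0.03, seed = 6, method = "circulant")
  inc <- diff(coords(tr)[, 1])
  expect_equal(var(inc), 2 * 0.1 * 0.03, tolerance = 0.05)
  expect_lt(abs(cor(inc[-1], inc[-length(inc)])), 0.03)
})

test_that("fBm ensemble MSD matches 4 D t^alpha + 4 sigmaErr^2", {
  # single-component cohort, Brownian with localization noise
  n <- 2000L
  cohort <- simulateCohort(list(trajectoryComponent(
    "brownian", n, nFrames = 60, D = 0.1, alpha = 1, sigmaErr = 0.02,
    dt = 0.03)), seed = 13)
  for (lag in c(1L, 10L, 40L)) {
    sq <- vapply(cohort$trajectories, function(tr) {
      cc <- coords(tr)
      sum((cc[1L + lag, ] - cc[1L, ])^2)
    }, numeric(1L))
    expected <- 4 * 0.1 * (lag * 0.03) + 4 * 0.02^2
    se <- sd(sq) / sqrt(n)
    expect_lt(abs(mean(sq) - expected), 3 * se)
  }
})

test_that("cholesky and circulant fGn samplers agree with the exact law", {
  # anomalous exponents, both sampling routes, displacement-from-origin
  # variance checked against 2 D t^alpha per coordinate
  for (alpha in c(0.5, 1.5)) {
    for (method in c("cholesky", "circulant")) {
      n <- 800L
      sq <- vapply(seq_len(n), function(i) {
        tr <- simulateTrajectory(33, D = 0.05, alpha = alpha,
                                 sigmaErr = 0, dt = 0.03,
                                 seed = 20000 + i, method = method)
        cc <- coords(tr)
        sum((cc[33L, ] - cc[1L, ])^2)
      }, numeric(1L))
      expected <- 4 * 0.05 * (32 * 0.03)^alpha
      se <- sd(sq) / sqrt(n)
      expect_lt(abs(mean(sq) - expected), 4 * se)
    }
  }
})

test_that("alpha = 2 gives ballistic (perfectly correlated) paths", {
  tr <- simulateTrajectory(50, D = 0.05, alpha = 2, sigmaErr = 0,
                           seed = 3)
  inc <- diff(coords(tr)[, 1])
  expect_equal(max(inc) - min(inc), 0, tolerance = 1e-12)
})

test_that("CSR pattern respects its window and the intensity -> 0 limit", {
  p <- simulatePointPattern(c(0, 0, 500, 800), "CSR", 1e-4, seed = 21)
  cc <- coords(p)
  expect_true(all(cc[, 1] >= 0 & cc[, 1] <= 500))
  expect_true(all(cc[, 2] >= 0 & cc[, 2] <= 800))
  empty <- simulatePointPattern(c(0, 0, 100, 100), "CSR", 1e-12, seed = 1)
  expect_identical(nPoints(empty), 0L)
  expect_error(simulatePointPattern(c(0, 0, 0, 100), "CSR", 1e-3,
                                    seed = 1), "window")
})

test_that("Thomas expected point count is parents x offspring x area", {
  lambdaP <- 2e-5; mu <- 6; win <- c(0, 0, 1500, 1500)
  counts <- vapply(1:200, function(i)
    nPoints(simulatePointPattern(win, "Thomas", lambdaP,
                                 meanOffspring = mu, clusterSd = 10,
                                 seed = 3000 + i, toroidal = TRUE)),
    numeric(1L))
  expected <- lambdaP * mu * 1500^2
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("clusterSd -> 0 collapses offspring onto parents", {
  p <- simulatePointPattern(c(0, 0, 2000, 2000), "Thomas", 5e-6,
                            meanOffspring = 4, clusterSd = 0, seed = 31)
  res <- countOligomers(p, clusterConfig(assocRadius = 50,
                                         dedupRadius = 10))
  # all coincident offspring deduplicate to one retained point per parent
  kept <- res$nRetained
  parents <- nrow(unique(coords(p)))
  expect_identical(kept, parents)
})

test_that("noise-free plate generators lie exactly on their models", {
  # spectrum: amplitude 0 means sample == donor-only
  sp <- simulateSpectrum(0.5, amplitude = 0, noiseSd = 0, seed = 2)
  expect_equal(intensities(sp$sample), intensities(sp$donorOnly))
  # 4PL midpoint identity at dose = EC50
  expect_equal(logisticModel(1e-9, 0, 100, -9, 1), 50)
  dr <- simulateDoseResponse(10^seq(-11, -7, length.out = 6),
                             bottom = 5, top = 90, logEC50 = -9,
                             hill = 1.3, noiseSd = 0, seed = 1)
  expect_equal(dr$response,
               logisticModel(dr$dose_M, 5, 90, -9, 1.3))
  # association plateau at L -> infinity equals Bmax
  expect_equal(associationModel(1e9, 1, kon = 1e6, koff = 1e-3,
                                bmax = 100), 100, tolerance = 1e-6)
  tb <- simulateBindingTraces(seq(0, 100, 10), 1e-8, 1e6, 1e-3, 100,
                              noiseSd = 0, seed = 1)
  expect_equal(tb$signal,
               associationModel(tb$time_s, tb$conc_M, 1e6, 1e-3, 100))
  # kinetic trace: noise-free channels sit on the stated rise model
  kt <- simulateKineticTrace(
    seq(0, 600, 30), channels = list(
      "570" = list(baseline = 100, amplitude = 0.5, rate = 0.01),
      "490" = list(baseline = 400, amplitude = 0, rate = 0)),
    tStim = 300, noiseSd = 0, seed = 1)
  s570 <- channelSignal(kt, 570)
  tt <- traceTimes(kt)
  model <- 100 * (1 + 0.5 * ifelse(tt < 300, 0,
                                   1 - exp(-0.01 * (tt - 300))))
  expect_equal(s570, model)
  expect_equal(channelSignal(kt, 490), rep(400, length(tt)))
})

test_that("generator validation errors fire", {
  expect_error(simulateSpectrum(1.2, 1, 0, seed = 1), "loWeight")
  expect_error(simulateSpectrum(0.5, 1, -1, seed = 1), "noiseSd")
  expect_error(simulateDoseResponse(c(0, 1e-9), seed = 1), "positive")
  expect_error(simulateBindingTraces(0:10, -1e-9, 1e6, 1e-3, 100,
                                     seed = 1), "positive")
})
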