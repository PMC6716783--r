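# TA-MSD computation, anomalous-diffusion fit and four-class motion
# classification.

test_that("timeAveragedMSD matches direct pair enumeration exactly", {
  withr::with_seed(101, {
    for (i in 1:100) {
      n <- sample(10:40, 1)
      fix <- randomTrackFixture(n, gapped = i %% 2 == 0)
      traj <- Trajectory(fix$coords, dt = 0.03, frames = fix$frames)
      cv <- timeAveragedMSD(traj, maxLagFraction = 1,
                            maxLag = max(fix$frames))
      oracle <- bruteTAMSD(fix$coords, fix$frames, max(fix$frames))
      expect_identical(cv@lags, as.integer(oracle[, "lag"]))
      expect_equal(cv@msd, unname(oracle[, "msd"]), tolerance = 1e-12)
      expect_identical(cv@nPairs, as.integer(oracle[, "n"]))
    }
  })
})

test_that("hand-enumerated MSD examples are reproduced", {
  # 3-point track (0,0),(1,0),(1,1), dt = 1: msd(1) = 1, msd(2) = 2
  traj <- Trajectory(rbind(c(0, 0), c(1, 0), c(1, 1)), dt = 1)
  cv <- timeAveragedMSD(traj, maxLagFraction = 1)
  expect_equal(cv@msd, c(1, 2))
  expect_identical(cv@nPairs, c(2L, 1L))
  expect_equal(cv@times, c(1, 2))

  # stationary 100-frame track: msd identically zero
  still <- Trajectory(matrix(5, nrow = 100, ncol = 2), dt = 0.03)
  expect_true(all(timeAveragedMSD(still)@msd == 0))

  # ballistic track x = v t with v = 1 um/s: msd(n) = (n dt)^2
  i <- 0:99
  bal <- Trajectory(cbind(1 * i * 0.03, 0 * i), dt = 0.03)
  cv <- timeAveragedMSD(bal)
  expect_equal(cv@msd, (cv@lags * 0.03)^2, tolerance = 1e-12)

  # gapped track frames 1,2,4: one pair each at lags 1, 2, 3
  g <- Trajectory(rbind(c(0, 0), c(1, 0), c(3, 0)), dt = 1,
                  frames = c(1L, 2L, 4L))
  cv <- timeAveragedMSD(g, maxLagFraction = 1)
  expect_identical(cv@lags, 1:3)
  expect_identical(cv@nPairs, c(1L, 1L, 1L))
  expect_equal(cv@msd, c(1, 4, 9))
})

test_that("fitMSD recovers noise-free model curves exactly", {
  t <- (1:25) * 0.03
  mk <- function(D, a, s) new("MSDCurve", lags = 1:25, times = t,
                              msd = 4 * D * t^a + 4 * s^2,
                              nPairs = rep(100L, 25), dt = 0.03)
  f <- fitMSD(mk(0.1, 1, 0))
  expect_true(f@converged)
  expect_equal(f@D, 0.1, tolerance = 1e-6)
  expect_equal(f@alpha, 1, tolerance = 1e-6)
  expect_equal(f@sigmaErr, 0, tolerance = 1e-4)

  f <- fitMSD(mk(0.05, 0.4, 0.02))
  expect_equal(f@D, 0.05, tolerance = 1e-6)
  expect_equal(f@alpha, 0.4, tolerance = 1e-6)
  expect_equal(f@sigmaErr, 0.02, tolerance = 1e-6)

  f <- fitMSD(mk(0.02, 1.6, 0.01), weighting = "npairs")
  expect_equal(f@alpha, 1.6, tolerance = 1e-6)

  # degenerate constant curve: D -> 0, sigma -> offset level
  fc <- fitMSD(mk(0, 1, 0.02))
  expect_lt(fc@D, 1e-8)
  expect_equal(fc@sigmaErr, 0.02, tolerance = 1e-6)

  # fixed-sigma mode: two-parameter recovery
  ff <- fitMSD(mk(0.05, 0.4, 0.02), fixSigma = 0.02)
  expect_equal(ff@D, 0.05, tolerance = 1e-6)
  expect_equal(ff@alpha, 0.4, tolerance = 1e-6)
  expect_identical(ff@sigmaErr, 0.02)

  expect_error(fitMSD(new("MSDCurve", lags = 1:4, times = (1:4) * 0.03,
                          msd = rep(1, 4), nPairs = rep(5L, 4),
                          dt = 0.03)), "at least 5 lags")
})

test_that("fit is invariant to translation and rotation of the track", {
  tr <- simulateTrajectory(120, D = 0.05, alpha = 0.8, sigmaErr = 0.01,
                           seed = 55)
  cc <- coords(tr)
  th <- 37 * pi / 180
  rot <- cc %*% rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  moved <- Trajectory(sweep(rot, 2, c(12.3, -4.5), "+"), dt = 0.03)
  f1 <- fitMSD(timeAveragedMSD(tr))
  f2 <- fitMSD(timeAveragedMSD(moved))
  expect_equal(f1@D, f2@D, tolerance = 1e-8)
  expect_equal(f1@alpha, f2@alpha, tolerance = 1e-8)
})

test_that("classifier reproduces the published threshold semantics", {
  mk <- function(D, a) new("MotionFit", D = D, alpha = a, sigmaErr = 0,
                           residualNorm = 0, converged = TRUE,
                           nFramesUsed = 150L)
  expect_identical(classifyMotion(mk(0.005, 1.0)), "immobile")
  expect_identical(classifyMotion(mk(0.02, 1.0)), "normal")
  expect_identical(classifyMotion(mk(0.02, 0.5)), "subdiffusion")
  expect_identical(classifyMotion(mk(0.02, 1.5)), "superdiffusion")
  # boundary semantics: D = 0.01 is mobile; alpha = 0.75 / 1.25 normal
  expect_identical(classifyMotion(mk(0.01, 0.75)), "normal")
  expect_identical(classifyMotion(mk(0.01, 1.25)), "normal")
  expect_identical(classifyMotion(mk(0.009999, 2)), "immobile")
  # immobility ignores alpha
  expect_identical(classifyMotion(mk(0.001, 1.9)), "immobile")
  bad <- new("MotionFit", D = 0.02, alpha = 1, sigmaErr = 0,
             residualNorm = 0, converged = FALSE, nFramesUsed = 150L)
  expect_error(classifyMotion(bad), "non-converged")
})

test_that("per-trajectory free fits recover subdiffusive parameters", {
  cohort <- simulateCohort(list(trajectoryComponent(
    "sub", 300, nFrames = 150, D = 0.05, alpha = 0.4, sigmaErr = 0.02)),
    seed = 17)
  fits <- lapply(cohort$trajectories, function(tr)
    fitMSD(timeAveragedMSD(tr)))
  conv <- vapply(fits, slot, logical(1), "converged")
  alphas <- vapply(fits[conv], slot, numeric(1), "alpha")
  Ds <- vapply(fits[conv], slot, numeric(1), "D")
  expect_gt(mean(conv), 0.95)
  expect_lt(abs(median(alphas) - 0.4), 0.1)
  expect_lt(abs(median(Ds) - 0.05) / 0.05, 0.3)
})

test_that("cohort summary filters, classifies and normalizes fractions", {
  still <- lapply(1:10, function(i)
    Trajectory(matrix(i, nrow = 120, ncol = 2) +
                 matrix(rnorm(240, sd = 1e-4), ncol = 2), dt = 0.03))
  res <- summarizeCohort(still)
  imm <- res$summary[res$summary$class == "immobile", ]
  expect_equal(imm$fraction, 1.0)
  expect_equal(sum(res$summary$fraction), 1.0)

  # 99-frame tracks are all excluded by the 100-frame filter
  short <- lapply(1:5, function(i)
    Trajectory(matrix(rnorm(198), ncol = 2), dt = 0.03))
  expect_error(summarizeCohort(short), "excluded")

  # heavily gapped tracks are excluded and counted
  gappy <- Trajectory(matrix(rnorm(222), ncol = 2), dt = 0.03,
                      frames = c(0:99, seq(120, 170, 5)))
  res <- summarizeCohort(c(still, list(gappy)))
  expect_identical(res$counts$nGapped, 1L)
  expect_identical(res$counts$nAnalyzed, 10L)
})

test_that("four-regime cohort is recovered with high per-class accuracy", {
  cohort <- simulateCohort(benchmarkRegimes(100), seed = 23)
  res <- summarizeCohort(cohort$trajectories, cohort$labels)
  acc <- vapply(split(res$fits, res$fits$condition), function(d)
    mean(d$class == d$condition[1]), numeric(1))
  expect_true(all(acc >= 0.9))
  expect_equal(res$cohortSigma, 0.02, tolerance = 0.25)
})

test_that("estimated D is monotone in the true D", {
  meds <- vapply(c(0.02, 0.05, 0.1), function(Dtrue) {
    cohort <- simulateCohort(list(trajectoryComponent(
      "x", 60, nFrames = 150, D = Dtrue, alpha = 1, sigmaErr = 0.02)),
      seed = 29)
    res <- summarizeCohort(cohort$trajectories)
    median(res$fits$D)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})
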