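# Synthetic generators: calibrated jump preset, Langevin dynamics on
# explicit potentials, and toy structures with planted clusters.

test_that("calibrated two-state preset has the exact closed-form truth", {
  preset <- ppiReleasePreset()
  k12 <- preset@rates[1, 2]
  k21 <- preset@rates[2, 1]
  # closed form for two-state exchange
  expect_equal(truthStationary(preset)[2], k12 / (k12 + k21), tolerance = 1e-12)
  expect_equal(jumpMFPT(preset)[1, 2], 1 / k12, tolerance = 1e-12)
  expect_equal(jumpMFPT(preset)[1, 2], 500)
  # matches the reported bound/released populations (12.6% / 87.4%)
  expect_equal(truthStationary(preset), c(0.126, 0.874), tolerance = 1e-5)
  expect_equal(diag(jumpMFPT(preset)), c(0, 0))
})

test_that("long-run occupancy converges to the stationary distribution", {
  sim <- simulateJump(ppiReleasePreset(), nFrames = 1e7, frameInterval = 1,
                      nTrajectories = 1, seed = 101)
  occ2 <- mean(sim$statePaths[[1]] == 2L)
  # frames are autocorrelated with correlation time 1/(k12+k21) frames;
  # SE = sqrt(pi1 pi2 * 2 tau_c / n)
  tauC <- 1 / sum(ppiReleasePreset()@rates)
  se <- sqrt(0.126 * 0.874 * 2 * tauC / 1e7)
  expect_lt(abs(occ2 - 0.874), 3 * se)
})

test_that("brute-force first-passage averaging matches the analytic MFPT", {
  # >= 1000 escapes from the bound state, measured directly on hidden paths
  sim <- simulateJump(ppiReleasePreset(), nFrames = 4000, frameInterval = 1,
                      nTrajectories = 1200, seed = 202, start = 1L)
  fp <- vapply(sim$statePaths, function(p) {
    hit <- match(2L, p)
    if (is.na(hit)) NA_real_ else (hit - 1)  # frames until first release
  }, numeric(1))
  fp <- fp[!is.na(fp)]
  expect_gt(length(fp), 1000)
  se <- sd(fp) / sqrt(length(fp))
  # censoring at 4000 frames trims < 0.1% of the exponential tail
  expect_lt(abs(mean(fp) - 500), 3 * se + 2)
})

test_that("absorbing model stays in its start state", {
  m <- jumpModel(matrix(c(0, 0, 2.8833e-4, 0), 2, byrow = TRUE),
                 c(4, 15), c(0.8, 2.5))
  sim <- simulateJump(m, nFrames = 500, frameInterval = 1,
                      nTrajectories = 1, seed = 1, start = 1L)
  expect_true(all(sim$statePaths[[1]] == 1L))
  expect_match(sim$metadata$warnings, "never visited")
})

test_that("symmetric two-state model splits occupancy 50/50", {
  m <- jumpModel(matrix(c(0, 1, 1, 0), 2, byrow = TRUE), c(0, 1), c(1, 1))
  sim <- simulateJump(m, nFrames = 1e6, frameInterval = 1,
                      nTrajectories = 1, seed = 7)
  occ <- mean(sim$statePaths[[1]] == 1L)
  # binomial SE inflated by the lag-1 autocorrelation factor
  rho <- exp(-2)
  se <- sqrt(0.25 / 1e6) * sqrt((1 + rho) / (1 - rho))
  expect_lt(abs(occ - 0.5), 3 * se)
})

test_that("transition counts follow the Poisson-thinning estimate", {
  sim <- simulateJump(ppiReleasePreset(), nFrames = 1e4, frameInterval = 1,
                      nTrajectories = 100, seed = 2013)
  n12 <- 0
  timeIn1 <- 0
  for (p in sim$statePaths) {
    n12 <- n12 + sum(p[-length(p)] == 1L & p[-1] == 2L)
    timeIn1 <- timeIn1 + sum(p == 1L)
  }
  expected <- timeIn1 * 2.0e-3
  expect_lt(abs(n12 - expected), 3 * sqrt(expected))
})

test_that("jump simulation is bit-identical under a fixed seed and uses
           per-trajectory substreams", {
  a <- simulateJump(ppiReleasePreset(), 300, 1, 4, seed = 11)
  b <- simulateJump(ppiReleasePreset(), 300, 1, 4, seed = 11)
  expect_identical(a$statePaths, b$statePaths)
  expect_identical(lapply(a$trajectories, featureValues),
                   lapply(b$trajectories, featureValues))
  # substream rule seed + j - 1: trajectory 3 of seed 11 = trajectory 1 of 13
  c13 <- simulateJump(ppiReleasePreset(), 300, 1, 1, seed = 13)
  expect_identical(a$statePaths[[3]], c13$statePaths[[1]])
})

test_that("free diffusion has i.i.d. normal increments of variance 2 kT dt / g", {
  traj <- simulateLangevin(flatPotential(kT = 1.5), nFrames = 1e5,
                           timeStep = 0.01, friction = 2, seed = 3)
  inc <- diff(c(0, featureValues(traj)[, 1]))
  v <- 2 * 1.5 * 0.01 / 2
  seVar <- v * sqrt(2 / 1e5)
  expect_lt(abs(var(inc) - v), 3 * seVar)
  expect_lt(abs(mean(inc)), 3 * sqrt(v / 1e5))
})

test_that("symmetric double well is occupied 50/50 in the long run", {
  pot <- doubleWellPotential(barrier = 1, halfSeparation = 1, tilt = 0)
  traj <- simulateLangevin(pot, nFrames = 5e5, timeStep = 0.004, seed = 4)
  occ <- mean(featureValues(traj)[, 1] < 0)
  # ~1e3 barrier crossings at these settings; allow 3 x sqrt(2/crossings)/2
  expect_lt(abs(occ - 0.5), 0.06)
})

test_that("asymmetric Gaussian double well matches the Boltzmann quadrature", {
  pot <- gaussianWellPotential(centers = c(0, 1), depths = c(3, 2),
                               widths = c(0.3, 0.3), kT = 1)
  traj <- simulateLangevin(pot, nFrames = 1e6, timeStep = 0.003, seed = 5)
  x <- featureValues(traj)[, 1]
  divider <- potentialBarrier(pot)
  occRatio <- mean(x >= divider) / mean(x < divider)
  bp <- boltzmannPopulations(pot, divider)
  expect_lt(abs(occRatio - bp[2] / bp[1]) / (bp[2] / bp[1]), 0.05)
})

test_that("Langevin integrator enforces its preconditions and domain", {
  pot <- doubleWellPotential(barrier = 2, halfSeparation = 1)
  # per-step sd must stay below 1/10 of the well separation
  expect_error(simulateLangevin(pot, 10, timeStep = 0.5, seed = 1),
               "well separation")
  narrow <- doubleWellPotential(2, 1, bounds = c(-1.05, 1.05))
  expect_error(simulateLangevin(narrow, 1e4, 0.004, seed = 1),
               "left the domain .* at frame")
})

test_that("toy structures: rigid motion is removed exactly by superposition", {
  toy0 <- makeToyStructures(nFrames = 6, displacementSd = 0, seed = 9,
                            clusterProb = 0)   # one planted site only
  tr <- toy0$trajectory
  ref <- getFrame(tr, 1)
  for (f in 2:6) {
    r <- metricRMSD(getFrame(tr, f), ref, tr@alignmentSubset,
                    tr@metricSubset)
    expect_lt(r, 1e-8)
  }
})

test_that("toy structures: planted clusters are recovered by 2-center", {
  toy <- makeToyStructures(nFrames = 40, displacementSd = 0.5, seed = 10,
                           clusterSeparation = 10)
  cl <- kCenter(toy$trajectory, k = 2)
  expect_true(sameUpToPerm(crispAssignment(cl), toy$labels))
})

test_that("synthetic truth sidecar round-trips through the key-value file", {
  sim <- simulateJump(ppiReleasePreset(), 100, 1, 1, seed = 1)
  path <- withr::local_tempfile(fileext = ".txt")
  writeTruthSidecar(sim$truth, path)
  lines <- readLines(path)
  expect_true(any(grepl("^stationary=", lines)))
  st <- as.numeric(strsplit(sub("^stationary=", "",
                                grep("^stationary=", lines, value = TRUE)),
                            ",")[[1]])
  expect_equal(st, truthStationary(sim$truth), tolerance = 1e-12)
})
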