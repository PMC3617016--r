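# Transition counting (sliding window + dwell filter), ergodic trimming,
# transition matrix estimation, implied timescales, macrostate-count choice.

test_that("sliding-window counting reproduces hand-enumerated examples", {
  # path 0,0,1,1 (1-based: 1,1,2,2), lag 1, dwell 1: windows 1->1, 1->2, 2->2
  d <- discreteTrajectories(c(1L, 1L, 2L, 2L))
  N <- transitionCounts(countTransitions(d, 1))
  expect_equal(N, matrix(c(1, 0, 1, 1), 2))
  # path 0,1,0,0, lag 1, dwell 2: the 0->1 event is rejected (1 persists one
  # frame); 1->0 and the final truncated 0->0 are kept
  d2 <- discreteTrajectories(c(1L, 2L, 1L, 1L))
  N2 <- transitionCounts(countTransitions(d2, 1, dwellFrames = 2))
  expect_equal(N2, matrix(c(1, 1, 0, 0), 2))
  # constant path: only the diagonal, for any lag < length
  d3 <- discreteTrajectories(rep(3L, 5), nStates = 3)
  for (lag in 1:4) {
    N3 <- transitionCounts(countTransitions(d3, lag))
    expect_equal(sum(N3) - N3[3, 3], 0)
    expect_equal(N3[3, 3], 5 - lag)
  }
})

test_that("transitions are never counted across trajectory boundaries", {
  d <- discreteTrajectories(list(c(1L, 1L), c(2L, 2L)))
  N <- transitionCounts(countTransitions(d, 1))
  expect_equal(N[1, 2] + N[2, 1], 0)
  expect_warning(countTransitions(discreteTrajectories(list(c(1L, 2L), 1L)),
                                  1),
                 "shorter than the lag")
})

test_that("stepped (non-sliding) counting uses disjoint windows", {
  d <- discreteTrajectories(c(1L, 2L, 1L, 2L, 1L, 2L, 1L))
  slid <- transitionCounts(countTransitions(d, 2, sliding = TRUE))
  step <- transitionCounts(countTransitions(d, 2, sliding = FALSE))
  expect_equal(sum(slid), 5)
  expect_equal(sum(step), 3)
})

test_that("off-diagonal counts are non-increasing in the dwell window", {
  set.seed(10)
  P <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE)
  d <- discreteTrajectories(simChain(P, 3000, 1L))
  off <- vapply(1:5, function(dw) {
    N <- transitionCounts(countTransitions(d, 1, dwellFrames = dw))
    sum(N) - sum(diag(N))
  }, numeric(1))
  expect_true(all(diff(off) <= 0))
})

test_that("largest ergodic subset keeps the biggest strong component", {
  # block-diagonal 3 + 2: the 3-block is kept
  N <- matrix(0, 5, 5)
  N[1:3, 1:3] <- 5
  N[4:5, 4:5] <- 3
  erg <- largestErgodicSubset(asCountMatrix(N))
  expect_identical(stateLabels(erg), 1:3)
  # a one-way sink (counts in, none out) is removed
  N2 <- matrix(c(5, 5, 2, 2, 5, 1, 0, 0, 0), 3, byrow = TRUE)
  erg2 <- largestErgodicSubset(asCountMatrix(N2))
  expect_identical(stateLabels(erg2), 1:2)
  # fully connected counts are unchanged
  N3 <- matrix(1, 4, 4)
  expect_equal(transitionCounts(largestErgodicSubset(asCountMatrix(N3))), N3)
})

test_that("row normalization and the stationary eigenvector are exact", {
  m <- transitionModel(asCountMatrix(matrix(c(9, 1, 1, 9), 2, byrow = TRUE)))
  expect_equal(transitionProbs(m),
               matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE))
  expect_equal(stationaryDistribution(m), c(0.5, 0.5), tolerance = 1e-12)
  # detailed balance by hand: pi1 * 0.1 = pi2 * 0.05 -> pi = (1/3, 2/3)
  m2 <- transitionModel(asCountMatrix(matrix(c(180, 20, 10, 190), 2,
                                             byrow = TRUE)))
  expect_equal(stationaryDistribution(m2), c(1, 2) / 3, tolerance = 1e-10)
  expect_equal(as.numeric(stationaryDistribution(m2) %*%
                            transitionProbs(m2)),
               stationaryDistribution(m2), tolerance = 1e-12)
})

test_that("zero-count rows are refused with a pointer to ergodic trimming", {
  N <- matrix(c(1, 1, 0, 0), 2, byrow = TRUE)
  expect_error(transitionModel(asCountMatrix(N)), "largestErgodicSubset")
})

test_that("implied timescales recover the generating eigenvalue and are
           flat in lag for Markovian data", {
  set.seed(12)
  Tgen <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  paths <- lapply(1:30, function(i) simChain(Tgen, 2000, sample(1:2, 1)))
  d <- discreteTrajectories(paths, 2)
  its <- impliedTimescales(d, lags = c(1, 2, 4, 8))
  target <- -1 / log(0.8)
  expect_true(all(its$defined))
  expect_lt(max(abs(its$timescaleFrames - target)), 0.25 * target)
  expect_lt(diff(range(its$timescaleFrames)), 0.2 * target)
})

test_that("eigenvalue relation is exact on the generating matrix itself", {
  # Eq-style identity: -tau/log(mu) on T^tau reproduces the lag-1 timescale
  Tgen <- matrix(c(0.95, 0.05, 0.02, 0.98), 2, byrow = TRUE)
  mu1 <- sort(Re(eigen(Tgen)$values))[1]
  for (lag in c(1, 2, 4)) {
    Tlag <- Tgen
    if (lag > 1) for (i in 2:lag) Tlag <- Tlag %*% Tgen
    mu <- sort(Re(eigen(Tlag)$values))[1]
    expect_equal(-lag / log(mu), -1 / log(mu1), tolerance = 1e-12)
  }
})

test_that("oscillatory data yield flagged undefined timescales, not a crash", {
  d <- discreteTrajectories(rep(c(1L, 2L), 50))
  its <- impliedTimescales(d, lags = 1)
  expect_false(any(its$defined))
  expect_true(all(is.na(its$timescaleFrames)))
})

test_that("macrostate count comes from the largest timescale gap", {
  fake <- function(ts, lag = 5L) {
    out <- data.frame(lagFrames = lag, lagTime = lag, k = seq_along(ts) + 1L,
                      eigenvalue = NA_real_, timescaleFrames = ts,
                      timescaleTime = ts, defined = is.finite(ts))
    class(out) <- c("ImpliedTimescaleTable", "data.frame")
    out
  }
  # (100, 90, 5, 4): gap between 2nd and 3rd -> m = 3
  sel <- chooseMacrostateCount(fake(c(100, 90, 5, 4)), 5L)
  expect_identical(sel$m, 3L)
  expect_equal(which.max(sel$ratios), 2L)
  # (500, 5, 4): dominant first gap -> m = 2
  expect_identical(chooseMacrostateCount(fake(c(500, 5, 4)), 5L)$m, 2L)
  # single finite timescale: m = 2 by convention, flagged
  single <- chooseMacrostateCount(fake(c(42, NA)), 5L)
  expect_identical(single$m, 2L)
  expect_true(single$flagged)
  expect_error(chooseMacrostateCount(fake(c(NA_real_, NA_real_)), 5L),
               "no defined timescales")
})

test_that("every estimated model conserves probability", {
  set.seed(13)
  for (rep in 1:5) {
    n <- sample(3:6, 1)
    P <- randomStochastic(n)
    d <- discreteTrajectories(simChain(P, 4000, 1L), n)
    m <- transitionModel(largestErgodicSubset(countTransitions(d, 1)))
    expect_lt(max(abs(rowSums(transitionProbs(m)) - 1)), 1e-12)
    pi <- stationaryDistribution(m)
    expect_lt(abs(sum(pi) - 1), 1e-10)
    expect_lt(max(abs(pi %*% transitionProbs(m) - pi)), 1e-10)
    expect_lte(max(Mod(modelEigenvalues(m))), 1 + 1e-10)
  }
})
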