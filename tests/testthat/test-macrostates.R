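# PCCA+ lumping, macrostate models, MFPT solves, bootstrap, residence
# validation.

test_that("PCCA+ splits two weakly coupled blocks along the slow eigenvector", {
  set.seed(20)
  bt <- makeBlockT(c(2, 2), leak = 0.01)
  tm <- asTransitionModel(bt$T)
  chi <- pccaPlus(tm, 2)
  expect_equal(rowSums(chi), rep(1, 4), tolerance = 1e-9)
  expect_true(all(chi >= -1e-12))
  crisp <- apply(chi, 1, which.max)
  expect_true(sameUpToPerm(crisp, bt$blocks))
  # crisp split coincides with the sign split of the second eigenvector
  v2 <- Re(eigen(bt$T)$vectors[, 2])
  expect_true(sameUpToPerm(crisp, as.integer(v2 > 0) + 1L))
  # and with the exhaustive best 2-partition by metastability
  parts <- partitionsInto(4, 2)
  pi <- stationaryDistribution(tm)
  scores <- vapply(parts, function(a) metastability(bt$T, pi, a), numeric(1))
  expect_true(sameUpToPerm(crisp, parts[[which.max(scores)]]))
})

test_that("PCCA+ is equivariant under state relabeling", {
  set.seed(21)
  bt <- makeBlockT(c(3, 2), leak = 0.02)
  perm <- sample(5)
  Tp <- bt$T[perm, perm]
  crisp <- apply(pccaPlus(asTransitionModel(bt$T), 2), 1, which.max)
  crispP <- apply(pccaPlus(asTransitionModel(Tp), 2), 1, which.max)
  expect_true(sameUpToPerm(crispP, crisp[perm]))
})

test_that("m = n gives the identity lumping", {
  set.seed(22)
  bt <- makeBlockT(c(2, 2), leak = 0.02)
  chi <- pccaPlus(asTransitionModel(bt$T), 4)
  crisp <- apply(chi, 1, which.max)
  expect_identical(sort(crisp), 1:4)
})

test_that("symmetrized analysis counts avoid complex spectra", {
  # a strongly non-reversible cycle has complex eigenvalues
  Tc <- matrix(c(0.05, 0.9, 0.05,
                 0.05, 0.05, 0.9,
                 0.9, 0.05, 0.05), 3, byrow = TRUE)
  expect_error(pccaPlus(asTransitionModel(Tc), 2), "complex")
  N <- round(Tc * 1000)
  expect_silent(chi <- pccaPlus(asCountMatrix(N), 2, symmetrize = TRUE))
  expect_equal(rowSums(chi), rep(1, 3), tolerance = 1e-9)
})

test_that("lumping sums counts and stationary weight over members", {
  # identity assignment leaves the model unchanged
  set.seed(23)
  N <- matrix(rpois(9, 40) + 1, 3, 3)
  cm <- asCountMatrix(N)
  macroId <- lumpMacrostates(cm, 1:3)
  expect_equal(transitionCounts(macroId), N + 0)
  expect_equal(transitionProbs(macroId),
               transitionProbs(transitionModel(cm)), tolerance = 1e-12)
  # micro pi (0.25, 0.25, 0.5) lumped as {1,2},{3} -> (0.5, 0.5)
  Tm <- matrix(c(0.5, 0.3, 0.2,
                 0.3, 0.5, 0.2,
                 0.1, 0.1, 0.8), 3, byrow = TRUE)
  Nm <- round(diag(c(0.25, 0.25, 0.5)) %*% Tm * 4000)
  macro <- lumpMacrostates(asCountMatrix(Nm), c(1L, 1L, 2L))
  expect_equal(populations(macro), c(0.5, 0.5), tolerance = 1e-3)
  expect_equal(sum(populations(macro)), 1, tolerance = 1e-12)
  expect_error(lumpMacrostates(asCountMatrix(Nm), c(1L, 1L, 1L), NULL),
               NA)  # single macrostate is allowed at the lump level
  expect_error(lumpMacrostates(asCountMatrix(Nm), c(2L, 2L, 2L)),
               "empty macrostate")
})

test_that("planted two-block chain reproduces the generator escape
           probabilities after lumping", {
  set.seed(24)
  eps <- 0.02
  Tgen <- matrix(c(0.7 - eps, 0.3, eps / 2, eps / 2,
                   0.3, 0.7 - eps, eps / 2, eps / 2,
                   eps / 2, eps / 2, 0.7 - eps, 0.3,
                   eps / 2, eps / 2, 0.3, 0.7 - eps), 4, byrow = TRUE)
  d <- discreteTrajectories(simChain(Tgen, 60000, 1L), 4)
  erg <- largestErgodicSubset(countTransitions(d, 1))
  chi <- pccaPlus(erg, 2)
  macro <- lumpMacrostates(erg, chi)
  # block escape probability is eps by construction
  off <- transitionProbs(macro)[cbind(1:2, 2:1)]
  se <- sqrt(eps * (1 - eps) / 30000)
  expect_lt(max(abs(off - eps)), 4 * se)
})

test_that("MFPT linear solve matches the 2-state closed form and boundary
           condition", {
  P <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  M <- mfpt(P, lagTime = 4.5)
  expect_equal(M[1, 2], 4.5 / 0.1, tolerance = 1e-12)   # 45 ns
  expect_equal(diag(M), c(0, 0))
  set.seed(25)
  for (rep in 1:3) {
    Pr <- randomStochastic(sample(3:5, 1))
    expect_equal(diag(mfpt(Pr, 1)), rep(0, nrow(Pr)))
  }
})

test_that("MFPT solve agrees with Monte-Carlo first passage on a 3-state
           chain", {
  set.seed(26)
  P <- randomStochastic(3)
  exact <- mfpt(P, lagTime = 1)
  mc <- mcFirstPassage(P, 1, 3, nPaths = 2e4)
  expect_lt(abs(mc$mean - exact[1, 3]), 2 * mc$se + 1e-9)
})

test_that("reducible matrices are rejected by the MFPT solver", {
  P <- diag(2)
  expect_error(mfpt(P, 1), "reducible")
})

test_that("bootstrap of identical trajectories has zero spread and is
           reproducible", {
  set.seed(27)
  path <- simChain(matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE), 800, 1L)
  d <- discreteTrajectories(rep(list(path), 6), 2)
  b <- bootstrapMSM(d, c(1L, 2L), lagFrames = 1, nReplicates = 20, seed = 5)
  expect_equal(b$popSd, c(0, 0), tolerance = 1e-12)
  expect_equal(max(b$mfptSd), 0, tolerance = 1e-10)
  expect_identical(b$nDegenerate, 0L)
  b2 <- bootstrapMSM(d, c(1L, 2L), lagFrames = 1, nReplicates = 20, seed = 5)
  expect_identical(b$popDraws, b2$popDraws)
})

test_that("bootstrap spread is positive for heterogeneous trajectories and
           degenerate resamples are excluded", {
  set.seed(28)
  T1 <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, byrow = TRUE)
  d <- discreteTrajectories(list(simChain(T1, 500, 1L),
                                 simChain(T1, 500, 2L),
                                 rep(1L, 500)), 2)
  b <- bootstrapMSM(d, c(1L, 2L), lagFrames = 1, nReplicates = 60, seed = 6)
  expect_gt(max(b$popSd), 0)
  # resamples made only of the constant trajectory lose macrostate 2
  expect_gte(b$nDegenerate, 0L)
  expect_identical(b$nReplicates + b$nDegenerate, 60L)
})

test_that("residence probabilities: exact at n = 0 and Markov-consistent on
           exactly-Markov data", {
  set.seed(29)
  Tgen <- matrix(c(0.95, 0.05, 0.02, 0.98), 2, byrow = TRUE)
  paths <- lapply(1:40, function(i) simChain(Tgen, 1500, sample(1:2, 1)))
  d <- discreteTrajectories(paths, 2)
  erg <- largestErgodicSubset(countTransitions(d, 1))
  macro <- lumpMacrostates(erg, 1:2)
  val <- validateResidence(macro, d, multiples = 0:10,
                           microLabels = stateLabels(erg))
  at0 <- val$curves[val$curves$n == 0, ]
  expect_equal(at0$predicted, rep(1, 2))
  expect_equal(at0$observed, rep(1, 2))
  cv <- val$curves[val$curves$n > 0, ]
  se <- sqrt(pmax(cv$predicted * (1 - cv$predicted), 1e-12) / cv$nObs)
  expect_true(all(abs(cv$predicted - cv$observed) <= 3 * se))
})

test_that("a hidden slow state makes the residence check fail (negative
           control)", {
  T3 <- matrix(c(0.70, 0.295, 0.005,
                 0.295, 0.695, 0.010,
                 0.005, 0.010, 0.985), 3, byrow = TRUE)
  set.seed(30)
  paths <- lapply(1:40, function(i) simChain(T3, 2000, sample(1:3, 1)))
  d <- discreteTrajectories(paths, 3)
  erg <- largestErgodicSubset(countTransitions(d, 1))
  # wrong lumping {1}, {2,3} hides the slow 2<->3 process
  macro <- lumpMacrostates(erg, c(1L, 2L, 2L))
  val <- validateResidence(macro, d, 1:10, microLabels = stateLabels(erg))
  cv <- val$curves
  se <- sqrt(pmax(cv$predicted * (1 - cv$predicted), 1e-12) / cv$nObs)
  expect_gt(max(abs(cv$predicted - cv$observed) / se), 3)
})

test_that("macrostate tables serialize with units in the header", {
  set.seed(31)
  path <- simChain(matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE), 2000, 1L)
  d <- discreteTrajectories(path, 2, frameInterval = 2, timeUnit = "ns")
  erg <- largestErgodicSubset(countTransitions(d, 1))
  macro <- lumpMacrostates(erg, 1:2)
  dir <- withr::local_tempdir()
  files <- writeMacrostateTables(macro, dir)
  expect_true(all(file.exists(files)))
  expect_match(readLines(file.path(dir, "populations.tsv"), n = 1), "lag=2 ns")
  expect_match(readLines(file.path(dir, "mfpt.tsv"), n = 1), "ns")
})

test_that("discretization noise biases the macro MFPT at short lags and
           fades as the lag grows", {
  # overlapping emissions put a small fraction of released-state frames on
  # the bound side of any crisp boundary; each such frame fakes one escape
  # event, so the apparent escape probability is inflated by a roughly
  # lag-independent amount while the true escape probability grows with the
  # lag -- the relative MFPT bias must therefore shrink with the lag
  sim <- simulateJump(ppiReleasePreset(), nFrames = 10000, frameInterval = 1,
                      nTrajectories = 60, seed = 303)
  x <- unlist(lapply(sim$trajectories, function(t) featureValues(t)[, 1]))
  cl <- kCenter(x, k = 50)
  paths <- split(cl@assignment, rep(seq_len(60), each = 10000))
  d <- discreteTrajectories(paths, 50)
  ratios <- vapply(c(5L, 20L), function(lag) {
    erg <- largestErgodicSubset(suppressWarnings(countTransitions(d, lag)))
    macro <- lumpMacrostates(erg, pccaPlus(erg, 2))
    b <- which.min(vapply(1:2, function(A)
      min(cl@centerValues[, 1][stateLabels(erg)[macro@assignment == A]]),
      numeric(1)))
    mfpt(macro)[b, 3 - b] / 500
  }, numeric(1))
  expect_lt(ratios[1], ratios[2])        # short lag underestimates more
  # at lag 20 only ~150 physical escape events remain (~8% sampling sd),
  # so "close to the truth" means within ~2.5 sigma of it
  expect_lt(abs(ratios[2] - 1), 0.20)
  expect_lt(abs(ratios[1] - 1), 0.35)    # short-lag bias is bounded too
})
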