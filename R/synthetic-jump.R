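## Markov jump-process generator with exact ground truth.
##
## The hidden process is a continuous-time Markov chain observed every
## frameInterval; the observed reaction coordinate is drawn from the current
## state's Gaussian emission distribution. For 2 states the per-frame
## transition matrix is the exact matrix exponential of the rate matrix; for
## more states a first-order competitive-exponential discretization is used
## (with a warning when per-frame exit probabilities get large).

#' Rate (generator) matrix of a JumpModel
#' @param model a \linkS4class{JumpModel}.
#' @return matrix Q with off-diagonal rates and diagonal -rowSums.
#' @keywords internal
rateMatrix <- function(model) {
  Q <- model@rates
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Exact stationary distribution of a continuous-time jump model
#'
#' Solves pi Q = 0, sum(pi) = 1 for the generator Q of an ergodic model.
#'
#' @param model a \linkS4class{JumpModel}.
#' @return numeric vector of stationary probabilities.
#' @export
jumpStationary <- function(model) {
  Q <- rateMatrix(model)
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  pi <- qr.solve(A, b)
  if (any(pi <= 1e-12))
    stop("model is not ergodic: stationary distribution not strictly positive")
  pi / sum(pi)
}

#' @rdname truthStationary
#' @export
setMethod("truthStationary", "JumpModel", function(x) jumpStationary(x))

#' Exact pairwise mean first passage times of a jump model
#'
#' For each target state f the MFPTs m(i -> f) solve the linear system
#' \code{Q[-f, -f] m = -1} with \code{m(f -> f) = 0}; in the 2-state case this
#' reduces to \code{MFPT(1 -> 2) = 1 / k12}.
#'
#' @param model a \linkS4class{JumpModel}.
#' @return matrix of MFPTs in the model's time unit; diagonal 0.
#' @export
jumpMFPT <- function(model) {
  Q <- rateMatrix(model)
  n <- nrow(Q)
  M <- matrix(0, n, n)
  for (f in seq_len(n)) {
    keep <- setdiff(seq_len(n), f)
    M[keep, f] <- solve(Q[keep, keep, drop = FALSE], rep(-1, length(keep)))
  }
  M
}

#' Two-state preset calibrated to the RNAP PPi-release observables
#'
#' Returns the calibrated two-state exchange model between the active-site
#' bound basin and the elongated secondary-channel (released) basin:
#' k(bound -> released) = 2.0e-3 / ns and k(released -> bound) = 2.8833e-4 /
#' ns, so the exact stationary probabilities are (0.12600, 0.87400) and the
#' exact bound -> released MFPT is 500 ns. The observed coordinate mimics the
#' PPi--Mg2+A distance: emission means 4.0 A (bound) and 15.0 A (released)
#' with sds 0.8 A and 2.5 A, overlapping enough in the tails to exercise the
#' clustering stage nontrivially.
#'
#' @return A \linkS4class{JumpModel} with states (1 = bound, 2 = released).
#' @examples
#' preset <- ppiReleasePreset()
#' truthStationary(preset)        # 0.126, 0.874
#' jumpMFPT(preset)[1, 2]         # 500 ns
#' @export
ppiReleasePreset <- function() {
  rates <- matrix(c(0, 2.0e-3,
                    2.8833e-4, 0), nrow = 2, byrow = TRUE)
  jumpModel(rates, emissionMean = c(4.0, 15.0), emissionSd = c(0.8, 2.5),
            timeUnit = "ns")
}

## Per-frame transition probability matrix of the discretized chain.
.frameTransitionMatrix <- function(model, frameInterval) {
  n <- model@nStates
  R <- model@rates
  if (n == 2L) {
    k12 <- R[1, 2]; k21 <- R[2, 1]
    lam <- k12 + k21
    if (lam == 0) return(diag(2))
    e <- exp(-lam * frameInterval)
    P <- matrix(c(k21 + k12 * e, k12 * (1 - e),
                  k21 * (1 - e), k12 + k21 * e) / lam,
                nrow = 2, byrow = TRUE)
    return(P)
  }
  P <- 1 - exp(-R * frameInterval)
  diag(P) <- 0
  exitP <- rowSums(P)
  if (any(exitP > 1))
    stop("frame interval too coarse: per-frame exit probability exceeds 1")
  if (max(exitP) > 0.1)
    warning(sprintf(
      "first-order discretization: max per-frame exit probability %.3f > 0.1",
      max(exitP)))
  diag(P) <- 1 - exitP
  P
}

## Simulate one hidden discrete-chain path of length n from transition
## matrix P via geometric run lengths (exact for the discretized chain).
.simulateHiddenPath <- function(P, n, start) {
  nStates <- nrow(P)
  exitP <- 1 - diag(P)
  out <- integer(n)
  pos <- 0L
  s <- start
  while (pos < n) {
    run <- if (exitP[s] <= 0) n - pos else min(1L + rgeom(1L, exitP[s]), n - pos)
    out[(pos + 1L):(pos + run)] <- s
    pos <- pos + run
    if (pos < n) {
      p <- P[s, ]; p[s] <- 0
      s <- sample.int(nStates, 1L, prob = p)
    }
  }
  out
}

#' Simulate trajectories from a Markov jump model
#'
#' Evolves the hidden state at the given frame interval (exact matrix
#' exponential discretization for 2-state models, first-order competitive
#' exponential probabilities otherwise) and emits the observed coordinate
#' from the current state's Gaussian emission distribution. One global seed
#' expands to per-trajectory substreams by the splitting rule
#' \code{seed + trajectoryIndex - 1}, so trajectory j is bit-identical no
#' matter how many others are generated.
#'
#' @param model a \linkS4class{JumpModel}.
#' @param nFrames frames per trajectory (>= 2).
#' @param frameInterval time between frames (> 0), in the model's time unit.
#' @param nTrajectories number of independent trajectories.
#' @param seed integer seed.
#' @param start initial state: \code{"stationary"} (sampled from the exact
#'   stationary distribution, per trajectory) or a fixed state index.
#' @param coordName name of the emitted coordinate, default \code{"d1"}.
#' @return list with components \code{statePaths} (list of hidden integer
#'   paths), \code{trajectories} (list of \linkS4class{FeatureTrajectory}),
#'   \code{truth} (a \linkS4class{SyntheticTruth}) and \code{metadata}
#'   (warnings such as unvisited states).
#' @examples
#' sim <- simulateJump(ppiReleasePreset(), nFrames = 500, frameInterval = 1,
#'                     nTrajectories = 2, seed = 1)
#' truthStationary(sim$truth)
#' @export
simulateJump <- function(model, nFrames, frameInterval, nTrajectories = 1L,
                         seed = 1L, start = "stationary", coordName = "d1") {
  stopifnot(nFrames >= 2, frameInterval > 0, nTrajectories >= 1)
  P <- .frameTransitionMatrix(model, frameInterval)
  n <- model@nStates
  ergodic <- tryCatch({jumpStationary(model); TRUE},
                      error = function(e) FALSE)
  pi0 <- if (ergodic) jumpStationary(model) else NULL
  if (identical(start, "stationary") && !ergodic)
    stop("cannot draw stationary start states from a non-ergodic model")
  statePaths <- vector("list", nTrajectories)
  trajs <- vector("list", nTrajectories)
  for (j in seq_len(nTrajectories)) {
    set.seed(as.integer(seed) + j - 1L)
    s0 <- if (identical(start, "stationary"))
      sample.int(n, 1L, prob = pi0) else as.integer(start)
    path <- .simulateHiddenPath(P, nFrames, s0)
    x <- rnorm(nFrames, mean = model@emissionMean[path],
               sd = model@emissionSd[path])
    statePaths[[j]] <- path
    trajs[[j]] <- featureTrajectory(x, frameInterval, model@timeUnit,
                                    source = sprintf("jump-sim %d", j),
                                    coordName = coordName)
  }
  visited <- sort(unique(unlist(lapply(statePaths, unique))))
  metadata <- list(warnings = character())
  if (length(visited) < n)
    metadata$warnings <- sprintf(
      "states never visited: %s (increase nTrajectories or nFrames)",
      paste(setdiff(seq_len(n), visited), collapse = ", "))
  truth <- new("SyntheticTruth",
               stationary = if (ergodic) pi0 else rep(NA_real_, n),
               mfptMatrix = if (ergodic) jumpMFPT(model) else
                 matrix(0, n, n),
               params = list(rates = model@rates,
                             emissionMean = model@emissionMean,
                             emissionSd = model@emissionSd,
                             frameInterval = frameInterval,
                             nFrames = nFrames,
                             nTrajectories = nTrajectories,
                             timeUnit = model@timeUnit),
               seed = as.integer(seed))
  list(statePaths = statePaths, trajectories = trajs, truth = truth,
       metadata = metadata)
}
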