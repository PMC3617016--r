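# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the package's own code paths wherever they serve
# as a cross-check (brute force, enumeration, quadrature, simulation).

# Simulate a discrete Markov chain path step by step (naive reference
# simulator, independent of the package's run-length generator).
simChain <- function(T, n, s0) {
  out <- integer(n)
  s <- s0
  for (t in seq_len(n)) {
    out[t] <- s
    s <- sample.int(nrow(T), 1L, prob = T[s, ])
  }
  out
}

# Monte-Carlo mean first passage time i -> f for a row-stochastic matrix,
# vectorized over paths; returns mean, standard error and path count.
mcFirstPassage <- function(P, i, f, nPaths = 1e5, maxSteps = 1e6) {
  n <- nrow(P)
  cur <- rep(i, nPaths)
  steps <- integer(nPaths)
  active <- rep(TRUE, nPaths)
  it <- 0L
  while (any(active)) {
    it <- it + 1L
    if (it > maxSteps) stop("first-passage simulation did not absorb")
    new <- cur
    for (s in unique(cur[active])) {
      sel <- active & cur == s
      new[sel] <- sample.int(n, sum(sel), replace = TRUE, prob = P[s, ])
    }
    cur <- new
    steps[active] <- steps[active] + 1L
    active <- active & cur != f
  }
  list(mean = mean(steps), se = stats::sd(steps) / sqrt(nPaths))
}

# Random dense row-stochastic matrix (strictly positive => irreducible).
randomStochastic <- function(n) {
  P <- matrix(stats::runif(n * n), n, n)
  P / rowSums(P)
}

# Reversible block transition matrix with m metastable blocks and the given
# inter-block leakage factor on the symmetric weights.
makeBlockT <- function(sizes, leak) {
  n <- sum(sizes)
  blk <- rep(seq_along(sizes), sizes)
  W <- matrix(stats::runif(n * n, 0.5, 1), n, n)
  W <- (W + t(W)) / 2
  off <- outer(blk, blk, "!=")
  W[off] <- W[off] * leak
  list(T = W / rowSums(W), blocks = blk)
}

# All partitions of 1..n into exactly m non-empty groups, in canonical
# (first-occurrence) labelling.
partitionsInto <- function(n, m) {
  res <- list()
  rec <- function(assign, used) {
    i <- length(assign) + 1L
    if (i > n) {
      if (used == m) res[[length(res) + 1L]] <<- assign
      return(invisible())
    }
    for (g in seq_len(min(used + 1L, m))) rec(c(assign, g), max(used, g))
  }
  rec(integer(), 0L)
  res
}

# Metastability of a crisp partition: sum over groups of the pi-weighted
# within-group transition probability.
metastability <- function(T, pi, assign) {
  s <- 0
  for (A in seq_len(max(assign))) {
    ia <- which(assign == A)
    s <- s + sum(pi[ia] %*% T[ia, ia, drop = FALSE]) / sum(pi[ia])
  }
  s
}

# TRUE when two labelings describe the same partition up to label names.
sameUpToPerm <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# Wrap a bare row-stochastic matrix as a TransitionModel (for feeding
# matrix-level fixtures into model-consuming code).
asTransitionModel <- function(T, lagFrames = 1L, frameInterval = 1,
                              timeUnit = "ns") {
  le <- eigen(t(T))
  p <- Re(le$vectors[, which.min(Mod(le$values - 1))])
  p <- p / sum(p)
  ev <- eigen(T, only.values = TRUE)$values
  ord <- order(-Mod(ev), -Re(ev))
  new("TransitionModel", probs = T, lagFrames = as.integer(lagFrames),
      stationary = p, eigenvalues = as.complex(ev[ord]),
      stateLabels = seq_len(nrow(T)), frameInterval = frameInterval,
      timeUnit = timeUnit)
}

# CountMatrix from a bare count matrix.
asCountMatrix <- function(N, lagFrames = 1L, dwellFrames = 1L,
                          sliding = TRUE, frameInterval = 1,
                          timeUnit = "ns") {
  new("CountMatrix", counts = N, lagFrames = as.integer(lagFrames),
      dwellFrames = as.integer(dwellFrames), sliding = sliding,
      stateLabels = seq_len(nrow(N)), frameInterval = frameInterval,
      timeUnit = timeUnit)
}

# Brute-force optimal k-center radius by enumerating all center subsets.
bruteForceKCenterRadius <- function(pts, k) {
  D <- as.matrix(stats::dist(pts))
  combs <- utils::combn(nrow(pts), k)
  opt <- Inf
  for (ci in seq_len(ncol(combs))) {
    r <- max(apply(D[, combs[, ci], drop = FALSE], 1, min))
    opt <- min(opt, r)
  }
  opt
}

# Best RMSD over proper rotations by multi-start quasi-Newton optimization
# on Euler angles (independent oracle for the Kabsch solution).
bruteForceFitRMSD <- function(mobile, reference, subset) {
  rotZ <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0,
                               0, 0, 1), 3, 3, byrow = TRUE)
  rotY <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0,
                               -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
  A <- mobile[subset, , drop = FALSE]
  B <- reference[subset, , drop = FALSE]
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  obj <- function(ang) {
    R <- rotZ(ang[1]) %*% rotY(ang[2]) %*% rotZ(ang[3])
    sqrt(mean(rowSums((A0 %*% t(R) - B0)^2)))
  }
  best <- Inf
  for (s in seq_len(40)) {
    start <- stats::runif(3, 0, 2 * pi)
    fit <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}
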