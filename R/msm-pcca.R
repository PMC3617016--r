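## PCCA+ metastable lumping.
##
## Robust Perron Cluster Cluster Analysis: the rows of the top-m right
## eigenvectors of a reversible transition matrix lie (approximately) in an
## (m-1)-simplex whose vertices correspond to the m metastable sets. The
## inner-simplex construction picks m maximally spread rows as vertices,
## maps all rows into the membership simplex by the linear transform sending
## the vertex rows to the unit vectors, and repairs small infeasibilities by
## projection (clip at 0, renormalize rows).
##
## Raw sliding-window counts need not be reversible; by default the analysis
## matrix is built from the symmetrized counts (N + t(N)) / 2, which
## guarantees a real spectrum. Populations and MFPTs are always computed
## from the raw-count model, never from the symmetrized one.

.pccaMemberships <- function(T, m) {
  es <- .sortedEigen(T)
  vals <- es$values[seq_len(m)]
  if (any(abs(Im(vals)) > 1e-8))
    stop(paste("complex eigenvalues among the top", m,
               "-- build the analysis matrix from symmetrized counts",
               "(symmetrize = TRUE)"))
  X <- Re(es$vectors[, seq_len(m), drop = FALSE])
  X[, 1] <- 1                                 # constant eigenvector
  n <- nrow(X)
  if (m > n) stop("more macrostates than microstates")
  ## vertex search: maximally spread rows
  idx <- integer(m)
  Y <- X
  idx[1] <- which.max(rowSums(Y^2))
  Y <- sweep(Y, 2, Y[idx[1], ])
  if (m > 1) {
    for (j in 2:m) {
      nrm <- sqrt(rowSums(Y^2))
      idx[j] <- which.max(nrm)
      v <- Y[idx[j], ] / nrm[idx[j]]
      Y <- Y - (Y %*% v) %*% t(v)
    }
  }
  A <- solve(X[idx, , drop = FALSE])
  chi <- X %*% A
  chi[chi < 0] <- 0                            # feasibility repair
  chi / rowSums(chi)
}

#' PCCA+ fuzzy lumping of microstates into macrostates
#'
#' @param x the model to lump: a \linkS4class{CountMatrix} (recommended; the
#'   analysis matrix is the row-normalized symmetrized counts when
#'   \code{symmetrize = TRUE}) or a \linkS4class{TransitionModel} (used
#'   as-is; errors if the top-m eigenvalues are complex).
#' @param m number of macrostates (>= 2, or n for the identity lumping).
#' @param symmetrize build the analysis matrix from \code{(N + t(N)) / 2}
#'   (default TRUE; only meaningful for CountMatrix input). Populations and
#'   MFPTs downstream always come from the raw-count model.
#' @return fuzzy membership matrix chi (microstate x macrostate, rows sum to
#'   1, entries >= 0). The crisp lumping is \code{apply(chi, 1, which.max)};
#'   for m = 2 it coincides with the sign split of the second eigenvector.
#' @examples
#' N <- matrix(c(90, 10, 1, 0, 10, 90, 0, 1,
#'               1, 0, 90, 10, 0, 1, 10, 90), 4, 4, byrow = TRUE)
#' cm <- new("CountMatrix", counts = N, lagFrames = 1L, dwellFrames = 1L,
#'           sliding = TRUE, stateLabels = 1:4, frameInterval = 1,
#'           timeUnit = "ns")
#' chi <- pccaPlus(cm, 2)
#' apply(chi, 1, which.max)
#' @export
pccaPlus <- function(x, m, symmetrize = TRUE) {
  m <- as.integer(m)
  if (m < 2L) stop("m must be >= 2")
  if (is(x, "CountMatrix")) {
    N <- x@counts
    if (symmetrize) N <- (N + t(N)) / 2
    rs <- rowSums(N)
    if (any(rs == 0)) stop("zero row in analysis counts; trim first")
    T <- N / rs
  } else if (is(x, "TransitionModel")) {
    T <- x@probs
  } else stop("x must be a CountMatrix or TransitionModel")
  .pccaMemberships(T, m)
}
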