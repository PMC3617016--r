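## Transition counting and transition-matrix estimation.
##
## Counts are taken with a sliding window (every start frame) or stepped
## window (every lag-th frame), never across trajectory boundaries. The
## re-crossing (dwell) filter implements the rule that a transition into
## state j is only counted if the path stays in j for at least dwellFrames
## frames (truncated at the trajectory end); it applies to self-transitions
## too. At the native 2 ps save interval the 50 ps rule is dwellFrames = 25,
## but dwell is always configured in frames so a different save interval
## cannot silently change semantics.

## Remaining run length at each position of an integer path.
.remainingRun <- function(path) {
  r <- rle(path)
  ends <- cumsum(r$lengths)
  rep(ends, r$lengths) - seq_along(path) + 1L
}

.countOnePath <- function(path, nStates, lag, dwell, sliding) {
  L <- length(path)
  if (L <= lag) return(NULL)
  starts <- if (sliding) seq_len(L - lag) else seq(1L, L - lag, by = lag)
  tt <- starts + lag
  rem <- .remainingRun(path)
  need <- pmin(dwell, L - tt + 1L)
  ok <- rem[tt] >= need
  i <- path[starts[ok]]
  j <- path[tt[ok]]
  tabulate((j - 1L) * nStates + i, nbins = nStates * nStates)
}

#' Count lagged transitions with a re-crossing (dwell) filter
#'
#' For every start frame t (step 1 if sliding, step \code{lagFrames}
#' otherwise) with \code{t + lagFrames} inside the same trajectory, the
#' transition \code{s(t) -> s(t + lagFrames)} is counted iff the destination
#' state persists for at least \code{dwellFrames} frames from
#' \code{t + lagFrames} on (the dwell check truncates to the frames available
#' before the trajectory end). Transitions are never counted across
#' trajectory boundaries; a trajectory shorter than the lag contributes zero
#' counts with a warning.
#'
#' @param dtrajs a \linkS4class{DiscreteTrajectorySet}.
#' @param lagFrames lag in frames (>= 1).
#' @param dwellFrames minimum dwell in frames (>= 1; 1 disables the filter).
#' @param sliding sliding-window counting, default TRUE.
#' @return A \linkS4class{CountMatrix}.
#' @examples
#' d <- discreteTrajectories(c(1L, 1L, 2L, 2L))
#' transitionCounts(countTransitions(d, 1))
#' @export
countTransitions <- function(dtrajs, lagFrames, dwellFrames = 1L,
                             sliding = TRUE) {
  stopifnot(is(dtrajs, "DiscreteTrajectorySet"),
            lagFrames >= 1, dwellFrames >= 1)
  lagFrames <- as.integer(lagFrames)
  dwellFrames <- as.integer(dwellFrames)
  n <- dtrajs@nStates
  acc <- numeric(n * n)
  short <- 0L
  for (p in dtrajs@paths) {
    one <- .countOnePath(p, n, lagFrames, dwellFrames, sliding)
    if (is.null(one)) short <- short + 1L else acc <- acc + one
  }
  if (short > 0L)
    warning(sprintf(
      "%d trajectory(ies) shorter than the lag contributed zero counts",
      short))
  N <- matrix(acc, n, n)
  new("CountMatrix", counts = N, lagFrames = lagFrames,
      dwellFrames = dwellFrames, sliding = sliding,
      stateLabels = seq_len(n), frameInterval = dtrajs@frameInterval,
      timeUnit = dtrajs@timeUnit)
}

## Per-trajectory count matrices (for trajectory bootstrap resampling;
## counts are additive over trajectories).
.perTrajectoryCounts <- function(dtrajs, lagFrames, dwellFrames = 1L,
                                 sliding = TRUE) {
  n <- dtrajs@nStates
  lapply(dtrajs@paths, function(p) {
    one <- .countOnePath(p, n, as.integer(lagFrames),
                         as.integer(dwellFrames), sliding)
    if (is.null(one)) matrix(0, n, n) else matrix(one, n, n)
  })
}

#' Restrict a count matrix to its largest strongly connected component
#'
#' The master-equation machinery requires an irreducible chain; states
#' outside the largest strongly connected component of the directed count
#' graph (edges where N[i, j] > 0) are dropped, and the mapping back to the
#' original labels is retained in \code{stateLabels}.
#'
#' @param counts a \linkS4class{CountMatrix}.
#' @return A trimmed \linkS4class{CountMatrix}; \code{stateLabels(x)} maps
#'   its rows to the original microstate labels.
#' @export
largestErgodicSubset <- function(counts) {
  stopifnot(is(counts, "CountMatrix"))
  N <- counts@counts
  present <- which(rowSums(N) + colSums(N) > 0)
  if (!length(present)) stop("count matrix is empty: no observed transitions")
  adj <- (N[present, present, drop = FALSE] > 0) * 1
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {                     # tie: keep most counts
    tot <- vapply(best, function(b) {
      idx <- present[comp$membership == b]
      sum(N[idx, idx])
    }, numeric(1))
    best <- best[which.max(tot)]
  }
  keep <- present[comp$membership == best]
  new("CountMatrix", counts = N[keep, keep, drop = FALSE],
      lagFrames = counts@lagFrames, dwellFrames = counts@dwellFrames,
      sliding = counts@sliding,
      stateLabels = counts@stateLabels[keep],
      frameInterval = counts@frameInterval, timeUnit = counts@timeUnit)
}

## Eigenvalues sorted by modulus (desc), ties by real part (desc) then index.
.sortedEigen <- function(T) {
  e <- eigen(T)
  ord <- order(-Mod(e$values), -Re(e$values), seq_along(e$values))
  list(values = as.complex(e$values[ord]),
       vectors = e$vectors[, ord, drop = FALSE])
}

#' Estimate a transition model from counts by row normalization
#'
#' \code{T[i, j] = N[i, j] / sum_j N[i, j]}. The stationary distribution is
#' the dominant left eigenvector of T normalized to sum 1 (the fixed point of
#' the master equation), not the row-count marginal. Eigenvalues are sorted
#' by modulus with a deterministic tie-break.
#'
#' @param counts a \linkS4class{CountMatrix} with every row sum > 0
#'   (guaranteed after \code{\link{largestErgodicSubset}}).
#' @return A \linkS4class{TransitionModel}.
#' @examples
#' d <- discreteTrajectories(rep(c(1L, 1L, 2L, 2L), 25))
#' m <- transitionModel(largestErgodicSubset(countTransitions(d, 1)))
#' stationaryDistribution(m)
#' @export
transitionModel <- function(counts) {
  stopifnot(is(counts, "CountMatrix"))
  N <- counts@counts
  rs <- rowSums(N)
  if (any(rs == 0))
    stop("count matrix has zero rows; apply largestErgodicSubset() first")
  T <- N / rs
  le <- eigen(t(T))
  iUnit <- which.min(Mod(le$values - 1))
  if (Mod(le$values[iUnit] - 1) > 1e-8)
    stop("no eigenvalue 1 found; the chain appears reducible")
  pi <- Re(le$vectors[, iUnit])
  pi <- pi / sum(pi)
  if (any(pi < -1e-10))
    stop("dominant left eigenvector is not non-negative; chain may be reducible")
  pi <- pmax(pi, 0)
  pi <- pi / sum(pi)
  ev <- .sortedEigen(T)$values
  ev[Mod(ev) > 1] <- ev[Mod(ev) > 1] / Mod(ev[Mod(ev) > 1])  # clip roundoff
  new("TransitionModel", probs = T, lagFrames = counts@lagFrames,
      stationary = pi, eigenvalues = ev,
      stateLabels = counts@stateLabels,
      frameInterval = counts@frameInterval, timeUnit = counts@timeUnit)
}

#' Serialize a count or transition matrix as TSV with a unit header
#' @param x a \linkS4class{CountMatrix} or \linkS4class{TransitionModel}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeMatrixTSV <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (is(x, "CountMatrix")) {
    writeLines(sprintf(
      "# counts lag_frames=%d lag_time=%g%s dwell_frames=%d sliding=%s states=%s",
      x@lagFrames, x@lagFrames * x@frameInterval, x@timeUnit, x@dwellFrames,
      x@sliding, paste(x@stateLabels, collapse = ",")), con)
    M <- x@counts
  } else {
    writeLines(sprintf(
      "# transition_probabilities lag_frames=%d lag_time=%g%s states=%s",
      x@lagFrames, x@lagFrames * x@frameInterval, x@timeUnit,
      paste(x@stateLabels, collapse = ",")), con)
    M <- x@probs
  }
  write.table(M, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
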