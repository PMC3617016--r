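## Implied timescales and macrostate-count selection.
##
## The implied timescale of the k-th eigenvalue mu_k of the transition matrix
## estimated at lag tau is tau_k = -tau / ln(mu_k). For a Markovian model the
## curve is flat in tau (mu(n tau) = mu(tau)^n cancels); the lag at which the
## curves plateau is the smallest usable model lag. One clear gap in the
## timescale spectrum separates the slow inter-macrostate processes from the
## fast intra-state ones and fixes the number of macrostates.

#' Implied timescales across a set of lags
#'
#' For each lag, builds counts -> largest ergodic subset -> transition
#' matrix -> eigenvalues, and reports \code{-lag / log(mu_k)} for the
#' \code{nTimescales} largest non-unit eigenvalues. Complex or non-positive
#' eigenvalues yield an undefined (NA) timescale with \code{defined = FALSE};
#' they are flagged, never silently dropped.
#'
#' @param dtrajs a \linkS4class{DiscreteTrajectorySet}.
#' @param lags integer vector of lags in frames (all >= 1).
#' @param nTimescales how many timescales to report per lag, default 1.
#' @param dwellFrames,sliding counting options, see
#'   \code{\link{countTransitions}}.
#' @return A data frame of class \code{ImpliedTimescaleTable} with columns
#'   \code{lagFrames}, \code{lagTime}, \code{k} (2 = slowest process),
#'   \code{eigenvalue} (real part), \code{timescaleFrames},
#'   \code{timescaleTime} and \code{defined}.
#' @examples
#' sim <- simulateJump(ppiReleasePreset(), 2000, 1, 5, seed = 7)
#' d <- discreteTrajectories(sim$statePaths)
#' impliedTimescales(d, lags = c(1, 2, 5))
#' @export
impliedTimescales <- function(dtrajs, lags, nTimescales = 1L,
                              dwellFrames = 1L, sliding = TRUE) {
  stopifnot(all(lags >= 1))
  rows <- list()
  for (lag in as.integer(lags)) {
    counts <- suppressWarnings(
      countTransitions(dtrajs, lag, dwellFrames, sliding))
    model <- transitionModel(largestErgodicSubset(counts))
    ev <- modelEigenvalues(model)[-1]          # drop the unit eigenvalue
    nAvail <- min(nTimescales, length(ev))
    for (k in seq_len(nAvail)) {
      mu <- ev[k]
      isReal <- abs(Im(mu)) <= 1e-10
      usable <- isReal && Re(mu) > 0 && Re(mu) < 1
      tsf <- if (usable) -lag / log(Re(mu)) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        lagFrames = lag,
        lagTime = lag * dtrajs@frameInterval,
        k = k + 1L,
        eigenvalue = if (isReal) Re(mu) else NA_real_,
        timescaleFrames = tsf,
        timescaleTime = tsf * dtrajs@frameInterval,
        defined = usable)
    }
    if (nAvail < nTimescales)
      rows[[length(rows) + 1L]] <- data.frame(
        lagFrames = lag, lagTime = lag * dtrajs@frameInterval,
        k = NA_integer_, eigenvalue = NA_real_,
        timescaleFrames = NA_real_, timescaleTime = NA_real_,
        defined = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "timeUnit") <- dtrajs@timeUnit
  class(out) <- c("ImpliedTimescaleTable", "data.frame")
  out
}

#' Choose the macrostate count from the timescale spectrum
#'
#' The number of metastable states is set by the clearest gap in the sorted
#' implied-timescale spectrum at the chosen lag:
#' \code{m = 1 + argmax_k tau_k / tau_(k+1)} over the finite timescales. With
#' a single finite timescale the convention is m = 2 (one slow process
#' separates two states), flagged.
#'
#' @param table an \code{ImpliedTimescaleTable}.
#' @param lagFrames the lag (frames) at which to read the spectrum.
#' @return list with \code{m}, \code{ratios} (the full gap-ratio list for
#'   inspection), \code{timescales} and \code{flagged}.
#' @export
chooseMacrostateCount <- function(table, lagFrames) {
  sub <- table[table$lagFrames == lagFrames & table$defined, , drop = FALSE]
  if (!nrow(sub)) stop("no defined timescales at the requested lag")
  ts <- sort(sub$timescaleFrames, decreasing = TRUE)
  if (length(ts) == 1L)
    return(list(m = 2L, ratios = numeric(), timescales = ts, flagged = TRUE))
  ratios <- ts[-length(ts)] / ts[-1]
  list(m = 1L + which.max(ratios), ratios = ratios, timescales = ts,
       flagged = FALSE)
}
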