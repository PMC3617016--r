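## Potential-of-mean-force projection.
##
## F(bin) = -ln(w(bin) / max_bin w) in kT units, minimum shifted to zero.
## Two weighting modes: uniform (raw histogram) and MSM-reweighted, where
## every frame of microstate i carries weight pi_i / (number of frames in i),
## so each microstate contributes exactly its equilibrium probability. The
## MSM mode is the default because seeding trajectories are generally not
## equilibrium-distributed.

#' Project trajectories onto a 1D or 2D potential of mean force
#'
#' @param features a \linkS4class{FeatureTrajectory} or list of them; all
#'   must carry the projected coordinate(s).
#' @param coords one or two coordinate names to project on (e.g. \code{"d1"}
#'   or \code{c("d1", "d2")}).
#' @param bins bin edges: a vector (1D), a list of vectors (2D), or a single
#'   count per dimension (default 50 equal-width bins over the data range).
#' @param weighting \code{"msm"} (default) or \code{"uniform"}.
#' @param microAssignment integer microstate label per frame (concatenated
#'   over trajectories in order); required for msm weighting. Frames whose
#'   label is absent from \code{pi} (outside the ergodic subset) are dropped
#'   and counted in the result.
#' @param pi named or indexed stationary probabilities per microstate label
#'   (from the micro \linkS4class{TransitionModel}: \code{stationaryDistribution}
#'   indexed by \code{stateLabels}).
#' @param kTScale multiply free energies by this factor (report in units of
#'   kTScale * kT), default 1.
#' @return A \linkS4class{PMFGrid}; attribute \code{droppedFrames} counts
#'   frames outside the ergodic subset.
#' @examples
#' ft <- featureTrajectory(rnorm(5000), frameInterval = 1, coordName = "x")
#' pmfProject(ft, "x", bins = 25, weighting = "uniform")
#' @export
pmfProject <- function(features, coords, bins = 50,
                       weighting = c("msm", "uniform"),
                       microAssignment = NULL, pi = NULL, kTScale = 1) {
  weighting <- match.arg(weighting)
  if (is(features, "FeatureTrajectory")) features <- list(features)
  vals <- do.call(rbind, lapply(features, function(tr) {
    v <- featureValues(tr)
    miss <- setdiff(coords, colnames(v))
    if (length(miss))
      stop("coordinate(s) not in trajectory: ", paste(miss, collapse = ", "))
    v[, coords, drop = FALSE]
  }))
  nFramesTotal <- nrow(vals)
  ndim <- length(coords)
  if (!ndim %in% 1:2) stop("project on one or two coordinates")
  ## frame weights
  dropped <- 0L
  if (weighting == "msm") {
    if (is.null(microAssignment) || is.null(pi))
      stop("msm weighting needs microAssignment and pi")
    if (length(microAssignment) != nFramesTotal)
      stop("microAssignment must label every frame")
    piOf <- rep(NA_real_, max(microAssignment))
    piOf[as.integer(names(pi) %||% seq_along(pi))] <- as.numeric(pi)
    w <- piOf[microAssignment]
    keep <- !is.na(w)
    dropped <- sum(!keep)
    cnt <- tabulate(microAssignment[keep], nbins = length(piOf))
    w <- w / cnt[microAssignment]
    vals <- vals[keep, , drop = FALSE]
    w <- w[keep]
  } else {
    w <- rep(1, nFramesTotal)
  }
  ## bin edges
  edges <- vector("list", ndim)
  if (is.list(bins)) {
    edges <- bins
  } else if (length(bins) == 1L && bins == round(bins) && bins > 1 &&
             length(unique(vals[, 1])) > 1) {
    for (d in seq_len(ndim)) {
      r <- range(vals[, d])
      edges[[d]] <- seq(r[1], r[2], length.out = bins + 1L)
    }
  } else {
    edges[[1]] <- bins
  }
  for (e in edges) if (any(diff(e) <= 0))
    stop("bin edges must be strictly increasing")
  ix <- findInterval(vals[, 1], edges[[1]], rightmost.closed = TRUE)
  inside <- ix >= 1 & ix <= length(edges[[1]]) - 1L
  if (ndim == 2) {
    iy <- findInterval(vals[, 2], edges[[2]], rightmost.closed = TRUE)
    inside <- inside & iy >= 1 & iy <= length(edges[[2]]) - 1L
  }
  if (!any(inside)) stop("all frames fall outside the bin range")
  nb1 <- length(edges[[1]]) - 1L
  if (ndim == 1) {
    wbin <- vapply(seq_len(nb1), function(b)
      sum(w[inside][ix[inside] == b]), numeric(1))
    mask <- wbin <= 0
    F <- rep(NA_real_, nb1)
    F[!mask] <- -log(wbin[!mask] / max(wbin)) * kTScale
    F[!mask] <- F[!mask] - min(F[!mask])
  } else {
    nb2 <- length(edges[[2]]) - 1L
    wbin <- matrix(0, nb1, nb2)
    idx <- cbind(ix[inside], iy[inside])
    for (r in seq_len(nrow(idx)))
      wbin[idx[r, 1], idx[r, 2]] <- wbin[idx[r, 1], idx[r, 2]] +
        w[inside][r]
    mask <- wbin <= 0
    F <- matrix(NA_real_, nb1, nb2)
    F[!mask] <- -log(wbin[!mask] / max(wbin)) * kTScale
    F[!mask] <- F[!mask] - min(F[!mask])
  }
  out <- new("PMFGrid", coordNames = coords, edges = edges, values = F,
             mask = mask, weighting = weighting)
  attr(out, "droppedFrames") <- dropped
  out
}

#' Free-energy difference between two regions of a 1D PMF
#'
#' Integrates the underlying Boltzmann weight (exp(-F)) over each region and
#' returns \code{-ln(w2 / w1)} -- the basin-to-basin free-energy difference
#' in kT.
#'
#' @param grid a 1D \linkS4class{PMFGrid}.
#' @param divider coordinate value splitting region 1 (below) from region 2
#'   (above).
#' @return free energy of region 2 relative to region 1 (kT units).
#' @export
pmfBasinDelta <- function(grid, divider) {
  if (length(grid@coordNames) != 1L) stop("1D grids only")
  centers <- (head(grid@edges[[1]], -1) + tail(grid@edges[[1]], -1)) / 2
  ok <- !grid@mask
  w <- exp(-grid@values[ok])
  cn <- centers[ok]
  w1 <- sum(w[cn < divider]); w2 <- sum(w[cn >= divider])
  if (w1 <= 0 || w2 <= 0) stop("a region holds no weight")
  -log(w2 / w1)
}

#' Write a PMF grid as CSV (long format for 2D)
#' @param grid a \linkS4class{PMFGrid}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writePMF <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# PMF in kT units; coords=%s (Angstrom); weighting=%s",
                     paste(grid@coordNames, collapse = ","),
                     grid@weighting), con)
  c1 <- (head(grid@edges[[1]], -1) + tail(grid@edges[[1]], -1)) / 2
  if (length(grid@coordNames) == 1L) {
    df <- data.frame(bin_center = c1, F_kT = grid@values,
                     mask = as.integer(grid@mask))
  } else {
    c2 <- (head(grid@edges[[2]], -1) + tail(grid@edges[[2]], -1)) / 2
    df <- data.frame(bin_center = rep(c1, times = length(c2)),
                     bin_center2 = rep(c2, each = length(c1)),
                     F_kT = as.vector(grid@values),
                     mask = as.integer(as.vector(grid@mask)))
  }
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
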