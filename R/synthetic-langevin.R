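## Explicit potentials with analytic gradients and Boltzmann quadrature, plus
## an overdamped Euler-Maruyama integrator. These provide the thermodynamic
## oracle the real polymerase system lacks: basin populations of the
## simulated data can be checked against numerically integrated Boltzmann
## weights.

#' Sum-of-Gaussian-wells potential
#'
#' \code{U(x) = -sum_i depth_i * exp(-(x - center_i)^2 / (2 width_i^2))}
#' (1D only). Depths are in the same energy unit as \code{kT}.
#'
#' Gaussian wells alone are not confining (the potential is flat far from
#' every well), so a steep polynomial wall
#' \code{wallHeight * ((x - mid) / span)^12} is added, centered between the
#' outermost wells and reaching \code{wallHeight} at \code{mid +- span}. The
#' wall is negligible (< 0.3% of its height) over the inner 60% of the span,
#' leaving the well dynamics untouched while keeping the Boltzmann integral
#' finite and the trajectory inside the domain.
#'
#' @param centers well centers.
#' @param depths well depths (> 0); energies at the well bottoms are
#'   approximately \code{-depth}.
#' @param widths Gaussian widths.
#' @param kT thermal energy, default 1.
#' @param bounds length-2 domain bounds; default spans the wells generously.
#' @param wallHeight confining wall energy at 90% of the half-domain,
#'   default \code{8 kT}.
#' @return A \linkS4class{PotentialSpec}.
#' @export
gaussianWellPotential <- function(centers, depths, widths, kT = 1,
                                  bounds = NULL, wallHeight = 8 * kT) {
  stopifnot(length(centers) == length(depths),
            length(centers) == length(widths), all(widths > 0))
  if (is.null(bounds))
    bounds <- c(min(centers) - 6 * max(widths), max(centers) + 6 * max(widths))
  mid <- mean(bounds)
  span <- 0.9 * (bounds[2] - bounds[1]) / 2
  new("PotentialSpec", dimension = 1L, form = "gaussian",
      params = list(centers = centers, depths = depths, widths = widths,
                    wallMid = mid, wallSpan = span, wallHeight = wallHeight),
      kT = kT, bounds = matrix(bounds, nrow = 2))
}

#' Tilted quartic double-well potential
#'
#' \code{U(x) = h ((x/a)^2 - 1)^2 + c x}: minima near x = -a and x = +a
#' separated by a barrier of height ~h, with a linear tilt c that makes the
#' two basins unequally populated.
#'
#' @param barrier barrier height h (energy units).
#' @param halfSeparation a; minima sit near \code{-a} and \code{+a}.
#' @param tilt linear tilt c (energy per length), default 0 (symmetric).
#' @param kT thermal energy, default 1.
#' @param bounds length-2 domain bounds, default \code{c(-4a, 4a)}.
#' @return A \linkS4class{PotentialSpec}.
#' @export
doubleWellPotential <- function(barrier, halfSeparation = 1, tilt = 0, kT = 1,
                                bounds = NULL) {
  if (is.null(bounds)) bounds <- c(-4, 4) * halfSeparation
  new("PotentialSpec", dimension = 1L, form = "polyDoubleWell",
      params = list(h = barrier, a = halfSeparation, c = tilt),
      kT = kT, bounds = matrix(bounds, nrow = 2))
}

#' Flat potential (free diffusion)
#' @param kT thermal energy, default 1.
#' @param bounds length-2 domain bounds, default \code{c(-1e6, 1e6)}.
#' @return A \linkS4class{PotentialSpec}.
#' @export
flatPotential <- function(kT = 1, bounds = c(-1e6, 1e6)) {
  new("PotentialSpec", dimension = 1L, form = "flat", params = list(),
      kT = kT, bounds = matrix(bounds, nrow = 2))
}

#' Evaluate a potential
#' @param potential a \linkS4class{PotentialSpec}.
#' @param x numeric vector of positions (1D).
#' @return potential energy at each position.
#' @export
potentialEnergy <- function(potential, x) {
  p <- potential@params
  switch(potential@form,
    flat = rep(0, length(x)),
    gaussian = {
      U <- p$wallHeight * ((x - p$wallMid) / p$wallSpan)^12
      for (i in seq_along(p$centers))
        U <- U - p$depths[i] * exp(-(x - p$centers[i])^2 / (2 * p$widths[i]^2))
      U
    },
    polyDoubleWell = p$h * ((x / p$a)^2 - 1)^2 + p$c * x,
    stop("unknown potential form: ", potential@form))
}

#' Gradient of a potential
#' @param potential a \linkS4class{PotentialSpec}.
#' @param x numeric vector of positions (1D).
#' @return dU/dx at each position.
#' @export
potentialGradient <- function(potential, x) {
  p <- potential@params
  switch(potential@form,
    flat = rep(0, length(x)),
    gaussian = {
      g <- 12 * p$wallHeight * ((x - p$wallMid) / p$wallSpan)^11 / p$wallSpan
      for (i in seq_along(p$centers)) {
        d <- x - p$centers[i]
        g <- g + p$depths[i] * d / p$widths[i]^2 *
          exp(-d^2 / (2 * p$widths[i]^2))
      }
      g
    },
    polyDoubleWell = 4 * p$h * x * ((x / p$a)^2 - 1) / p$a^2 + p$c,
    stop("unknown potential form: ", potential@form))
}

#' Locations of the potential's minima (1D)
#' @param potential a \linkS4class{PotentialSpec}.
#' @return numeric vector of local minimum positions, increasing.
#' @export
potentialMinima <- function(potential) {
  lo <- potential@bounds[1, 1]; hi <- potential@bounds[2, 1]
  xs <- seq(lo, hi, length.out = 4096)
  U <- potentialEnergy(potential, xs)
  idx <- which(diff(sign(diff(U))) > 0) + 1L
  vapply(idx, function(i) {
    optimize(function(x) potentialEnergy(potential, x),
             lower = xs[max(1L, i - 2L)],
             upper = xs[min(length(xs), i + 2L)])$minimum
  }, numeric(1))
}

#' Barrier position between two minima (1D)
#' @param potential a \linkS4class{PotentialSpec}.
#' @param between length-2 vector bracketing the barrier; defaults to the two
#'   outermost minima.
#' @return position of the maximum of U between the minima.
#' @export
potentialBarrier <- function(potential, between = NULL) {
  if (is.null(between)) {
    m <- potentialMinima(potential)
    if (length(m) < 2) stop("potential has fewer than two minima")
    between <- range(m)
  }
  optimize(function(x) -potentialEnergy(potential, x),
           lower = between[1], upper = between[2])$minimum
}

#' Boltzmann basin populations by numerical quadrature
#'
#' Integrates \code{exp(-U/kT)} over basins delimited by the given divider
#' positions and returns normalized basin weights -- the exact equilibrium
#' populations any unbiased sampler must reproduce.
#'
#' @param potential a \linkS4class{PotentialSpec} (1D).
#' @param dividers positions splitting the domain into basins; default is the
#'   single barrier between the two outermost minima.
#' @return numeric vector of basin probabilities (left to right), sum 1.
#' @examples
#' pot <- doubleWellPotential(barrier = 1.5, tilt = 0.25)
#' boltzmannPopulations(pot)
#' @export
boltzmannPopulations <- function(potential, dividers = NULL) {
  if (is.null(dividers)) dividers <- potentialBarrier(potential)
  lo <- potential@bounds[1, 1]; hi <- potential@bounds[2, 1]
  edges <- c(lo, sort(dividers), hi)
  w <- vapply(seq_len(length(edges) - 1L), function(i) {
    integrate(function(x) exp(-potentialEnergy(potential, x) / potential@kT),
              lower = edges[i], upper = edges[i + 1L],
              rel.tol = 1e-10)$value
  }, numeric(1))
  if (!all(is.finite(w))) stop("Boltzmann integral not finite on the domain")
  w / sum(w)
}

#' Overdamped Langevin dynamics on an explicit potential
#'
#' Euler-Maruyama integration of
#' \code{x <- x - (dU/dx / friction) dt + sqrt(2 kT dt / friction) xi} with
#' standard normal xi. The per-step displacement sd must be below 1/10 of the
#' minimum well separation (checked for multi-well potentials) so the
#' discretization resolves the basin structure.
#'
#' @param potential a \linkS4class{PotentialSpec} (1D).
#' @param nFrames number of steps/frames to record.
#' @param timeStep integration time step dt (> 0).
#' @param friction friction coefficient gamma (> 0), default 1.
#' @param seed integer seed.
#' @param x0 starting position; default the deepest minimum (or 0 for a flat
#'   potential).
#' @param coordName emitted coordinate name, default \code{"x"}.
#' @return A \linkS4class{FeatureTrajectory} of the positions (frame interval
#'   = \code{timeStep}).
#' @export
simulateLangevin <- function(potential, nFrames, timeStep, friction = 1,
                             seed = 1L, x0 = NULL, coordName = "x") {
  stopifnot(nFrames >= 1, timeStep > 0, friction > 0)
  noiseSd <- sqrt(2 * potential@kT * timeStep / friction)
  if (potential@form != "flat") {
    minima <- potentialMinima(potential)
    if (length(minima) >= 2) {
      sep <- min(diff(sort(minima)))
      if (noiseSd >= sep / 10)
        stop(sprintf(paste0(
          "time step too coarse: per-step displacement sd %.4g must be < ",
          "1/10 of the minimum well separation %.4g"), noiseSd, sep))
    }
    if (is.null(x0)) {
      Umin <- potentialEnergy(potential, minima)
      x0 <- if (length(minima)) minima[which.min(Umin)] else 0
    }
  } else if (is.null(x0)) x0 <- 0
  lo <- potential@bounds[1, 1]; hi <- potential@bounds[2, 1]
  set.seed(as.integer(seed))
  xi <- rnorm(nFrames)
  x <- numeric(nFrames)
  cur <- x0
  invFr <- timeStep / friction
  p <- potential@params
  gradFun <- switch(potential@form,
    flat = function(x) 0,
    polyDoubleWell = function(x) 4 * p$h * x * ((x / p$a)^2 - 1) / p$a^2 + p$c,
    gaussian = function(x) {
      gg <- 12 * p$wallHeight * ((x - p$wallMid) / p$wallSpan)^11 / p$wallSpan
      for (kk in seq_along(p$centers)) {
        d <- x - p$centers[kk]
        gg <- gg + p$depths[kk] * d / p$widths[kk]^2 *
          exp(-d^2 / (2 * p$widths[kk]^2))
      }
      gg
    },
    stop("unknown potential form: ", potential@form))
  for (i in seq_len(nFrames)) {
    cur <- cur - gradFun(cur) * invFr + noiseSd * xi[i]
    if (cur < lo || cur > hi)
      stop(sprintf("trajectory left the domain [%g, %g] at frame %d",
                   lo, hi, i))
    x[i] <- cur
  }
  featureTrajectory(x, frameInterval = timeStep, timeUnit = "tau",
                    source = sprintf("langevin %s", potential@form),
                    coordName = coordName)
}
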