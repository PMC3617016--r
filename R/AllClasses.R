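#' @import methods
#' @importFrom stats rnorm runif rgeom integrate optimize sd setNames
#' @importFrom utils read.csv write.csv write.table head tail modifyList
NULL

## ---------------------------------------------------------------------------
## Trajectory containers
## ---------------------------------------------------------------------------

#' FeatureTrajectory: per-frame values of named reaction coordinates
#'
#' Holds a time-ordered series of one or more scalar reaction coordinates
#' (for the PPi-release system, typically d1 = distance between the PPi group
#' and the catalytic Mg2+A ion, in Angstrom) sampled at a fixed frame interval.
#'
#' @slot values numeric matrix, one row per frame, one named column per
#'   coordinate (Angstrom for distances).
#' @slot frameInterval positive scalar; time between consecutive frames.
#' @slot timeUnit unit label for \code{frameInterval} (e.g. \code{"ns"}).
#' @slot source free-form identifier of where the trajectory came from.
#' @exportClass FeatureTrajectory
setClass("FeatureTrajectory",
  representation(values = "matrix", frameInterval = "numeric",
                 timeUnit = "character", source = "character"))

setValidity("FeatureTrajectory", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (nrow(v) < 1L) return("trajectory must contain at least one frame")
  if (anyNA(v)) return("values contain missing frames (NA)")
  if (is.null(colnames(v)) || any(!nzchar(colnames(v))))
    return("every coordinate column must be named")
  if (length(object@frameInterval) != 1L || !is.finite(object@frameInterval) ||
      object@frameInterval <= 0)
    return("frameInterval must be a single positive number")
  TRUE
})

#' Construct a FeatureTrajectory
#'
#' @param values numeric matrix (frames x coordinates) with column names, or a
#'   numeric vector for a single coordinate.
#' @param frameInterval time between frames (> 0).
#' @param timeUnit time unit label, default \code{"ns"}.
#' @param source identifier string.
#' @param coordName column name used when \code{values} is a bare vector.
#' @return A \linkS4class{FeatureTrajectory}.
#' @examples
#' ft <- featureTrajectory(c(4.1, 4.3, 14.9), frameInterval = 1)
#' nFrames(ft)
#' @export
featureTrajectory <- function(values, frameInterval, timeUnit = "ns",
                              source = "", coordName = "d1") {
  if (is.null(dim(values))) {
    values <- matrix(as.numeric(values), ncol = 1L,
                     dimnames = list(NULL, coordName))
  }
  new("FeatureTrajectory", values = values,
      frameInterval = as.numeric(frameInterval),
      timeUnit = timeUnit, source = source)
}

#' CoordinateTrajectory: per-frame Cartesian coordinates of a small atom set
#'
#' Frames of an explicit (toy or extracted) atom set with two named subsets:
#' the alignment subset (the analogue of the bridge-helix C-alpha scaffold the
#' clustering metric is aligned on) and the metric subset (the analogue of the
#' three PPi atoms the RMSD metric is computed over).
#'
#' @slot coords numeric array \code{[atom, xyz, frame]} in Angstrom.
#' @slot atomLabels character vector of atom labels.
#' @slot alignmentSubset integer indices of atoms used for superposition.
#' @slot metricSubset integer indices of atoms the RMSD metric is taken over.
#' @slot frameInterval time between frames.
#' @slot timeUnit time unit label.
#' @exportClass CoordinateTrajectory
setClass("CoordinateTrajectory",
  representation(coords = "array", atomLabels = "character",
                 alignmentSubset = "integer", metricSubset = "integer",
                 frameInterval = "numeric", timeUnit = "character"))

setValidity("CoordinateTrajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    return("coords must be an [atom, 3, frame] array")
  if (length(object@atomLabels) != d[1])
    return("atomLabels length must equal the atom count")
  for (s in list(object@alignmentSubset, object@metricSubset)) {
    if (length(s) && (min(s) < 1L || max(s) > d[1]))
      return("atom subset index out of range")
  }
  if (object@frameInterval <= 0) return("frameInterval must be > 0")
  TRUE
})

#' Construct a CoordinateTrajectory
#'
#' @param coords array \code{[atom, 3, frame]} (Angstrom).
#' @param atomLabels atom labels; defaults to \code{"A1"}, \code{"A2"}, ...
#' @param alignmentSubset,metricSubset integer atom indices.
#' @param frameInterval time between frames, default 1.
#' @param timeUnit unit label, default \code{"ns"}.
#' @return A \linkS4class{CoordinateTrajectory}.
#' @export
coordinateTrajectory <- function(coords, atomLabels = NULL,
                                 alignmentSubset = integer(),
                                 metricSubset = integer(),
                                 frameInterval = 1, timeUnit = "ns") {
  if (is.null(atomLabels)) atomLabels <- paste0("A", seq_len(dim(coords)[1]))
  new("CoordinateTrajectory", coords = coords, atomLabels = atomLabels,
      alignmentSubset = as.integer(alignmentSubset),
      metricSubset = as.integer(metricSubset),
      frameInterval = as.numeric(frameInterval), timeUnit = timeUnit)
}

## ---------------------------------------------------------------------------
## Synthetic generators
## ---------------------------------------------------------------------------

#' JumpModel: continuous-time Markov jump process with Gaussian emissions
#'
#' Ground-truth kinetic model used by the synthetic generator. Hidden states
#' exchange with the given rates; the observed reaction coordinate is drawn
#' from a per-state Gaussian emission distribution.
#'
#' @slot nStates number of hidden states.
#' @slot rates matrix of per-unit-time transition rates; off-diagonal entries
#'   are the rates k(i -> j), the diagonal is unused.
#' @slot emissionMean per-state emission mean (Angstrom).
#' @slot emissionSd per-state emission standard deviation (Angstrom, > 0).
#' @slot timeUnit unit of the rates' inverse time (e.g. \code{"ns"}).
#' @exportClass JumpModel
setClass("JumpModel",
  representation(nStates = "integer", rates = "matrix",
                 emissionMean = "numeric", emissionSd = "numeric",
                 timeUnit = "character"))

setValidity("JumpModel", function(object) {
  n <- object@nStates
  R <- object@rates
  if (!all(dim(R) == c(n, n))) return("rates must be nStates x nStates")
  off <- R[row(R) != col(R)]
  if (any(!is.finite(off)) || any(off < 0))
    return("all off-diagonal rates must be finite and >= 0")
  if (length(object@emissionMean) != n || length(object@emissionSd) != n)
    return("emission parameters must have one entry per state")
  if (any(object@emissionSd <= 0)) return("emissionSd must be > 0")
  TRUE
})

#' Construct a JumpModel
#'
#' @param rates square matrix of transition rates (off-diagonal k(i->j) >= 0;
#'   diagonal ignored).
#' @param emissionMean,emissionSd per-state Gaussian emission parameters
#'   (Angstrom).
#' @param timeUnit inverse-time unit of the rates, default \code{"ns"}.
#' @return A \linkS4class{JumpModel}.
#' @export
jumpModel <- function(rates, emissionMean, emissionSd, timeUnit = "ns") {
  rates <- as.matrix(rates)
  diag(rates) <- 0
  new("JumpModel", nStates = nrow(rates), rates = rates,
      emissionMean = as.numeric(emissionMean),
      emissionSd = as.numeric(emissionSd), timeUnit = timeUnit)
}

#' PotentialSpec: explicit low-dimensional potential with Boltzmann oracle
#'
#' An analytic potential energy surface used to drive overdamped Langevin
#' dynamics and to provide exactly integrable Boltzmann statistics.
#'
#' @slot dimension 1 or 2.
#' @slot form \code{"gaussian"} (sum of Gaussian wells) or
#'   \code{"polyDoubleWell"} (tilted quartic double well).
#' @slot params named list of form-specific coefficients.
#' @slot kT thermal energy (arbitrary energy unit; energies are in kT).
#' @slot bounds numeric matrix 2 x dimension of domain bounds.
#' @exportClass PotentialSpec
setClass("PotentialSpec",
  representation(dimension = "integer", form = "character", params = "list",
                 kT = "numeric", bounds = "matrix"))

setValidity("PotentialSpec", function(object) {
  if (!object@dimension %in% c(1L, 2L)) return("dimension must be 1 or 2")
  if (object@kT <= 0) return("kT must be > 0")
  if (!all(dim(object@bounds) == c(2L, object@dimension)))
    return("bounds must be a 2 x dimension matrix")
  if (any(object@bounds[1, ] >= object@bounds[2, ]))
    return("lower bounds must be below upper bounds")
  TRUE
})

#' SyntheticTruth: generator-side ground truth for a synthetic data set
#'
#' @slot stationary exact stationary probabilities of the generating process.
#' @slot mfptMatrix exact pairwise mean first passage times (diagonal 0), in
#'   the generator's time unit.
#' @slot params generator parameters (rates, emissions, frame interval, ...).
#' @slot seed integer seed the data were generated from.
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(stationary = "numeric", mfptMatrix = "matrix",
                 params = "list", seed = "integer"))

setValidity("SyntheticTruth", function(object) {
  # NA stationary marks a non-ergodic generator (no equilibrium to report)
  if (!anyNA(object@stationary) &&
      abs(sum(object@stationary) - 1) > 1e-9)
    return("stationary probabilities must sum to 1")
  if (any(abs(diag(object@mfptMatrix)) > 0))
    return("MFPT diagonal must be 0")
  TRUE
})

## ---------------------------------------------------------------------------
## Clustering
## ---------------------------------------------------------------------------

#' Clustering: result of greedy k-center splitting
#'
#' @slot k number of clusters.
#' @slot centerFrames integer indices (into the clustered frame set) of the
#'   center conformations.
#' @slot assignment integer cluster label (1..k) per frame.
#' @slot distToCenter distance of every frame to its assigned center.
#' @slot radii per-cluster maximum member-to-center distance.
#' @slot meanDist per-cluster mean member-to-center distance.
#' @slot metric descriptor of the metric used.
#' @slot centerValues coordinates of the centers when frames were a numeric
#'   matrix (one row per center), otherwise NULL.
#' @exportClass Clustering
setClass("Clustering",
  representation(k = "integer", centerFrames = "integer",
                 assignment = "integer", distToCenter = "numeric",
                 radii = "numeric", meanDist = "numeric", metric = "character",
                 centerValues = "ANY"))

setValidity("Clustering", function(object) {
  k <- object@k
  if (length(object@centerFrames) != k) return("need k center frames")
  if (any(object@assignment < 1L) || any(object@assignment > k))
    return("assignments out of range")
  if (any(object@assignment[object@centerFrames] != seq_len(k)))
    return("each center must be assigned to itself")
  if (any(object@radii + 1e-12 < object@meanDist))
    return("radius must be >= mean distance")
  TRUE
})

## ---------------------------------------------------------------------------
## MSM objects
## ---------------------------------------------------------------------------

#' DiscreteTrajectorySet: integer state paths at a fixed frame interval
#'
#' @slot paths list of integer vectors with state labels in 1..nStates.
#' @slot nStates number of microstates.
#' @slot frameInterval time between frames.
#' @slot timeUnit time unit label.
#' @exportClass DiscreteTrajectorySet
setClass("DiscreteTrajectorySet",
  representation(paths = "list", nStates = "integer",
                 frameInterval = "numeric", timeUnit = "character"))

setValidity("DiscreteTrajectorySet", function(object) {
  if (!length(object@paths)) return("need at least one trajectory")
  for (p in object@paths) {
    if (!length(p)) return("paths must be non-empty")
    if (min(p) < 1L || max(p) > object@nStates)
      return("state labels must lie in 1..nStates")
  }
  if (object@frameInterval <= 0) return("frameInterval must be > 0")
  TRUE
})

#' Construct a DiscreteTrajectorySet
#'
#' @param paths list of integer vectors (state labels in 1..nStates), or a
#'   single integer vector.
#' @param nStates number of microstates; defaults to the largest label seen.
#' @param frameInterval time between frames, default 1.
#' @param timeUnit unit label, default \code{"ns"}.
#' @return A \linkS4class{DiscreteTrajectorySet}.
#' @export
discreteTrajectories <- function(paths, nStates = NULL, frameInterval = 1,
                                 timeUnit = "ns") {
  if (!is.list(paths)) paths <- list(paths)
  paths <- lapply(paths, function(p) as.integer(p))
  if (is.null(nStates)) nStates <- max(vapply(paths, max, integer(1)))
  new("DiscreteTrajectorySet", paths = paths, nStates = as.integer(nStates),
      frameInterval = as.numeric(frameInterval), timeUnit = timeUnit)
}

#' CountMatrix: lagged transition counts with dwell (re-crossing) filter
#'
#' @slot counts integer-valued matrix N[i, j] of observed i -> j transitions
#'   at the stated lag.
#' @slot lagFrames lag in frames.
#' @slot dwellFrames minimum dwell, in frames, the destination state must
#'   persist for a transition to be counted (the 50 ps re-crossing rule at the
#'   native 2 ps save interval corresponds to 25 frames).
#' @slot sliding logical; sliding-window counting.
#' @slot stateLabels original microstate labels of the rows/columns (identity
#'   before ergodic trimming).
#' @slot frameInterval,timeUnit physical time per frame and its unit.
#' @exportClass CountMatrix
setClass("CountMatrix",
  representation(counts = "matrix", lagFrames = "integer",
                 dwellFrames = "integer", sliding = "logical",
                 stateLabels = "integer", frameInterval = "numeric",
                 timeUnit = "character"))

setValidity("CountMatrix", function(object) {
  N <- object@counts
  if (nrow(N) != ncol(N)) return("counts must be square")
  if (any(N < 0) || any(abs(N - round(N)) > 1e-9))
    return("counts must be non-negative integers")
  if (length(object@stateLabels) != nrow(N))
    return("stateLabels must map every row")
  if (object@lagFrames < 1L || object@dwellFrames < 1L)
    return("lagFrames and dwellFrames must be >= 1")
  TRUE
})

#' TransitionModel: row-stochastic Markov model at a fixed lag
#'
#' The first-order master equation P(n dt) = P(0) T^n is parameterized by the
#' row-stochastic transition probability matrix T at lag dt; the stationary
#' distribution is its dominant left eigenvector.
#'
#' @slot probs row-stochastic transition matrix T.
#' @slot lagFrames lag in frames.
#' @slot stationary stationary distribution (left eigenvector for
#'   eigenvalue 1, normalized to sum 1).
#' @slot eigenvalues complex eigenvalues sorted by decreasing modulus
#'   (ties broken by real part, then index).
#' @slot stateLabels original microstate labels of the rows.
#' @slot frameInterval,timeUnit physical time per frame and its unit.
#' @exportClass TransitionModel
setClass("TransitionModel",
  representation(probs = "matrix", lagFrames = "integer",
                 stationary = "numeric", eigenvalues = "complex",
                 stateLabels = "integer", frameInterval = "numeric",
                 timeUnit = "character"))

setValidity("TransitionModel", function(object) {
  T <- object@probs
  if (any(abs(rowSums(T) - 1) > 1e-12)) return("rows of T must sum to 1")
  p <- object@stationary
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-10)
    return("stationary distribution must be non-negative and sum to 1")
  if (max(abs(p %*% T - p)) > 1e-10)
    return("stationary distribution must satisfy pi T = pi")
  if (any(Mod(object@eigenvalues) > 1 + 1e-8))
    return("eigenvalue moduli must be <= 1")
  TRUE
})

#' MacrostateModel: metastable lumping of a microstate MSM
#'
#' @slot nMacro number of macrostates.
#' @slot memberships fuzzy PCCA+ memberships (microstate x macrostate; rows
#'   sum to 1).
#' @slot assignment crisp microstate -> macrostate assignment (argmax of the
#'   fuzzy memberships).
#' @slot counts lumped transition count matrix.
#' @slot probs lumped row-stochastic transition matrix at the model lag.
#' @slot populations macrostate equilibrium populations from summing the
#'   microstate stationary distribution over members (primary output).
#' @slot populationsCount populations from the stationary distribution of the
#'   lumped matrix itself (count-level cross-check).
#' @slot lagFrames,frameInterval,timeUnit model lag and time base.
#' @slot bootstrap list with elements popMean, popSd, mfptMean, mfptSd,
#'   nReplicates, nDegenerate once \code{\link{bootstrapMSM}} has been run;
#'   empty list otherwise.
#' @exportClass MacrostateModel
setClass("MacrostateModel",
  representation(nMacro = "integer", memberships = "matrix",
                 assignment = "integer", counts = "matrix", probs = "matrix",
                 populations = "numeric", populationsCount = "numeric",
                 lagFrames = "integer", frameInterval = "numeric",
                 timeUnit = "character", bootstrap = "list"))

setValidity("MacrostateModel", function(object) {
  m <- object@nMacro
  if (ncol(object@memberships) != m) return("memberships must have m columns")
  if (any(abs(rowSums(object@memberships) - 1) > 1e-8))
    return("fuzzy membership rows must sum to 1")
  if (!identical(object@assignment,
                 as.integer(apply(object@memberships, 1, which.max))))
    return("crisp assignment must be the argmax of the fuzzy memberships")
  if (abs(sum(object@populations) - 1) > 1e-10)
    return("macrostate populations must sum to 1")
  if (any(abs(rowSums(object@probs) - 1) > 1e-12))
    return("lumped transition matrix must be row-stochastic")
  TRUE
})

## ---------------------------------------------------------------------------
## PMF
## ---------------------------------------------------------------------------

#' PMFGrid: binned free-energy surface over one or two reaction coordinates
#'
#' Free energies are in units of kT with the minimum over non-empty bins
#' shifted to zero; empty bins are masked (NA), never interpolated.
#'
#' @slot coordNames names of the projected coordinates.
#' @slot edges list of strictly increasing bin edge vectors, one per
#'   coordinate (Angstrom).
#' @slot values free energy per bin (vector for 1D, matrix for 2D), kT units.
#' @slot mask logical, TRUE where a bin holds no weight.
#' @slot weighting \code{"uniform"} or \code{"msm"}.
#' @exportClass PMFGrid
setClass("PMFGrid",
  representation(coordNames = "character", edges = "list", values = "ANY",
                 mask = "ANY", weighting = "character"))

setValidity("PMFGrid", function(object) {
  v <- object@values
  filled <- v[!object@mask]
  if (length(filled) && abs(min(filled)) > 1e-9)
    return("minimum free energy over non-empty bins must be 0")
  for (e in object@edges)
    if (any(diff(e) <= 0)) return("bin edges must be strictly increasing")
  TRUE
})

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "FeatureTrajectory", function(object) {
  cat(sprintf("FeatureTrajectory: %d frames x %d coordinate(s) [%s]\n",
              nrow(object@values), ncol(object@values),
              paste(colnames(object@values), collapse = ", ")))
  cat(sprintf("  frame interval: %g %s; source: %s\n", object@frameInterval,
              object@timeUnit,
              if (nzchar(object@source)) object@source else "<unset>"))
})

setMethod("show", "CoordinateTrajectory", function(object) {
  d <- dim(object@coords)
  cat(sprintf("CoordinateTrajectory: %d frames, %d atoms\n", d[3], d[1]))
  cat(sprintf("  alignment subset: %d atoms; metric subset: %d atoms\n",
              length(object@alignmentSubset), length(object@metricSubset)))
})

setMethod("show", "JumpModel", function(object) {
  cat(sprintf("JumpModel: %d states, rates in 1/%s\n", object@nStates,
              object@timeUnit))
  print(signif(object@rates, 5))
  cat("  emission means (A):", paste(object@emissionMean, collapse = ", "),
      "\n  emission sds   (A):", paste(object@emissionSd, collapse = ", "),
      "\n")
})

setMethod("show", "Clustering", function(object) {
  cat(sprintf("Clustering: k = %d (%s metric), %d frames\n", object@k,
              object@metric, length(object@assignment)))
  cat(sprintf("  radius: max %.4g, mean %.4g; mean member-to-center %.4g\n",
              max(object@radii), mean(object@radii), mean(object@distToCenter)))
})

setMethod("show", "DiscreteTrajectorySet", function(object) {
  cat(sprintf(
    "DiscreteTrajectorySet: %d trajectories, %d frames total, %d states\n",
    length(object@paths), sum(lengths(object@paths)), object@nStates))
  cat(sprintf("  frame interval: %g %s\n", object@frameInterval,
              object@timeUnit))
})

setMethod("show", "CountMatrix", function(object) {
  cat(sprintf(
    "CountMatrix: %d states, lag %d frame(s) (%g %s), dwell %d, %s window\n",
    nrow(object@counts), object@lagFrames,
    object@lagFrames * object@frameInterval, object@timeUnit,
    object@dwellFrames, if (object@sliding) "sliding" else "stepped"))
  cat(sprintf("  total counts: %g\n", sum(object@counts)))
})

setMethod("show", "TransitionModel", function(object) {
  cat(sprintf("TransitionModel: %d states at lag %d frame(s) (%g %s)\n",
              nrow(object@probs), object@lagFrames,
              object@lagFrames * object@frameInterval, object@timeUnit))
  ev <- Mod(object@eigenvalues)
  cat("  leading |eigenvalues|:",
      paste(signif(head(ev, 4), 4), collapse = ", "), "\n")
})

setMethod("show", "MacrostateModel", function(object) {
  cat(sprintf("MacrostateModel: %d macrostates over %d microstates\n",
              object@nMacro, nrow(object@memberships)))
  cat("  populations:",
      paste(sprintf("%.4f", object@populations), collapse = ", "), "\n")
  if (length(object@bootstrap))
    cat(sprintf("  bootstrap: %d replicates (%d degenerate)\n",
                object@bootstrap$nReplicates, object@bootstrap$nDegenerate))
})

setMethod("show", "PMFGrid", function(object) {
  cat(sprintf("PMFGrid over %s (%s-weighted): %s bins, %d empty\n",
              paste(object@coordNames, collapse = " x "), object@weighting,
              paste(vapply(object@edges, function(e) length(e) - 1L,
                           integer(1)), collapse = " x "),
              sum(object@mask)))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth\n  stationary:",
      paste(sprintf("%.5f", object@stationary), collapse = ", "), "\n")
  cat("  MFPT matrix (", object@params$timeUnit %||% "time", "):\n", sep = "")
  print(signif(object@mfptMatrix, 5))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
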