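## Generics and accessors. Slot access from user code should go through these.

#' Number of frames in a trajectory
#' @param x a trajectory object.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @describeIn nFrames frames of a FeatureTrajectory
#' @export
setMethod("nFrames", "FeatureTrajectory", function(x) nrow(x@values))

#' @describeIn nFrames frames of a CoordinateTrajectory
#' @export
setMethod("nFrames", "CoordinateTrajectory", function(x) dim(x@coords)[3])

#' Coordinate values of a FeatureTrajectory
#' @param x a \linkS4class{FeatureTrajectory}.
#' @return numeric matrix, frames x coordinates.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @describeIn featureValues matrix of per-frame coordinate values
#' @export
setMethod("featureValues", "FeatureTrajectory", function(x) x@values)

#' Frame interval of a time-ordered object
#' @param x an object with a frame interval.
#' @return numeric scalar (in \code{timeUnit(x)} units).
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname frameInterval
#' @export
setMethod("frameInterval", "FeatureTrajectory", function(x) x@frameInterval)
#' @rdname frameInterval
#' @export
setMethod("frameInterval", "CoordinateTrajectory", function(x) x@frameInterval)
#' @rdname frameInterval
#' @export
setMethod("frameInterval", "DiscreteTrajectorySet", function(x) x@frameInterval)

#' Time unit label
#' @param x an object carrying a time unit.
#' @return character scalar.
#' @export
setGeneric("timeUnit", function(x) standardGeneric("timeUnit"))

#' @rdname timeUnit
#' @export
setMethod("timeUnit", "FeatureTrajectory", function(x) x@timeUnit)
#' @rdname timeUnit
#' @export
setMethod("timeUnit", "DiscreteTrajectorySet", function(x) x@timeUnit)
#' @rdname timeUnit
#' @export
setMethod("timeUnit", "TransitionModel", function(x) x@timeUnit)

#' Transition counts
#' @param x a \linkS4class{CountMatrix} or \linkS4class{MacrostateModel}.
#' @return numeric matrix of transition counts.
#' @export
setGeneric("transitionCounts", function(x) standardGeneric("transitionCounts"))

#' @rdname transitionCounts
#' @export
setMethod("transitionCounts", "CountMatrix", function(x) x@counts)
#' @rdname transitionCounts
#' @export
setMethod("transitionCounts", "MacrostateModel", function(x) x@counts)

#' Transition probability matrix
#' @param x a \linkS4class{TransitionModel} or \linkS4class{MacrostateModel}.
#' @return row-stochastic numeric matrix.
#' @export
setGeneric("transitionProbs", function(x) standardGeneric("transitionProbs"))

#' @rdname transitionProbs
#' @export
setMethod("transitionProbs", "TransitionModel", function(x) x@probs)
#' @rdname transitionProbs
#' @export
setMethod("transitionProbs", "MacrostateModel", function(x) x@probs)

#' Stationary distribution of a Markov model
#' @param x a \linkS4class{TransitionModel}.
#' @return numeric vector summing to 1.
#' @export
setGeneric("stationaryDistribution",
           function(x) standardGeneric("stationaryDistribution"))

#' @rdname stationaryDistribution
#' @export
setMethod("stationaryDistribution", "TransitionModel", function(x) x@stationary)

#' Eigenvalues of a transition matrix, sorted by modulus
#' @param x a \linkS4class{TransitionModel}.
#' @return complex vector, largest modulus first.
#' @export
setGeneric("modelEigenvalues", function(x) standardGeneric("modelEigenvalues"))

#' @rdname modelEigenvalues
#' @export
setMethod("modelEigenvalues", "TransitionModel", function(x) x@eigenvalues)

#' Lag of a lagged model, in frames
#' @param x a lagged object.
#' @return integer lag in frames.
#' @export
setGeneric("lagFrames", function(x) standardGeneric("lagFrames"))

#' @rdname lagFrames
#' @export
setMethod("lagFrames", "CountMatrix", function(x) x@lagFrames)
#' @rdname lagFrames
#' @export
setMethod("lagFrames", "TransitionModel", function(x) x@lagFrames)
#' @rdname lagFrames
#' @export
setMethod("lagFrames", "MacrostateModel", function(x) x@lagFrames)

#' Original microstate labels behind a (possibly trimmed) model
#' @param x a \linkS4class{CountMatrix} or \linkS4class{TransitionModel}.
#' @return integer vector mapping rows to original labels.
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' @rdname stateLabels
#' @export
setMethod("stateLabels", "CountMatrix", function(x) x@stateLabels)
#' @rdname stateLabels
#' @export
setMethod("stateLabels", "TransitionModel", function(x) x@stateLabels)

#' Macrostate populations
#' @param x a \linkS4class{MacrostateModel}.
#' @param level \code{"pi"} (sums of the microstate stationary distribution,
#'   the primary estimate) or \code{"count"} (stationary distribution of the
#'   lumped matrix).
#' @return numeric vector summing to 1.
#' @export
setGeneric("populations", function(x, ...) standardGeneric("populations"))

#' @rdname populations
#' @export
setMethod("populations", "MacrostateModel", function(x, level = c("pi", "count")) {
  level <- match.arg(level)
  if (level == "pi") x@populations else x@populationsCount
})

#' Fuzzy PCCA+ memberships
#' @param x a \linkS4class{MacrostateModel}.
#' @return matrix microstate x macrostate, rows summing to 1.
#' @export
setGeneric("memberships", function(x) standardGeneric("memberships"))

#' @rdname memberships
#' @export
setMethod("memberships", "MacrostateModel", function(x) x@memberships)

#' Crisp microstate-to-macrostate assignment
#' @param x a \linkS4class{MacrostateModel} or \linkS4class{Clustering}.
#' @return integer vector of labels.
#' @export
setGeneric("crispAssignment", function(x) standardGeneric("crispAssignment"))

#' @rdname crispAssignment
#' @export
setMethod("crispAssignment", "MacrostateModel", function(x) x@assignment)
#' @rdname crispAssignment
#' @export
setMethod("crispAssignment", "Clustering", function(x) x@assignment)

#' Cluster centers
#' @param x a \linkS4class{Clustering}.
#' @return list with \code{frames} (center frame indices) and \code{values}
#'   (center coordinates, or NULL for non-matrix frame sets).
#' @export
setGeneric("clusterCenters", function(x) standardGeneric("clusterCenters"))

#' @rdname clusterCenters
#' @export
setMethod("clusterCenters", "Clustering",
          function(x) list(frames = x@centerFrames, values = x@centerValues))

#' Cluster radii (max member-to-center distance)
#' @param x a \linkS4class{Clustering}.
#' @return numeric vector of per-cluster radii.
#' @export
setGeneric("clusterRadii", function(x) standardGeneric("clusterRadii"))

#' @rdname clusterRadii
#' @export
setMethod("clusterRadii", "Clustering", function(x) x@radii)

#' Bootstrap summary of a MacrostateModel
#' @param x a \linkS4class{MacrostateModel} after \code{\link{bootstrapMSM}}.
#' @return list(popMean, popSd, mfptMean, mfptSd, nReplicates, nDegenerate)
#'   or an empty list when no bootstrap has been attached.
#' @export
setGeneric("bootstrapSummary", function(x) standardGeneric("bootstrapSummary"))

#' @rdname bootstrapSummary
#' @export
setMethod("bootstrapSummary", "MacrostateModel", function(x) x@bootstrap)

#' Ground-truth stationary probabilities of a synthetic generator
#' @param x a \linkS4class{SyntheticTruth} or \linkS4class{JumpModel}.
#' @return numeric vector summing to 1.
#' @export
setGeneric("truthStationary", function(x) standardGeneric("truthStationary"))

#' @rdname truthStationary
#' @export
setMethod("truthStationary", "SyntheticTruth", function(x) x@stationary)

#' Ground-truth MFPT matrix of a synthetic generator
#' @param x a \linkS4class{SyntheticTruth}.
#' @return numeric matrix, diagonal 0, in the generator's time unit.
#' @export
setGeneric("truthMFPT", function(x) standardGeneric("truthMFPT"))

#' @rdname truthMFPT
#' @export
setMethod("truthMFPT", "SyntheticTruth", function(x) x@mfptMatrix)
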