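## Kabsch superposition and RMSD metrics.
##
## The clustering metric mirrors the construction used for the PPi system:
## superpose each conformation on a reference by a rigid-body fit over an
## alignment subset (the bridge-helix C-alpha analogue), then measure RMSD
## over a small metric subset (the three-PPi-atom analogue).

.asFrameMatrix <- function(frame) {
  frame <- as.matrix(frame)
  if (ncol(frame) != 3L) stop("a frame must be an nAtoms x 3 matrix")
  frame
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation (determinant +1; reflections disallowed) and
#' translation minimizing the RMSD of \code{subset} atoms between a mobile
#' and a reference frame, and applies it to the whole mobile frame.
#'
#' @param mobile,reference nAtoms x 3 coordinate matrices (Angstrom).
#' @param subset integer indices of the atoms to fit on (>= 3, non-collinear);
#'   default all atoms.
#' @return list with \code{aligned} (transformed mobile frame),
#'   \code{rotation} (3 x 3, det +1), \code{translation} (length 3) such that
#'   \code{aligned = mobile \%*\% t(rotation) + translation}, and \code{rmsd}
#'   (RMSD over \code{subset} after superposition).
#' @examples
#' ref <- matrix(rnorm(12), 4, 3)
#' fit <- kabschSuperpose(ref, ref)
#' fit$rmsd  # 0
#' @export
kabschSuperpose <- function(mobile, reference, subset = NULL) {
  mobile <- .asFrameMatrix(mobile)
  reference <- .asFrameMatrix(reference)
  if (nrow(mobile) != nrow(reference))
    stop("mobile and reference must have the same atom count")
  if (is.null(subset)) subset <- seq_len(nrow(mobile))
  if (length(subset) < 3L)
    stop("alignment subset needs at least 3 atoms")
  A <- mobile[subset, , drop = FALSE]
  B <- reference[subset, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  sv <- svd(A0)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("alignment subset is collinear or degenerate")
  H <- crossprod(A0, B0)             # 3x3 covariance
  dec <- svd(H)
  d <- sign(det(dec$v %*% t(dec$u)))
  D <- diag(c(1, 1, d))
  R <- dec$v %*% D %*% t(dec$u)      # aligned = mobile %*% t(R)
  translation <- cb - as.numeric(ca %*% t(R))
  aligned <- mobile %*% t(R) + rep(translation, each = nrow(mobile))
  rmsd <- sqrt(mean(rowSums((aligned[subset, , drop = FALSE] - B)^2)))
  list(aligned = aligned, rotation = R, translation = translation,
       rmsd = rmsd)
}

#' RMSD between two coordinate matrices (no fitting)
#' @param a,b nAtoms x 3 matrices.
#' @return root-mean-square deviation in the same length unit.
#' @export
rawRMSD <- function(a, b) {
  a <- .asFrameMatrix(a); b <- .asFrameMatrix(b)
  sqrt(mean(rowSums((a - b)^2)))
}

#' Alignment-subset / metric-subset RMSD between two frames
#'
#' Superposes frame \code{a} onto frame \code{b} by the alignment subset,
#' then returns the RMSD over the metric subset only. Symmetric in its
#' arguments (to numerical precision) and a pseudo-metric on frames.
#'
#' @param a,b nAtoms x 3 coordinate matrices sharing atom ordering.
#' @param alignmentSubset atom indices for the rigid fit.
#' @param metricSubset atom indices the RMSD is computed over.
#' @return RMSD (Angstrom).
#' @export
metricRMSD <- function(a, b, alignmentSubset, metricSubset) {
  fit <- kabschSuperpose(a, b, alignmentSubset)
  sqrt(mean(rowSums(
    (fit$aligned[metricSubset, , drop = FALSE] -
       .asFrameMatrix(b)[metricSubset, , drop = FALSE])^2)))
}

#' Extract one frame of a CoordinateTrajectory as a matrix
#' @param traj a \linkS4class{CoordinateTrajectory}.
#' @param i frame index.
#' @return nAtoms x 3 matrix.
#' @export
getFrame <- function(traj, i) {
  traj@coords[, , i, drop = TRUE]
}

.resolveAtoms <- function(traj, atoms) {
  if (is.character(atoms)) {
    idx <- match(atoms, traj@atomLabels)
    if (anyNA(idx))
      stop("unknown atom label(s): ",
           paste(atoms[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(atoms)
}

#' Distance reaction coordinates from a coordinate trajectory
#'
#' For each requested pair of point sets, computes per frame the Euclidean
#' distance between the centers of geometry of the two sets -- e.g. the
#' distance between the PPi group and the Mg2+A ion, the d1 coordinate the
#' release process is projected on.
#'
#' @param traj a \linkS4class{CoordinateTrajectory}.
#' @param pairs list of \code{list(a = , b = )} entries, each an integer index
#'   vector or character vector of atom labels (sets must be non-empty).
#' @param names coordinate names, one per pair.
#' @param massWeights optional per-atom weights for mass-weighted centers;
#'   default NULL gives the unweighted center of geometry.
#' @return A \linkS4class{FeatureTrajectory} with one column per pair.
#' @export
distanceFeatures <- function(traj, pairs, names = NULL, massWeights = NULL) {
  if (is.null(names))
    names <- paste0("d", seq_along(pairs))
  stopifnot(length(names) == length(pairs))
  nf <- nFrames(traj)
  out <- matrix(NA_real_, nf, length(pairs), dimnames = list(NULL, names))
  for (p in seq_along(pairs)) {
    ia <- .resolveAtoms(traj, pairs[[p]]$a)
    ib <- .resolveAtoms(traj, pairs[[p]]$b)
    if (!length(ia) || !length(ib)) stop("point sets must be non-empty")
    wa <- if (is.null(massWeights)) rep(1, length(ia)) else massWeights[ia]
    wb <- if (is.null(massWeights)) rep(1, length(ib)) else massWeights[ib]
    for (f in seq_len(nf)) {
      fr <- traj@coords[, , f]
      ca <- colSums(fr[ia, , drop = FALSE] * wa) / sum(wa)
      cb <- colSums(fr[ib, , drop = FALSE] * wb) / sum(wb)
      out[f, p] <- sqrt(sum((ca - cb)^2))
    }
  }
  featureTrajectory(out, frameInterval = traj@frameInterval,
                    timeUnit = traj@timeUnit, source = "distanceFeatures")
}
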