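## Toy coordinate frames for exercising the superposition + k-center stack:
## a rigid 8-atom scaffold (alignment subset, analogue of the bridge-helix
## C-alpha frame) plus a 3-atom ligand (metric subset, analogue of the three
## PPi atoms) whose position relative to the scaffold follows a planted
## two-cluster distribution.

## Uniform random proper rotation via QR of a Gaussian matrix.
.randomRotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  d <- diag(qr.R(qr_))
  Q <- Q %*% diag(sign(d))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

## Fixed scaffold: a 2 x 2 x 2 A cube (8 corners) -- rigid, non-collinear.
.scaffoldTemplate <- function() {
  as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) * 1.0
}

## Ligand template: small triangle (three PPi-like atoms).
.ligandTemplate <- function() {
  matrix(c(0, 0, 0,
           1.5, 0, 0,
           0.75, 1.3, 0), nrow = 3, byrow = TRUE)
}

#' Generate toy structures with a planted two-cluster ligand distribution
#'
#' Each frame contains a rigid 8-atom scaffold and a 3-atom ligand. The
#' ligand sits at one of two planted offsets from the scaffold (cluster 1
#' near the scaffold, cluster 2 displaced by \code{clusterSeparation} along
#' x), perturbed isotropically with sd \code{displacementSd}; the whole frame
#' is then randomly rigidly rotated and translated. Because the scaffold is
#' rigid, superposition on it removes the rigid motion exactly, and the
#' alignment/metric RMSD between frames reflects only the planted ligand
#' displacement.
#'
#' @param nFrames number of frames (>= 1).
#' @param displacementSd isotropic sd of the ligand perturbation (Angstrom);
#'   0 gives identical frames up to rigid motion.
#' @param seed integer seed.
#' @param clusterSeparation distance between the two planted ligand sites
#'   (Angstrom), default 10.
#' @param clusterProb probability of drawing cluster 2, default 0.5.
#' @return list with \code{trajectory} (a
#'   \linkS4class{CoordinateTrajectory}; atoms 1-8 scaffold = alignment
#'   subset, atoms 9-11 ligand = metric subset) and \code{labels} (planted
#'   cluster label per frame).
#' @export
makeToyStructures <- function(nFrames, displacementSd, seed = 1L,
                              clusterSeparation = 10, clusterProb = 0.5) {
  stopifnot(nFrames >= 1, displacementSd >= 0)
  set.seed(as.integer(seed))
  scaffold <- .scaffoldTemplate()
  ligand0 <- .ligandTemplate()
  offsets <- rbind(c(3, 0, 0), c(3 + clusterSeparation, 0, 0))
  labels <- 1L + (runif(nFrames) < clusterProb)
  coords <- array(NA_real_, dim = c(11L, 3L, nFrames))
  for (f in seq_len(nFrames)) {
    lig <- ligand0 +
      rep(offsets[labels[f], ], each = 3) +
      matrix(rnorm(9, sd = displacementSd), 3, 3)
    frame <- rbind(scaffold, lig)
    R <- .randomRotation()
    tr <- rnorm(3, sd = 20)
    coords[, , f] <- frame %*% t(R) + rep(tr, each = 11)
  }
  traj <- coordinateTrajectory(
    coords,
    atomLabels = c(paste0("CA", 1:8), "O1", "P1", "P2"),
    alignmentSubset = 1:8, metricSubset = 9:11)
  list(trajectory = traj, labels = labels)
}
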