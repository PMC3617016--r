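## Greedy k-center clustering.
##
## The splitting stage of the MSM pipeline: conformations are divided into
## geometric microstates by the greedy k-center rule (each new center is the
## frame farthest from its nearest existing center), which guarantees a
## maximum cluster radius within 2x of the optimal k-center radius.
## Deterministic given the data, k and the initial center.

#' Greedy k-center clustering
#'
#' The first center is \code{frames[initialIndex]}; each subsequent center is
#' the frame farthest from its nearest existing center; the final assignment
#' is nearest-center with ties broken to the lowest center index.
#'
#' @param frames frames to cluster: a numeric matrix (rows = frames; the
#'   metric is Euclidean distance between rows), a numeric vector (treated as
#'   a 1-column matrix), or a \linkS4class{CoordinateTrajectory} (the metric
#'   is \code{\link{metricRMSD}} with the trajectory's alignment and metric
#'   subsets).
#' @param k number of clusters (<= number of frames).
#' @param initialIndex index of the seeding frame, default 1 (the
#'   seeding rule is not part of the method; a fixed deterministic start
#'   makes runs reproducible).
#' @param stride optional frame stride: centers are chosen among the strided
#'   frames only, but every frame is assigned. Default 1 (all frames).
#' @return A \linkS4class{Clustering}.
#' @examples
#' cl <- kCenter(c(0, 10, 1, 9, 5), k = 2)
#' crispAssignment(cl)
#' @export
kCenter <- function(frames, k, initialIndex = 1L, stride = 1L) {
  if (is(frames, "CoordinateTrajectory"))
    return(.kCenterRMSD(frames, k, initialIndex))
  if (is.null(dim(frames)))
    frames <- matrix(as.numeric(frames), ncol = 1L)
  n <- nrow(frames)
  k <- as.integer(k)
  if (k > n) stop(sprintf("k = %d exceeds the number of frames (%d)", k, n))
  stopifnot(k >= 1, initialIndex >= 1, initialIndex <= n)
  candidates <- seq(1L, n, by = as.integer(stride))
  centers <- integer(k)
  centers[1] <- as.integer(initialIndex)
  d2 <- rowSums(sweep(frames, 2, frames[centers[1], ])^2)  # squared dist
  assignment <- rep(1L, n)
  if (k > 1) {
    for (j in 2:k) {
      far <- candidates[which.max(d2[candidates])]
      centers[j] <- far
      nd2 <- rowSums(sweep(frames, 2, frames[far, ])^2)
      closer <- nd2 < d2           # strict: ties keep the earlier center
      assignment[closer] <- j
      d2[closer] <- nd2[closer]
    }
  }
  dist <- sqrt(d2)
  radii <- vapply(seq_len(k), function(j) {
    m <- dist[assignment == j]
    if (length(m)) max(m) else 0
  }, numeric(1))
  meanD <- vapply(seq_len(k), function(j) {
    m <- dist[assignment == j]
    if (length(m)) mean(m) else 0
  }, numeric(1))
  new("Clustering", k = k, centerFrames = centers, assignment = assignment,
      distToCenter = dist, radii = radii, meanDist = meanD,
      metric = sprintf("euclidean/%dd", ncol(frames)),
      centerValues = frames[centers, , drop = FALSE])
}

## k-center on a CoordinateTrajectory under the alignment/metric RMSD.
.kCenterRMSD <- function(traj, k, initialIndex = 1L) {
  n <- nFrames(traj)
  k <- as.integer(k)
  if (k > n) stop(sprintf("k = %d exceeds the number of frames (%d)", k, n))
  al <- traj@alignmentSubset; me <- traj@metricSubset
  if (!length(al) || !length(me))
    stop("trajectory must carry alignment and metric subsets")
  dTo <- function(ci) {
    ref <- getFrame(traj, ci)
    vapply(seq_len(n), function(f)
      metricRMSD(getFrame(traj, f), ref, al, me), numeric(1))
  }
  centers <- integer(k)
  centers[1] <- as.integer(initialIndex)
  d <- dTo(centers[1])
  assignment <- rep(1L, n)
  if (k > 1) {
    for (j in 2:k) {
      far <- which.max(d)
      centers[j] <- far
      nd <- dTo(far)
      closer <- nd < d
      assignment[closer] <- j
      d[closer] <- nd[closer]
    }
  }
  radii <- vapply(seq_len(k), function(j) {
    m <- d[assignment == j]; if (length(m)) max(m) else 0
  }, numeric(1))
  meanD <- vapply(seq_len(k), function(j) {
    m <- d[assignment == j]; if (length(m)) mean(m) else 0
  }, numeric(1))
  new("Clustering", k = k, centerFrames = centers, assignment = assignment,
      distToCenter = d, radii = radii, meanDist = meanD,
      metric = "rmsd(align,metric)", centerValues = NULL)
}

#' Assign frames to an existing clustering
#'
#' Nearest-center assignment under the clustering's metric; assigning the
#' training frames reproduces the stored assignment exactly; ties break to
#' the lowest center index; an empty frame set yields an empty result.
#'
#' @param frames numeric matrix/vector of new frames (matrix-metric
#'   clusterings only).
#' @param clustering a \linkS4class{Clustering} built from a numeric matrix.
#' @return integer vector of cluster labels.
#' @export
assignFrames <- function(frames, clustering) {
  if (is.null(clustering@centerValues))
    stop("assignFrames requires a clustering with stored center coordinates")
  if (is.null(dim(frames)))
    frames <- matrix(as.numeric(frames), ncol = ncol(clustering@centerValues))
  if (!nrow(frames)) return(integer())
  d2 <- rowSums(sweep(frames, 2, clustering@centerValues[1, ])^2)
  assignment <- rep(1L, nrow(frames))
  for (j in seq_len(clustering@k)[-1]) {
    nd2 <- rowSums(sweep(frames, 2, clustering@centerValues[j, ])^2)
    closer <- nd2 < d2
    assignment[closer] <- j
    d2[closer] <- nd2[closer]
  }
  assignment
}

#' Serialize a clustering as TSV (assignments + center sidecar)
#'
#' Writes `<path>` with one row per frame (`frame_id<TAB>cluster`) and
#' `<path>.centers.tsv` listing per-cluster center frame, radius and mean
#' member-to-center distance.
#'
#' @param clustering a \linkS4class{Clustering}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeClustering <- function(clustering, path) {
  df <- data.frame(frame_id = seq_along(clustering@assignment) - 1L,
                   cluster = clustering@assignment)
  con <- file(path, "w")
  writeLines(sprintf("# k=%d metric=%s", clustering@k, clustering@metric),
             con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  side <- data.frame(cluster = seq_len(clustering@k),
                     center_frame = clustering@centerFrames - 1L,
                     radius = clustering@radii,
                     mean_dist = clustering@meanDist)
  write.table(side, paste0(path, ".centers.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
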