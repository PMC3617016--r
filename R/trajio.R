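## Plain-text trajectory IO.
##
## FeatureTrajectory CSV dialect: an optional metadata comment line
##   # time_unit=<u> frame_interval=<dt> source=<s>
## then a header row `frame,time,<coord names...>`, frames 0-indexed and
## contiguous, time = frame * frame_interval. CoordinateTrajectory uses
## standard multi-frame XYZ. All lengths are Angstrom.

#' Write a FeatureTrajectory as CSV
#'
#' @param traj a \linkS4class{FeatureTrajectory}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureCSV <- function(traj, path) {
  stopifnot(is(traj, "FeatureTrajectory"))
  v <- traj@values
  n <- nrow(v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# time_unit=%s frame_interval=%.17g source=%s",
                     traj@timeUnit, traj@frameInterval, traj@source), con)
  writeLines(paste(c("frame", "time", colnames(v)), collapse = ","), con)
  frame <- seq_len(n) - 1L
  body <- cbind(frame, frame * traj@frameInterval, v)
  writeLines(apply(format(body, digits = 17, trim = TRUE, scientific = NA),
                   1, paste, collapse = ","), con)
  invisible(path)
}

#' Read a FeatureTrajectory from CSV
#'
#' Errors (naming the offending line) on ragged rows, non-contiguous or
#' non-monotone frame indices, a missing header, or an empty file.
#'
#' @param path CSV file written by \code{\link{writeFeatureCSV}} (or matching
#'   its dialect).
#' @return A \linkS4class{FeatureTrajectory}.
#' @export
readFeatureCSV <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  meta <- list(timeUnit = "ns", frameInterval = NA_real_, source = "")
  headerAt <- 1L
  if (length(lines) && startsWith(lines[1], "#")) {
    kv <- regmatches(lines[1],
                     gregexpr("[A-Za-z_]+=[^ ]*", lines[1]))[[1]]
    for (item in kv) {
      key <- sub("=.*", "", item); val <- sub("^[^=]*=", "", item)
      if (key == "time_unit") meta$timeUnit <- val
      if (key == "frame_interval") meta$frameInterval <- as.numeric(val)
      if (key == "source") meta$source <- val
    }
    headerAt <- 2L
  }
  if (length(lines) < headerAt)
    stop("empty file: ", path)
  header <- strsplit(lines[headerAt], ",", fixed = TRUE)[[1]]
  if (length(header) < 3L || header[1] != "frame" || header[2] != "time")
    stop(sprintf("missing or malformed header at line %d (expected 'frame,time,<coords>')",
                 headerAt))
  body <- lines[-seq_len(headerAt)]
  body <- body[nzchar(body)]
  if (!length(body)) stop("no data rows in ", path)
  parts <- strsplit(body, ",", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != length(header))) {
    bad <- which(nc != length(header))[1]
    stop(sprintf("ragged row at line %d: %d fields, expected %d",
                 bad + headerAt, nc[bad], length(header)))
  }
  num <- matrix(as.numeric(unlist(parts)), ncol = length(header),
                byrow = TRUE)
  if (anyNA(num)) {
    bad <- which(apply(num, 1, anyNA))[1]
    stop(sprintf("non-numeric value at line %d", bad + headerAt))
  }
  frames <- num[, 1]
  expect <- seq_len(nrow(num)) - 1
  if (any(frames != expect)) {
    bad <- which(frames != expect)[1]
    stop(sprintf("non-contiguous frames at line %d (frame %g, expected %g)",
                 bad + headerAt, frames[bad], expect[bad]))
  }
  dt <- meta$frameInterval
  if (is.na(dt)) {
    dt <- if (nrow(num) >= 2) num[2, 2] - num[1, 2] else 1
    if (dt <= 0) stop("cannot infer a positive frame interval from the time column")
  }
  vals <- num[, -(1:2), drop = FALSE]
  colnames(vals) <- header[-(1:2)]
  featureTrajectory(vals, frameInterval = dt, timeUnit = meta$timeUnit,
                    source = meta$source)
}

#' Write a CoordinateTrajectory as multi-frame XYZ
#'
#' @param traj a \linkS4class{CoordinateTrajectory}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeXYZ <- function(traj, path) {
  stopifnot(is(traj, "CoordinateTrajectory"))
  d <- dim(traj@coords)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(d[3])) {
    writeLines(as.character(d[1]), con)
    writeLines(sprintf("frame %d", f - 1L), con)
    fr <- traj@coords[, , f]
    writeLines(sprintf("%s %.10f %.10f %.10f", traj@atomLabels,
                       fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ file as a CoordinateTrajectory
#'
#' @param path XYZ file (atom-count line, comment line, then
#'   \code{element x y z} rows, repeated per frame).
#' @param alignmentSubset,metricSubset optional atom index subsets to attach.
#' @param frameInterval time between frames, default 1.
#' @param timeUnit unit label, default \code{"ns"}.
#' @return A \linkS4class{CoordinateTrajectory}.
#' @export
readXYZ <- function(path, alignmentSubset = integer(),
                    metricSubset = integer(), frameInterval = 1,
                    timeUnit = "ns") {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  pos <- 1L
  frames <- list()
  labels <- NULL
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat))
      stop(sprintf("expected an atom count at line %d", pos))
    if (pos + 1L + nat > length(lines))
      stop(sprintf("truncated frame starting at line %d", pos))
    rows <- lines[(pos + 2L):(pos + 1L + nat)]
    parts <- strsplit(trimws(rows), "[[:space:]]+")
    if (any(lengths(parts) != 4L))
      stop(sprintf("malformed atom row near line %d", pos + 2L))
    lab <- vapply(parts, `[[`, character(1), 1L)
    xyz <- matrix(as.numeric(vapply(parts, function(p) p[2:4],
                                    character(3))),
                  ncol = 3, byrow = TRUE)
    if (is.null(labels)) labels <- lab
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + 2L + nat
    while (pos <= length(lines) && !nzchar(trimws(lines[pos])))
      pos <- pos + 1L
  }
  if (!length(frames)) stop("no frames in ", path)
  coords <- array(unlist(frames), dim = c(nrow(frames[[1]]), 3,
                                          length(frames)))
  coordinateTrajectory(coords, atomLabels = labels,
                       alignmentSubset = alignmentSubset,
                       metricSubset = metricSubset,
                       frameInterval = frameInterval, timeUnit = timeUnit)
}

#' Write generator ground truth as a key-value sidecar
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeTruthSidecar <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("seed=%d", truth@seed), con)
  writeLines(sprintf("stationary=%s",
                     paste(sprintf("%.17g", truth@stationary),
                           collapse = ",")), con)
  n <- nrow(truth@mfptMatrix)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    writeLines(sprintf("mfpt_%d_%d=%.17g", i, j, truth@mfptMatrix[i, j]),
               con)
  tu <- truth@params$timeUnit
  if (!is.null(tu)) writeLines(sprintf("time_unit=%s", tu), con)
  invisible(path)
}
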