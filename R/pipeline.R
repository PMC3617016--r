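## Pipeline orchestration: configuration, presets, staged execution and
## serialized outputs. The command-line wrapper in inst/scripts/msm_pipeline.R
## is a thin shell over these functions.

#' Convert a physical time to a whole number of frames
#'
#' Aborts (naming both values) when the time is not an exact multiple of the
#' frame interval -- a silently rounded dwell or lag would change the model
#' semantics.
#'
#' @param time physical time.
#' @param frameInterval frame interval in the same unit.
#' @return integer number of frames.
#' @export
timeToFrames <- function(time, frameInterval) {
  frames <- time / frameInterval
  if (abs(frames - round(frames)) > 1e-9 * max(1, abs(frames)))
    stop(sprintf(
      "time %g is not a whole number of frames at frame interval %g",
      time, frameInterval))
  as.integer(round(frames))
}

#' Build a validated pipeline configuration
#'
#' Times (\code{finalLagTime}, \code{dwellTime}, \code{lagTimes}) are given
#' in physical units and must convert to whole frames exactly. The
#' \code{"rnap"} preset carries the settings used for the polymerase system
#' (200 microstates, lag scan to a plateau, final lag 4.5 ns, dwell 50 ps at
#' a 2 ps save interval, 2 macrostates, 100 bootstrap replicates); the
#' \code{"twostate-demo"} preset carries the desk-scale calibrated two-state
#' study (k = 50 microstates on the 1D coordinate, lag scan {1,2,5,10,20}
#' frames at 1 ns, final lag 5 frames, dwell 1 frame, 2 macrostates, 100
#' bootstrap replicates).
#'
#' @param preset \code{"twostate-demo"}, \code{"rnap"}, or NULL for a fully
#'   manual configuration.
#' @param ... field overrides (highest precedence): \code{frameInterval},
#'   \code{timeUnit}, \code{k}, \code{lagTimes}, \code{finalLagTime},
#'   \code{dwellTime}, \code{macrostates} (count or \code{"auto"}),
#'   \code{bootstrapReplicates}, \code{seed}, \code{weighting}
#'   (\code{"msm"} or \code{"uniform"}), \code{pmfBins}, \code{coordName}.
#' @return a validated list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(preset = "twostate-demo", ...) {
  base <- list(frameInterval = 1, timeUnit = "ns", k = 50L,
               lagTimes = c(1, 2, 5, 10, 20), finalLagTime = 5,
               dwellTime = 1, macrostates = 2L, bootstrapReplicates = 100L,
               seed = 1L, weighting = "msm", pmfBins = 50L,
               coordName = "d1", sliding = TRUE, preset = "manual")
  if (!is.null(preset)) {
    base <- switch(preset,
      "twostate-demo" = utils::modifyList(base, list(preset = preset)),
      "rnap" = utils::modifyList(base, list(
        frameInterval = 0.002, timeUnit = "ns", k = 200L,
        lagTimes = c(0.5, 1, 2, 3, 4, 4.5, 5, 6),
        finalLagTime = 4.5, dwellTime = 0.05, macrostates = 2L,
        bootstrapReplicates = 100L, preset = preset)),
      stop("unknown preset: ", preset))
  }
  cfg <- utils::modifyList(base, list(...))
  validatePipelineConfig(cfg)
}

#' Validate a pipeline configuration
#' @param cfg a configuration list.
#' @return the validated config (class \code{PipelineConfig}); errors name
#'   the offending field.
#' @export
validatePipelineConfig <- function(cfg) {
  if (!is.numeric(cfg$frameInterval) || cfg$frameInterval <= 0)
    stop("config field frameInterval: must be > 0")
  if (!is.numeric(cfg$k) || cfg$k < 1)
    stop("config field k: must be a positive cluster count")
  for (f in c("lagTimes", "finalLagTime", "dwellTime")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || any(v <= 0))
      stop(sprintf("config field %s: must be positive", f))
    tryCatch(vapply(v, timeToFrames, integer(1), cfg$frameInterval),
             error = function(e)
               stop(sprintf("config field %s: %s", f, conditionMessage(e)),
                    call. = FALSE))
  }
  if (!identical(cfg$macrostates, "auto") &&
      (!is.numeric(cfg$macrostates) || cfg$macrostates < 2))
    stop("config field macrostates: must be >= 2 or \"auto\"")
  if (!cfg$weighting %in% c("msm", "uniform"))
    stop("config field weighting: must be \"msm\" or \"uniform\"")
  if (!is.numeric(cfg$bootstrapReplicates) || cfg$bootstrapReplicates < 2)
    stop("config field bootstrapReplicates: must be >= 2")
  cfg$k <- as.integer(cfg$k)
  cfg$bootstrapReplicates <- as.integer(cfg$bootstrapReplicates)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys are \code{\link{pipelineConfig}} fields
#'   (an optional \code{preset} key selects the base preset).
#' @return a validated \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  raw <- yaml::read_yaml(path)
  preset <- raw$preset %||% "twostate-demo"
  raw$preset <- NULL
  do.call(pipelineConfig, c(list(preset = preset), raw))
}

#' Run the MSM pipeline on feature trajectories
#'
#' Executes the staged analysis: k-center splitting of the frames into
#' microstates, lag-scan implied timescales, transition-model estimation at
#' the final lag on the largest ergodic subset, PCCA+ lumping into
#' macrostates, MFPTs, trajectory bootstrap, residence validation, and PMF
#' projection.
#'
#' @param trajectories list of \linkS4class{FeatureTrajectory} (or a single
#'   one) sharing the configured frame interval.
#' @param config a \code{PipelineConfig}.
#' @param stages character vector of stages to run (any of \code{"cluster"},
#'   \code{"its"}, \code{"build"}, \code{"validate"}, \code{"mfpt"},
#'   \code{"bootstrap"}, \code{"pmf"}); default all. Later stages pull in
#'   the earlier ones they need.
#' @return list of class \code{MSMPipelineResult} with elements
#'   \code{clustering}, \code{dtrajs}, \code{its}, \code{countsFinal},
#'   \code{ergodic}, \code{microModel}, \code{memberships}, \code{macro},
#'   \code{mfpt}, \code{bootstrap}, \code{residence}, \code{pmf},
#'   \code{config}, plus a \code{log} of stage summaries.
#' @export
runPipeline <- function(trajectories, config,
                        stages = c("cluster", "its", "build", "validate",
                                   "mfpt", "bootstrap", "pmf")) {
  if (is(trajectories, "FeatureTrajectory"))
    trajectories <- list(trajectories)
  cfg <- if (inherits(config, "PipelineConfig")) config else
    validatePipelineConfig(config)
  logLines <- character()
  note <- function(...) {
    msg <- sprintf(...)
    logLines <<- c(logLines, msg)
    message(msg)
  }
  dt <- cfg$frameInterval
  lagF <- timeToFrames(cfg$finalLagTime, dt)
  dwellF <- timeToFrames(cfg$dwellTime, dt)
  lagsF <- vapply(cfg$lagTimes, timeToFrames, integer(1), dt)

  values <- do.call(rbind, lapply(trajectories, function(tr)
    featureValues(tr)[, cfg$coordName, drop = FALSE]))
  lens <- vapply(trajectories, nFrames, integer(1))
  note("cluster: %d frames from %d trajectories, k = %d",
       nrow(values), length(trajectories), cfg$k)
  clustering <- kCenter(values, cfg$k)
  bounds <- cumsum(c(0L, lens))
  paths <- lapply(seq_along(lens), function(j)
    clustering@assignment[(bounds[j] + 1L):bounds[j + 1L]])
  dtrajs <- discreteTrajectories(paths, nStates = cfg$k,
                                 frameInterval = dt,
                                 timeUnit = cfg$timeUnit)
  its <- NULL
  if ("its" %in% stages) {
    its <- impliedTimescales(dtrajs, lagsF,
                             nTimescales = max(
                               2L,
                               if (identical(cfg$macrostates, "auto")) 5L
                               else cfg$macrostates),
                             dwellFrames = dwellF, sliding = cfg$sliding)
    note("its: lags {%s} frames", paste(lagsF, collapse = ", "))
  }
  countsFinal <- suppressWarnings(
    countTransitions(dtrajs, lagF, dwellF, cfg$sliding))
  ergodic <- largestErgodicSubset(countsFinal)
  note("build: lag %d frames, ergodic subset %d / %d microstates (%.1f%% of counts)",
       lagF, nrow(ergodic@counts), cfg$k,
       100 * sum(ergodic@counts) / sum(countsFinal@counts))
  microModel <- transitionModel(ergodic)
  m <- if (identical(cfg$macrostates, "auto")) {
    sel <- chooseMacrostateCount(its, lagF)
    note("build: macrostate count auto-selected m = %d (gap ratios %s)",
         sel$m, paste(signif(sel$ratios, 3), collapse = ", "))
    sel$m
  } else as.integer(cfg$macrostates)
  memberships <- pccaPlus(ergodic, m)
  macro <- lumpMacrostates(ergodic, memberships, microModel)
  note("build: macrostate populations %s",
       paste(sprintf("%.4f", macro@populations), collapse = ", "))
  mfptM <- NULL
  if ("mfpt" %in% stages) mfptM <- mfpt(macro)
  boot <- NULL
  if ("bootstrap" %in% stages) {
    macroAssignment <- rep(NA_integer_, cfg$k)
    macroAssignment[ergodic@stateLabels] <- macro@assignment
    boot <- bootstrapMSM(dtrajs, macroAssignment, lagF, dwellF,
                         cfg$sliding, cfg$bootstrapReplicates, cfg$seed)
    macro <- attachBootstrap(macro, boot)
    note("bootstrap: %d replicates used, %d degenerate",
         boot$nReplicates, boot$nDegenerate)
  }
  residence <- NULL
  if ("validate" %in% stages) {
    residence <- validateResidence(macro, dtrajs, multiples = 1:10,
                                   microLabels = ergodic@stateLabels)
    note("validate: max |predicted - observed| residence = %s",
         paste(signif(residence$maxAbsDeviation, 3), collapse = ", "))
  }
  pmfGrid <- NULL
  if ("pmf" %in% stages) {
    pi <- setNames(microModel@stationary, ergodic@stateLabels)
    pmfGrid <- pmfProject(trajectories, cfg$coordName, bins = cfg$pmfBins,
                          weighting = cfg$weighting,
                          microAssignment = clustering@assignment, pi = pi)
  }
  out <- list(clustering = clustering, dtrajs = dtrajs, its = its,
              countsFinal = countsFinal, ergodic = ergodic,
              microModel = microModel, memberships = memberships,
              macro = macro, mfpt = mfptM, bootstrap = boot,
              residence = residence, pmf = pmfGrid, config = cfg,
              log = logLines)
  class(out) <- c("MSMPipelineResult", "list")
  out
}

#' Identify the macrostate containing the lowest-coordinate basin
#'
#' For a 1D reaction coordinate (e.g. the PPi--Mg2+A distance), returns the
#' macrostate whose member microstate has the smallest center value -- the
#' "bound" basin near the active site; the other macrostates are channel-like
#' released basins.
#'
#' @param result an \code{MSMPipelineResult}.
#' @return integer macrostate index.
#' @export
boundMacrostate <- function(result) {
  centers <- result$clustering@centerValues[, 1]
  ergLabels <- result$ergodic@stateLabels
  lowMicro <- ergLabels[which.min(centers[ergLabels])]
  result$macro@assignment[match(lowMicro, ergLabels)]
}

#' Write all pipeline artifacts to a directory
#'
#' Serializes the clustering, the final count and transition matrices, the
#' implied-timescale table, macrostate tables (populations, MFPT, residence
#' curves) and the PMF, plus a run log recording the configuration and seed.
#' Reruns with an identical configuration and seed are byte-identical.
#'
#' @param result an \code{MSMPipelineResult}.
#' @param dir output directory (created if needed).
#' @return invisible character vector of files written.
#' @export
writePipelineOutputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  f <- file.path(dir, "clustering.tsv")
  writeClustering(result$clustering, f)
  files <- c(files, f, paste0(f, ".centers.tsv"))
  f <- file.path(dir, "counts.tsv")
  writeMatrixTSV(result$countsFinal, f); files <- c(files, f)
  f <- file.path(dir, "transition_matrix.tsv")
  writeMatrixTSV(result$microModel, f); files <- c(files, f)
  if (!is.null(result$its)) {
    f <- file.path(dir, "implied_timescales.csv")
    con <- file(f, "w")
    writeLines(sprintf("# implied timescales in %s",
                       attr(result$its, "timeUnit")), con)
    write.csv(as.data.frame(result$its), con, row.names = FALSE,
              quote = FALSE)
    close(con)
    files <- c(files, f)
  }
  files <- c(files, writeMacrostateTables(result$macro, dir,
                                          result$residence))
  if (!is.null(result$pmf)) {
    f <- file.path(dir, "pmf.csv")
    writePMF(result$pmf, f); files <- c(files, f)
  }
  f <- file.path(dir, "run_log.txt")
  cfg <- result$config
  cfgLines <- vapply(sort(names(cfg)), function(nm)
    sprintf("%s=%s", nm, paste(format(cfg[[nm]]), collapse = ",")),
    character(1))
  writeLines(c(sprintf("# run log; config_hash=%s; seed=%d",
                       .configHash(cfg), cfg$seed),
               cfgLines, "", result$log), f)
  files <- c(files, f)
  invisible(files)
}

.configHash <- function(cfg) {
  s <- paste(vapply(sort(names(cfg)), function(nm)
    paste(nm, paste(format(cfg[[nm]]), collapse = ","), sep = "="),
    character(1)), collapse = ";")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}
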