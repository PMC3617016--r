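## Macrostate models: lumping, MFPT linear solves, trajectory bootstrap,
## residence-probability validation.

#' Lump a microstate count matrix into a macrostate model
#'
#' Macro counts are sums of micro counts over member pairs; the macro
#' transition matrix is the row-normalized macro counts. Macrostate
#' populations are reported at two levels: sums of the microstate stationary
#' distribution over members (primary, the master-equation fixed point of the
#' micro model) and the stationary distribution of the lumped matrix itself
#' (count-level cross-check).
#'
#' @param counts a \linkS4class{CountMatrix} restricted to the ergodic subset.
#' @param memberships fuzzy membership matrix from \code{\link{pccaPlus}}
#'   (rows = the microstates of \code{counts}), or a crisp integer assignment
#'   vector.
#' @param microModel optional \linkS4class{TransitionModel} of the same
#'   counts; estimated internally when missing.
#' @return A \linkS4class{MacrostateModel}.
#' @export
lumpMacrostates <- function(counts, memberships, microModel = NULL) {
  stopifnot(is(counts, "CountMatrix"))
  N <- counts@counts
  n <- nrow(N)
  if (is.matrix(memberships)) {
    chi <- memberships
    assignment <- as.integer(apply(chi, 1, which.max))
  } else {
    assignment <- as.integer(memberships)
    m0 <- max(assignment)
    chi <- matrix(0, n, m0)
    chi[cbind(seq_len(n), assignment)] <- 1
  }
  if (nrow(chi) != n)
    stop("membership rows must match the count matrix dimension")
  m <- ncol(chi)
  if (any(tabulate(assignment, m) == 0L))
    stop("empty macrostate in the crisp assignment")
  if (is.null(microModel)) microModel <- transitionModel(counts)
  ind <- matrix(0, n, m)
  ind[cbind(seq_len(n), assignment)] <- 1
  macroN <- t(ind) %*% N %*% ind
  macroT <- macroN / rowSums(macroN)
  pops <- as.numeric(t(ind) %*% microModel@stationary)
  pops <- pops / sum(pops)
  le <- eigen(t(macroT))
  iu <- which.min(Mod(le$values - 1))
  pc <- Re(le$vectors[, iu]); pc <- pmax(pc / sum(pc), 0); pc <- pc / sum(pc)
  new("MacrostateModel", nMacro = as.integer(m), memberships = chi,
      assignment = assignment, counts = macroN, probs = macroT,
      populations = pops, populationsCount = pc,
      lagFrames = counts@lagFrames, frameInterval = counts@frameInterval,
      timeUnit = counts@timeUnit, bootstrap = list())
}

#' Mean first passage times by exact linear solve
#'
#' For each target state f, the MFPTs solve
#' \code{MFPT[i, f] = sum_j P[i, j] (tLag + MFPT[j, f])} with the boundary
#' condition \code{MFPT[f, f] = 0}; equivalently
#' \code{(I - P[-f, -f]) m = tLag * 1}, solved exactly (no iteration
#' tolerance). For an irreducible 2-state chain this reduces to
#' \code{MFPT(1 -> 2) = tLag / P[1, 2]}.
#'
#' @param x a row-stochastic matrix, a \linkS4class{MacrostateModel} or a
#'   \linkS4class{TransitionModel}.
#' @param lagTime physical time per lag step (e.g. 4.5 ns); defaults to
#'   \code{lagFrames(x) * frameInterval} for model objects.
#' @return matrix of MFPTs in \code{lagTime} units; diagonal 0.
#' @examples
#' mfpt(matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE), lagTime = 4.5)
#' @export
mfpt <- function(x, lagTime = NULL) {
  if (is(x, "MacrostateModel") || is(x, "TransitionModel")) {
    P <- x@probs
    if (is.null(lagTime)) lagTime <- x@lagFrames * x@frameInterval
  } else {
    P <- as.matrix(x)
    if (is.null(lagTime)) stop("lagTime is required for a bare matrix")
  }
  if (any(abs(rowSums(P) - 1) > 1e-9)) stop("matrix is not row-stochastic")
  n <- nrow(P)
  ## irreducibility check on the probability graph
  g <- igraph::graph_from_adjacency_matrix((P > 0) * 1, mode = "directed")
  if (igraph::components(g, mode = "strong")$no != 1L)
    stop("transition matrix is reducible; MFPTs are not all finite")
  M <- matrix(0, n, n)
  I <- diag(n - 1L)
  for (f in seq_len(n)) {
    keep <- setdiff(seq_len(n), f)
    A <- I - P[keep, keep, drop = FALSE]
    M[keep, f] <- solve(A, rep(lagTime, n - 1L))
  }
  M
}

#' Trajectory bootstrap of macrostate populations and MFPTs
#'
#' Resamples whole trajectories with replacement to the original count
#' (the resampling unit is the trajectory, matching how the seeding
#' simulations are independent units), holding the microstate definition and
#' the macrostate assignment fixed, and rebuilds counts -> ergodic subset ->
#' transition model -> lumped model -> populations and MFPT per replicate.
#' Replicates whose resample loses a macrostate entirely are recorded and
#' excluded.
#'
#' @param dtrajs a \linkS4class{DiscreteTrajectorySet}.
#' @param macroAssignment crisp microstate -> macrostate labels for all
#'   \code{nStates} microstates (NA allowed for never-ergodic microstates).
#' @param lagFrames,dwellFrames,sliding counting parameters of the model.
#' @param nReplicates number of bootstrap replicates (>= 2), default 100.
#' @param seed integer seed.
#' @return list with \code{popMean}, \code{popSd}, \code{mfptMean},
#'   \code{mfptSd} (matrices in physical time units), \code{nReplicates}
#'   (used), \code{nDegenerate} (excluded) and the per-replicate draws in
#'   \code{popDraws} / \code{mfptDraws}.
#' @export
bootstrapMSM <- function(dtrajs, macroAssignment, lagFrames,
                         dwellFrames = 1L, sliding = TRUE,
                         nReplicates = 100L, seed = 1L) {
  stopifnot(nReplicates >= 2)
  nTraj <- length(dtrajs@paths)
  nStates <- dtrajs@nStates
  m <- max(macroAssignment, na.rm = TRUE)
  perTraj <- .perTrajectoryCounts(dtrajs, lagFrames, dwellFrames, sliding)
  lagTime <- lagFrames * dtrajs@frameInterval
  set.seed(as.integer(seed))
  popDraws <- matrix(NA_real_, nReplicates, m)
  mfptDraws <- array(NA_real_, dim = c(m, m, nReplicates))
  nDegenerate <- 0L
  for (r in seq_len(nReplicates)) {
    pick <- sample.int(nTraj, nTraj, replace = TRUE)
    N <- Reduce(`+`, perTraj[pick])
    cm <- new("CountMatrix", counts = N, lagFrames = as.integer(lagFrames),
              dwellFrames = as.integer(dwellFrames), sliding = sliding,
              stateLabels = seq_len(nStates),
              frameInterval = dtrajs@frameInterval,
              timeUnit = dtrajs@timeUnit)
    ok <- tryCatch({
      erg <- largestErgodicSubset(cm)
      assign <- macroAssignment[erg@stateLabels]
      if (anyNA(assign) || length(unique(assign)) < m)
        stop("macrostate lost")
      micro <- transitionModel(erg)
      macro <- lumpMacrostates(erg, assign, micro)
      popDraws[r, ] <- macro@populations
      mfptDraws[, , r] <- mfpt(macro, lagTime)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) nDegenerate <- nDegenerate + 1L
  }
  used <- !is.na(popDraws[, 1])
  if (!any(used)) stop("all bootstrap replicates were degenerate")
  list(popMean = colMeans(popDraws[used, , drop = FALSE]),
       popSd = apply(popDraws[used, , drop = FALSE], 2, sd),
       mfptMean = apply(mfptDraws[, , used, drop = FALSE], c(1, 2), mean),
       mfptSd = apply(mfptDraws[, , used, drop = FALSE], c(1, 2), sd),
       nReplicates = sum(used), nDegenerate = nDegenerate,
       popDraws = popDraws[used, , drop = FALSE],
       mfptDraws = mfptDraws[, , used, drop = FALSE])
}

#' Attach a bootstrap summary to a MacrostateModel
#' @param model a \linkS4class{MacrostateModel}.
#' @param boot result of \code{\link{bootstrapMSM}}.
#' @return the model with the bootstrap slot filled.
#' @export
attachBootstrap <- function(model, boot) {
  model@bootstrap <- boot[c("popMean", "popSd", "mfptMean", "mfptSd",
                            "nReplicates", "nDegenerate")]
  model
}

#' MFPT table with bootstrap uncertainties
#' @param model a \linkS4class{MacrostateModel}.
#' @param lagTime physical time per lag step; default from the model.
#' @return data frame from, to, mfpt, sd (NA without a bootstrap).
#' @export
mfptTable <- function(model, lagTime = NULL) {
  M <- mfpt(model, lagTime)
  m <- nrow(M)
  idx <- which(row(M) != col(M))
  data.frame(from = row(M)[idx], to = col(M)[idx], mfpt = M[idx],
             sd = if (length(model@bootstrap))
               model@bootstrap$mfptSd[idx] else NA_real_)
}

#' Residence-probability validation of a macrostate model
#'
#' Compares, for each macrostate A and each multiple n of the model lag, the
#' model prediction \code{[T_macro^n][A, A]} with the fraction of frames in A
#' that are still (or again) in A after n * lag frames, counted directly from
#' the discrete trajectories with a sliding window. A Markovian lumping
#' reproduces the observed curves within sampling error; a lumping that
#' hides a slow process does not.
#'
#' @param model a \linkS4class{MacrostateModel}.
#' @param dtrajs the \linkS4class{DiscreteTrajectorySet} the model was built
#'   from.
#' @param multiples integer lag multiples n (>= 1; n = 0 trivially gives 1).
#' @param microLabels optional mapping of the model's microstates to the
#'   original labels (from \code{stateLabels} of the ergodic counts);
#'   defaults to identity.
#' @return list with \code{curves} (data frame: macrostate, n, predicted,
#'   observed, nObs) and \code{maxAbsDeviation} per macrostate; points where
#'   n * lag exceeds every trajectory are flagged NA.
#' @export
validateResidence <- function(model, dtrajs, multiples = 1:10,
                              microLabels = NULL) {
  stopifnot(all(multiples >= 0))
  m <- model@nMacro
  lag <- model@lagFrames
  if (is.null(microLabels)) microLabels <- seq_along(model@assignment)
  ## macro label per original microstate (NA when outside the model)
  macroOf <- rep(NA_integer_, dtrajs@nStates)
  macroOf[microLabels] <- model@assignment
  sortedMult <- sort(unique(as.integer(multiples)))
  predAt <- list()
  p <- diag(m); lastN <- 0L
  for (n in sortedMult) {
    while (lastN < n) { p <- p %*% model@probs; lastN <- lastN + 1L }
    predAt[[as.character(n)]] <- diag(p)
  }
  rows <- list()
  for (ni in seq_along(sortedMult)) {
    n <- sortedMult[ni]
    shift <- n * lag
    stay <- numeric(m); tot <- numeric(m)
    for (path in dtrajs@paths) {
      L <- length(path)
      if (shift >= L) next
      a <- macroOf[path]
      from <- a[seq_len(L - shift)]
      to <- a[seq_len(L - shift) + shift]
      okf <- !is.na(from) & !is.na(to)
      for (A in seq_len(m)) {
        sel <- okf & from == A
        tot[A] <- tot[A] + sum(sel)
        stay[A] <- stay[A] + sum(to[sel] == A)
      }
    }
    for (A in seq_len(m)) {
      rows[[length(rows) + 1L]] <- data.frame(
        macrostate = A, n = n,
        predicted = predAt[[as.character(n)]][A],
        observed = if (tot[A] > 0) stay[A] / tot[A] else NA_real_,
        nObs = tot[A])
    }
  }
  curves <- do.call(rbind, rows)
  dev <- vapply(seq_len(m), function(A) {
    sub <- curves[curves$macrostate == A & !is.na(curves$observed), ]
    if (!nrow(sub)) return(NA_real_)
    max(abs(sub$predicted - sub$observed))
  }, numeric(1))
  list(curves = curves, maxAbsDeviation = dev)
}

#' Write population / MFPT / residence outputs as delimited text
#' @param model a \linkS4class{MacrostateModel} (with bootstrap attached for
#'   uncertainty columns).
#' @param dir output directory (created if needed).
#' @param residence optional result of \code{\link{validateResidence}}.
#' @return invisible vector of the files written.
#' @export
writeMacrostateTables <- function(model, dir, residence = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  bs <- model@bootstrap
  lagT <- model@lagFrames * model@frameInterval
  popPath <- file.path(dir, "populations.tsv")
  con <- file(popPath, "w")
  writeLines(sprintf("# macrostate populations; lag=%g %s", lagT,
                     model@timeUnit), con)
  write.table(data.frame(
    macrostate = seq_len(model@nMacro),
    population = model@populations,
    sd = if (length(bs)) bs$popSd else NA_real_), con, sep = "\t",
    quote = FALSE, row.names = FALSE)
  close(con)
  files <- c(files, popPath)
  mfptPath <- file.path(dir, "mfpt.tsv")
  con <- file(mfptPath, "w")
  writeLines(sprintf("# mean first passage times in %s; lag=%g %s",
                     model@timeUnit, lagT, model@timeUnit), con)
  write.table(mfptTable(model), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  close(con)
  files <- c(files, mfptPath)
  if (!is.null(residence)) {
    resPath <- file.path(dir, "residence.csv")
    con <- file(resPath, "w")
    writeLines(sprintf("# residence probabilities; lag=%g %s", lagT,
                       model@timeUnit), con)
    write.csv(residence$curves, con, row.names = FALSE, quote = FALSE)
    close(con)
    files <- c(files, resPath)
  }
  invisible(files)
}
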