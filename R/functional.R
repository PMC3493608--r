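#' Construct a TimeSeriesSet
#'
#' @param series numeric n_vertices x n_timepoints matrix.
#' @param tr sampling interval, seconds.
#' @param subject subject identifier.
#' @param hemisphere `"left"` or `"right"`.
#' @return a [TimeSeriesSet-class].
#' @export
TimeSeriesSet <- function(series, tr = 3.5, subject = "s1", hemisphere = "left") {
  series <- as.matrix(series)
  storage.mode(series) <- "double"
  new("TimeSeriesSet", series = series, tr = tr, subject = subject,
      hemisphere = hemisphere)
}

#' Estimate spatial smoothness (FWHM, mm) of a surface field
#'
#' Assuming a Gaussian spatial autocorrelation, the neighbour correlation
#' implied by first differences across mesh edges, `r = 1 - var(diff) /
#' (2 var(field))`, gives the smoothing-kernel FWHM as
#' `d * sqrt(-2 log(2) / log(r))` for edge length `d`. Edges are grouped by
#' length (regular tessellations have few classes), the estimate is pooled
#' over timepoints, and classes are combined weighted by edge count.
#' Unsmoothed data (`r <= 0`) contribute 0.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param x numeric vector (one field) or n x T matrix of per-vertex data,
#'   or a [TimeSeriesSet-class].
#' @return scalar FWHM estimate in mm (0 for spatially white data).
#' @export
estimateFwhm <- function(mesh, x) {
  if (is(x, "TimeSeriesSet")) x <- x@series
  x <- as.matrix(x)
  el <- meshEdges(mesh)
  fieldVar <- mean(apply(x, 2L, stats::var))
  if (fieldVar == 0) return(0)
  d2 <- (x[el$edges[, 1L], , drop = FALSE] - x[el$edges[, 2L], , drop = FALSE])^2
  cls <- round(el$lengths, 6)
  ucls <- sort(unique(cls))
  fw <- w <- numeric(length(ucls))
  for (i in seq_along(ucls)) {
    sel <- cls == ucls[i]
    r <- 1 - mean(d2[sel, ]) / (2 * fieldVar)
    w[i] <- sum(sel)
    fw[i] <- if (r <= 0 || r >= 1) 0 else ucls[i] * sqrt(-2 * log(2) / log(r))
  }
  sum(fw * w) / sum(w)
}

## Row-normalized one-step smoothing operator: Gaussian 1-ring weights with
## bandwidth tau (mm), self-weight 1.
smoothingOperator <- function(mesh, tau) {
  el <- meshEdges(mesh)
  n <- nrow(mesh@vertices)
  wgt <- exp(-el$lengths^2 / (2 * tau^2))
  S <- Matrix::sparseMatrix(
    i = c(seq_len(n), el$edges[, 1L], el$edges[, 2L]),
    j = c(seq_len(n), el$edges[, 2L], el$edges[, 1L]),
    x = c(rep(1, n), wgt, wgt), dims = c(n, n))
  Matrix::Diagonal(x = 1 / Matrix::rowSums(S)) %*% S
}

#' Heat-kernel smoothing of surface time series to a target FWHM
#'
#' Iterative normalized Gaussian weighting over 1-ring neighbours
#' (bandwidth `targetFwhm / 4`, capped at twice the mean edge length),
#' re-estimating the achieved smoothness with [estimateFwhm()] after every
#' iteration and stopping once it reaches the target (within the
#' estimator's step resolution; the contract is the achieved FWHM, within
#' about 10 percent of the target). The per-timepoint spatial mean is
#' restored exactly after every step, so spatially constant fields are
#' fixed points.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param ts a [TimeSeriesSet-class] or an n x T matrix.
#' @param targetFwhm target smoothness in mm; must exceed the estimated
#'   smoothness of the input.
#' @param maxIter iteration cap (reaching it is an error).
#' @return object of the same type as `ts`, smoothed.
#' @export
heatSmooth <- function(mesh, ts, targetFwhm, maxIter = 500L) {
  isSet <- is(ts, "TimeSeriesSet")
  x <- if (isSet) ts@series else as.matrix(ts)
  if (all(apply(x, 2L, stats::var) == 0)) return(ts)  # constants are fixed points
  current <- estimateFwhm(mesh, x)
  if (targetFwhm <= current)
    stop(sprintf("already smoother than target (%.2f mm >= %.2f mm)",
                 current, targetFwhm))
  tau <- min(targetFwhm / 4, 2 * meanEdgeLength(mesh))
  S <- smoothingOperator(mesh, tau)
  m0 <- colMeans(x)
  for (it in seq_len(maxIter)) {
    x <- as.matrix(S %*% x)
    x <- sweep(x, 2L, colMeans(x) - m0)    # restore spatial mean exactly
    current <- estimateFwhm(mesh, x)
    if (current >= 0.95 * targetFwhm) break
    if (it == maxIter)
      stop("failed to reach target FWHM within iteration cap")
  }
  if (isSet) {
    ts@series <- x
    ts
  } else x
}

#' Cross-hemispheric correlation argmax for one subject
#'
#' Correlates every non-excluded seed vertex's time series with every
#' non-excluded contralateral vertex's (Pearson), returning per seed the
#' maximum correlation and the index attaining it (functional
#' correspondence). Computed blockwise, so peak memory is
#' `O(blockSize x n_targets)` while results stay exact; the dense
#' seed x target block is retained only when small or requested.
#'
#' @param seedTs,targetTs [TimeSeriesSet-class] objects with equal
#'   timepoint counts (opposite hemispheres).
#' @param excludeSeed,excludeTarget logical per-vertex exclusion flags
#'   (medial wall); default none.
#' @param keepDense `TRUE`, `FALSE`, or `NA` (default: keep when
#'   `n_seed * n_target <= 1.6e7`).
#' @param blockSize seed rows per block.
#' @return a [CrossCorrSummary-class]. Zero-variance rows are excluded
#'   with a warning and carry `NA` sentinels.
#' @export
crossHemiCorrelation <- function(seedTs, targetTs, excludeSeed = NULL,
                                 excludeTarget = NULL, keepDense = NA,
                                 blockSize = 2048L) {
  Xs <- seedTs@series; Xt <- targetTs@series
  if (ncol(Xs) != ncol(Xt))
    stop("timepoint counts differ between hemispheres")
  if (is.null(excludeSeed)) excludeSeed <- rep(FALSE, nrow(Xs))
  if (is.null(excludeTarget)) excludeTarget <- rep(FALSE, nrow(Xt))
  excludeSeed <- excludeSeed | flagZeroVar(Xs, excludeSeed)
  excludeTarget <- excludeTarget | flagZeroVar(Xt, excludeTarget)
  Zs <- standardizeRows(Xs, excludeSeed, "time series")
  Zt <- standardizeRows(Xt, excludeTarget, "time series")
  if (is.na(keepDense))
    keepDense <- nrow(Xs) * as.numeric(nrow(Xt)) <= 1.6e7
  dense <- NULL
  if (keepDense) {
    dense <- Zs %*% t(Zt)
    dense[excludeSeed, ] <- NA_real_
    dense[, excludeTarget] <- NA_real_
  }
  am <- blockArgmax(Zs, Zt, excludeSeed, excludeTarget, blockSize)
  new("CrossCorrSummary", maxCorr = am$value, argmaxIndex = am$index,
      direction = if (seedTs@hemisphere == "left") "LR" else "RL",
      dense = dense, nTarget = nrow(Xt))
}

clampedAtanh <- function(b) {
  b[] <- atanh(pmin(1 - 1e-15, pmax(-1 + 1e-15, b)))
  b
}

flagZeroVar <- function(x, already) {
  v <- apply(x, 1L, stats::sd) == 0
  extra <- v & !already
  if (any(extra))
    warning(sprintf("%d zero-variance time series excluded (first: vertex %d)",
                    sum(extra), which(extra)[1L]))
  v
}

#' Entrywise group average of per-subject correlation matrices
#'
#' The group cross-correlation structure is the arithmetic mean of the
#' per-subject correlation matrices (optionally averaged on the Fisher-z
#' scale); the group functional correspondence is the argmax of this
#' averaged matrix, not the average of per-subject argmaxes.
#'
#' @param blocks list of equally sized numeric matrices.
#' @param fisherZ average `atanh(rho)` and back-transform.
#' @return numeric matrix.
#' @export
groupAverageCorrelation <- function(blocks, fisherZ = FALSE) {
  stopifnot(length(blocks) >= 1L)
  dims <- dim(blocks[[1L]])
  for (b in blocks) if (!all(dim(b) == dims))
    stop("inconsistent correlation block shapes")
  if (fisherZ) {
    acc <- Reduce(`+`, lapply(blocks, clampedAtanh))
    tanh(acc / length(blocks))
  } else {
    Reduce(`+`, blocks) / length(blocks)
  }
}

#' Group functional correspondence from multi-subject time series
#'
#' Forms each subject's left x right time-series correlation matrix
#' (blockwise), averages across subjects, and extracts the argmax
#' functional correspondence in both directions (row argmax for left
#' seeds, column argmax for right seeds). Ties break to the lowest index.
#'
#' @param subjects list of per-subject lists with [TimeSeriesSet-class]
#'   elements `left` and `right`.
#' @param excludeLeft,excludeRight logical exclusion flags per hemisphere.
#' @param fisherZ average correlations on the Fisher-z scale.
#' @param keepDense keep and return the group dense matrix (left x right);
#'   `NA`: keep when it fits comfortably in memory.
#' @param blockSize seed rows per block for the streaming path.
#' @return list with `lr` and `rl` ([CorrespondenceMap-class], kind
#'   `"functional"`) and `dense` (group matrix or `NULL`).
#' @export
functionalCorrespondence <- function(subjects, excludeLeft = NULL,
                                     excludeRight = NULL, fisherZ = FALSE,
                                     keepDense = NA, blockSize = 2048L) {
  stopifnot(length(subjects) >= 1L)
  nL <- nrow(subjects[[1L]]$left@series)
  nR <- nrow(subjects[[1L]]$right@series)
  if (is.null(excludeLeft)) excludeLeft <- rep(FALSE, nL)
  if (is.null(excludeRight)) excludeRight <- rep(FALSE, nR)
  for (s in subjects) {
    excludeLeft <- excludeLeft | apply(s$left@series, 1L, stats::sd) == 0
    excludeRight <- excludeRight | apply(s$right@series, 1L, stats::sd) == 0
  }
  ZL <- lapply(subjects, function(s)
    standardizeRows(s$left@series, excludeLeft, "time series"))
  ZR <- lapply(subjects, function(s)
    standardizeRows(s$right@series, excludeRight, "time series"))
  if (is.na(keepDense)) keepDense <- nL * as.numeric(nR) <= 1.6e7

  zfun <- if (fisherZ) clampedAtanh else identity
  backfun <- if (fisherZ) tanh else identity

  keepL <- which(!excludeLeft); keepR <- which(!excludeRight)
  lrIdx <- rep(NA_integer_, nL); lrVal <- rep(NA_real_, nL)
  rlIdx <- rep(NA_integer_, nR); rlVal <- rep(NA_real_, nR)
  colBest <- rep(-Inf, length(keepR)); colArg <- rep(NA_integer_, length(keepR))
  dense <- if (keepDense) matrix(NA_real_, nL, nR) else NULL

  for (start in seq(1L, length(keepL), by = blockSize)) {
    rows <- keepL[start:min(start + blockSize - 1L, length(keepL))]
    C <- 0
    for (s in seq_along(subjects))
      C <- C + zfun(ZL[[s]][rows, , drop = FALSE] %*% t(ZR[[s]][keepR, , drop = FALSE]))
    C <- backfun(C / length(subjects))
    if (keepDense) dense[rows, keepR] <- C
    j <- max.col(C, ties.method = "first")
    lrIdx[rows] <- keepR[j]
    lrVal[rows] <- pmin(1, pmax(-1, C[cbind(seq_along(rows), j)]))
    cm <- apply(C, 2L, which.max)
    cv <- C[cbind(cm, seq_along(keepR))]
    upd <- cv > colBest
    colBest[upd] <- cv[upd]
    colArg[upd] <- rows[cm[upd]]
  }
  rlIdx[keepR] <- colArg
  rlVal[keepR] <- pmin(1, pmax(-1, colBest))

  list(
    lr = new("CorrespondenceMap", targetIndex = lrIdx, score = lrVal,
             direction = "LR", kind = "functional", nTarget = nR),
    rl = new("CorrespondenceMap", targetIndex = rlIdx, score = rlVal,
             direction = "RL", kind = "functional", nTarget = nL),
    dense = dense)
}
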