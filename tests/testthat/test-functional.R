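test_that("heat smoothing: fixed points, diffusion shape, preconditions", {
  g <- planarGridMesh(25, 25, 1)
  n <- nVertices(g)

  cst <- matrix(7, n, 3)
  expect_equal(heatSmooth(g, cst, 8), cst)

  # delta function: maximum stays put, mass decays with distance
  delta <- matrix(0, n, 1)
  center <- 313L                       # middle of the grid
  delta[center, 1] <- 1
  sm <- heatSmooth(g, delta, 4)
  expect_equal(which.max(sm[, 1]), center)
  d <- geodesicDistance(g, center)
  bins <- cut(d, breaks = c(-1, 0.5, 1.6, 2.6, 3.6))
  binMeans <- tapply(sm[, 1], bins, mean)
  expect_true(all(diff(binMeans) < 0))

  # spatial mean preserved; smoothing something already smooth errors
  set.seed(9)
  x <- matrix(rnorm(n * 4), n) + 50
  sx <- heatSmooth(g, x, 5)
  expect_equal(colMeans(sx), colMeans(x), tolerance = 1e-9)
  expect_error(heatSmooth(g, sx, 2), "already smoother than target")

  # smoothing strictly increases lag-1 spatial autocorrelation
  el <- cbind(faces(g)[, 1], faces(g)[, 2])
  lag1 <- function(z) cor(z[el[, 1]], z[el[, 2]])
  expect_gt(lag1(sx[, 1]), lag1(x[, 1]))
})

test_that("achieved FWHM lands within 10 percent of the target", {
  g <- planarGridMesh(50, 50, 1)
  set.seed(2)
  x <- matrix(rnorm(nVertices(g) * 4), nVertices(g))
  expect_lt(estimateFwhm(g, x), 2)     # white noise: essentially unsmoothed
  sm <- heatSmooth(g, x, 6)
  est <- estimateFwhm(g, sm)
  expect_gte(est, 0.9 * 6)
  expect_lte(est, 1.1 * 6)
})

test_that("cross-hemispheric argmax: planted correlates and brute force", {
  set.seed(5)
  T <- 80
  seedX <- matrix(rnorm(6 * T), 6)
  targetX <- matrix(rnorm(9 * T), 9)
  targetX[4, ] <- seedX[2, ]                       # exact copy
  targetX[7, ] <- seedX[5, ] + 0.1 * rnorm(T)      # planted noisy correlate
  sTs <- TimeSeriesSet(seedX, hemisphere = "left")
  tTs <- TimeSeriesSet(targetX, hemisphere = "right")
  cc <- crossHemiCorrelation(sTs, tTs)

  expect_equal(cc@argmaxIndex[2], 4L)
  expect_equal(cc@maxCorr[2], 1, tolerance = 1e-12)
  expect_equal(cc@argmaxIndex[5], 7L)

  full <- cor(t(seedX), t(targetX))                # exhaustive oracle
  expect_equal(cc@argmaxIndex, apply(full, 1, which.max))
  expect_equal(cc@maxCorr, apply(full, 1, max), tolerance = 1e-10)
  expect_equal(cc@dense, full, tolerance = 1e-10)

  # exact directional symmetry of the correlation itself
  ccRev <- crossHemiCorrelation(tTs, sTs)
  expect_equal(ccRev@dense, t(cc@dense), tolerance = 1e-12)
  expect_equal(direction(cc), "LR")
  expect_equal(direction(ccRev), "RL")

  expect_error(crossHemiCorrelation(sTs, TimeSeriesSet(targetX[, 1:50])),
               "timepoint counts differ")
  flat <- targetX; flat[3, ] <- 2
  expect_warning(cc2 <- crossHemiCorrelation(sTs, TimeSeriesSet(flat)),
                 "zero-variance")
  expect_true(all(cc2@argmaxIndex != 3L, na.rm = TRUE))

  # blockwise path is exact
  cc3 <- crossHemiCorrelation(sTs, tTs, blockSize = 2L)
  expect_equal(cc3@argmaxIndex, cc@argmaxIndex)
  expect_equal(cc3@maxCorr, cc@maxCorr)
})

test_that("group averaging is the entrywise mean with optional Fisher z", {
  A <- matrix(c(0.2, -0.5, 0.9, 0.1), 2)
  expect_equal(groupAverageCorrelation(list(A, A)), A)
  expect_equal(groupAverageCorrelation(list(A, -A)), matrix(0, 2, 2))

  set.seed(6)
  blocks <- replicate(3, matrix(runif(100, -1, 1), 10), simplify = FALSE)
  loop <- matrix(0, 10, 10)
  for (b in blocks) loop <- loop + b
  expect_equal(groupAverageCorrelation(blocks), loop / 3, tolerance = 1e-12)

  fz <- tanh((atanh(blocks[[1]]) + atanh(blocks[[2]]) + atanh(blocks[[3]])) / 3)
  expect_equal(groupAverageCorrelation(blocks, fisherZ = TRUE), fz,
               tolerance = 1e-12)

  expect_error(groupAverageCorrelation(list(A, matrix(0, 3, 3))),
               "inconsistent")
})

test_that("group functional correspondence equals argmax of averaged matrix", {
  set.seed(8)
  n <- 30; T <- 50
  subjects <- lapply(1:3, function(s) list(
    left = TimeSeriesSet(matrix(rnorm(n * T), n), hemisphere = "left"),
    right = TimeSeriesSet(matrix(rnorm(n * T), n), hemisphere = "right")))
  fc <- functionalCorrespondence(subjects, keepDense = TRUE)
  oracle <- groupAverageCorrelation(lapply(subjects, function(s)
    cor(t(tsMatrix(s$left)), t(tsMatrix(s$right)))))
  expect_equal(fc$dense, oracle, tolerance = 1e-10)
  expect_equal(targetIndex(fc$lr), apply(oracle, 1, which.max))
  expect_equal(targetIndex(fc$rl), apply(oracle, 2, which.max))
  # argmax of the average, not average of per-subject argmaxes: check value
  expect_equal(matchScore(fc$lr), apply(oracle, 1, max), tolerance = 1e-10)

  # streaming (small blocks, no dense) agrees exactly
  fc2 <- functionalCorrespondence(subjects, keepDense = FALSE, blockSize = 7L)
  expect_null(fc2$dense)
  expect_equal(targetIndex(fc2$lr), targetIndex(fc$lr))
  expect_equal(targetIndex(fc2$rl), targetIndex(fc$rl))
  expect_equal(matchScore(fc2$rl), matchScore(fc$rl), tolerance = 1e-12)

  # excluded vertices never appear as seed or target
  excl <- rep(FALSE, n); excl[c(2, 9)] <- TRUE
  fc3 <- functionalCorrespondence(subjects, excludeLeft = excl)
  expect_true(all(is.na(targetIndex(fc3$lr)[c(2, 9)])))
  expect_true(all(!targetIndex(fc3$rl) %in% c(2L, 9L), na.rm = TRUE))
})
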