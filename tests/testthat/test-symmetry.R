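test_that("AFCD is the target-hemisphere distance between AC and FC", {
  cm <- chainMesh(6, spacing = 1, hemisphere = "right")
  n <- nVertices(cm)
  ac <- idMap(n)
  expect_equal(afcd(ac, idMap(n, kind = "functional"), cm), rep(0, n))

  # FC displaced by exactly k chain edges -> k mm
  k <- 3L
  fcIdx <- c(seq_len(6 - k) + k, rep(6L, k), 7:n)    # chain part shifted
  fc <- CorrespondenceMap(fcIdx, rep(0.5, n), "LR", "functional", n)
  expect_equal(afcd(ac, fc, cm)[1:(6 - k)], rep(k, 6 - k))

  # random maps against the all-pairs oracle
  m <- randomSmallMesh(13)
  D <- floydWarshall(m)
  set.seed(14)
  i <- sample(nVertices(m), nVertices(m), TRUE)
  j <- sample(nVertices(m), nVertices(m), TRUE)
  acr <- CorrespondenceMap(i, rep(1, length(i)), "LR", "anatomical", nVertices(m))
  fcr <- CorrespondenceMap(j, rep(1, length(j)), "LR", "functional", nVertices(m))
  expect_equal(afcd(acr, fcr, m), D[cbind(i, j)], tolerance = 1e-12)

  expect_error(afcd(ac, CorrespondenceMap(1:n, rep(1, n), "RL",
                                          "functional", n), cm),
               "direction mismatch")
})

test_that("FAD separates true asymmetry from criss-cross patterns", {
  lm <- chainMesh(8, hemisphere = "left")
  n <- nVertices(lm)
  acLR <- idMap(n); acRL <- idMap(n, "RL")
  fcSym <- idMap(n, kind = "functional")
  fcSymRL <- idMap(n, "RL", kind = "functional")

  # fully symmetric -> FAD 0 everywhere
  expect_equal(fad(acLR, fcSym, fcSymRL, lm, acRL), rep(0, n))

  # criss-cross: seeds 1 and 6 swap functional targets
  swapLR <- seq_len(n); swapLR[c(1, 6)] <- c(6L, 1L)
  fcX <- CorrespondenceMap(swapLR, rep(0.5, n), "LR", "functional", n)
  fcXRL <- CorrespondenceMap(swapLR, rep(0.5, n), "RL", "functional", n)
  fadX <- fad(acLR, fcX, fcXRL, lm, acRL)
  afcdX <- afcd(acLR, fcX, lm)
  expect_equal(fadX[c(1, 6)], c(0, 0))       # hand-chained: both project to 6,1
  expect_equal(afcdX[c(1, 6)], c(5, 5))      # while AFCD sees the 5 mm swap

  # one-sided displacement of k mm: FAD = k on the chain
  k <- 2L
  oneSided <- c(seq_len(8 - k) + k, rep(8L, k), 9:n)
  fcD <- CorrespondenceMap(oneSided, rep(0.5, n), "LR", "functional", n)
  fadD <- fad(acLR, fcD, fcSymRL, lm, acRL)
  expect_equal(fadD[1:(8 - k)], rep(k, 8 - k))

  # sentinel propagation with a warning
  brokenIdx <- seq_len(n); brokenIdx[2] <- NA
  broken <- CorrespondenceMap(brokenIdx, rep(NA_real_, n), "LR",
                              "functional", n)
  expect_warning(fb <- fad(acLR, broken, fcSymRL, lm, acRL),
                 "excluded chain members")
  expect_true(is.na(fb[2]))
  expect_equal(fb[-2], rep(0, n - 1))
})

test_that("high-FAD clustering applies threshold, size filter and adjacency", {
  m <- icosphereMesh(2, radius = 80)
  n <- nVertices(m)
  mel <- meanEdgeLength(m)

  expect_equal(nrow(highFadClusters(rep(50, n), m, threshold = 100)), 0L)

  # one 25-vertex and one 10-vertex supra-threshold patch; min 20 keeps one
  d1 <- geodesicDistance(m, 1L)
  patchA <- order(d1)[1:25]
  far <- which.max(d1)
  patchB <- order(geodesicDistance(m, far))[1:10]
  stopifnot(length(intersect(patchA, patchB)) == 0)
  fadv <- rep(10, n)
  fadv[patchA] <- 150
  fadv[patchB] <- 180
  ct <- highFadClusters(fadv, m, threshold = 100, minVertices = 20L)
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$size, 25L)
  expect_setequal(ct$vertices[[1]], patchA)
  ct2 <- highFadClusters(fadv, m, threshold = 100, minVertices = 5L)
  expect_equal(ct2$size, c(10L, 25L))        # ordered by descending mean FAD
  expect_gt(ct2$areaMm2[2], ct2$areaMm2[1])

  # two patches joined only through a sub-threshold vertex stay separate
  cm <- chainMesh(9)
  fadc <- rep(0, nVertices(cm))
  fadc[c(1, 2, 3)] <- 200
  fadc[c(5, 6, 7)] <- 200                    # vertex 4 stays below
  cc <- highFadClusters(fadc, cm, threshold = 100, minVertices = 2L)
  expect_equal(nrow(cc), 2L)
  expect_equal(sort(unlist(cc$vertices)), c(1, 2, 3, 5, 6, 7))

  # percentile thresholds and permutation equivariance
  set.seed(15)
  fr <- runif(n, 0, 120)
  cp <- highFadClusters(fr, m, threshold = "p90", minVertices = 1L)
  expect_equal(sum(cp$size), sum(fr > quantile(fr, 0.9)))
  perm <- sample(n)
  mperm <- SurfaceMesh(vertices(m)[perm, ],
                       matrix(match(faces(m), perm), ncol = 3))
  cpp <- highFadClusters(fr[perm], mperm, threshold = "p90", minVertices = 1L)
  expect_equal(cpp$size, cp$size)
  expect_equal(cpp$meanFad, cp$meanFad, tolerance = 1e-12)
})

test_that("average correlation maps over seed sets", {
  set.seed(16)
  dense <- matrix(rnorm(200), 20)
  expect_equal(averageCorrMap(4L, dense), dense[4, ])
  dense2 <- dense; dense2[2, ] <- -dense[1, ]
  expect_equal(averageCorrMap(c(1L, 2L), dense2), rep(0, 10))
  seeds <- c(3L, 7L, 11L, 15L, 19L)
  loop <- rep(0, 10)
  for (s in seeds) loop <- loop + dense[s, ]
  expect_equal(averageCorrMap(seeds, dense), loop / 5, tolerance = 1e-12)
  expect_error(averageCorrMap(integer(), dense), "empty seed set")
})

test_that("map similarity is 1 for symmetric structure and low under noise", {
  set.seed(17)
  n <- 12
  ac <- idMap(n)
  # symmetric structure: dense[v, w] depends only on (v, w) symmetric pattern
  base <- matrix(rnorm(n * n), n)
  sym <- (base + t(base)) / 2
  ms <- mapSimilarity(ac, sym)
  expect_equal(ms$rho, rep(1, n), tolerance = 1e-6)
  expect_true(all(ms$mask))

  # independent noise rows: similarity small, rarely above 0.2
  nullHits <- replicate(200, {
    noisy <- matrix(rnorm(n * n), n)
    v <- sample(n, 1)
    a <- noisy[v, ]; b <- rnorm(n)
    abs(cor(a, b))
  })
  expect_lt(mean(nullHits > 0.6), 0.05)

  # hand-built example against a direct Pearson computation
  d4 <- rbind(c(1, .2, .1, 0), c(.2, 1, .3, .1),
              c(.1, .3, 1, .4), c(0, .1, .4, 1))
  ac4 <- idMap(4)
  byHand <- sapply(1:4, function(v) cor(d4[v, ], d4[, v]))
  expect_equal(mapSimilarity(ac4, d4)$rho, byHand, tolerance = 1e-12)
})

test_that("tSNR asymmetry testing flags systematic hemisphere differences", {
  T <- 40
  z <- as.numeric(scale(rnorm(T)))         # exactly mean 0, sd 1
  mk <- function(mean, sd, n = 3) TimeSeriesSet(
    matrix(rep(mean + sd * z, n), n, byrow = TRUE), hemisphere = "left")
  expect_equal(rowMeans(tsMatrix(mk(100, 10))) /
                 apply(tsMatrix(mk(100, 10)), 1, sd), rep(10, 3))

  nSub <- 10
  set.seed(18)
  mkSub <- function(tsnrs, hemi) lapply(seq_len(nSub), function(s)
    TimeSeriesSet(do.call(rbind, lapply(tsnrs[, s], function(tv)
      tv + 1 * as.numeric(scale(rnorm(T))))), hemisphere = hemi))
  # 4 vertices: vertex 1 has left tSNR above right in every subject
  # (distinct differences, so the exact signed-rank null applies)
  rightT <- matrix(10, 4, nSub)
  leftT <- rightT
  leftT[1, ] <- 10 + seq(0.6, 1.5, by = 0.1)
  res <- tsnrAsymmetry(mkSub(leftT, "left"), mkSub(rightT, "right"),
                       idMap(4, "RL"), alpha = 0.01)
  expect_true(res$flagged[1])
  # identical tSNRs elsewhere: differences are pure noise, p never tiny
  expect_equal(res$p[1], 2 / 2^nSub, tolerance = 1e-12)  # exact all-positive
  expect_false(any(res$p[2:4] < 1e-3, na.rm = TRUE))

  expect_error(tsnrAsymmetry(mkSub(leftT, "left")[1:3],
                             mkSub(rightT, "right")[1:3], idMap(4, "RL")),
               "at least 6 subjects")
})
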