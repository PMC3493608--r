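# Shared mirrored scene (no time series needed here).
hp2 <- makeHemispherePair(2, perturb = 0, seed = 11)
parcL2 <- makeParcellation(hp2$left, 8, seed = 12)
parcR2 <- mirrorParcellation(parcL2, hp2$mirrorMap, hp2$right)
lvL2 <- buildLabelVectors(hp2$left, parcL2)
lvR2 <- buildLabelVectors(hp2$right, parcR2)

test_that("label vectors hold geodesic distances to every centroid", {
  # 3 collinear vertices spaced 1 mm, single-vertex regions at the ends
  cm <- chainMesh(3)
  p <- Parcellation(c(1L, 0L, 2L, 0L, 0L), centroidVertex = c(1L, 3L))
  lv <- buildLabelVectors(cm, p)
  expect_equal(labelVectors(lv)[1:3, ], rbind(c(0, 2), c(1, 1), c(2, 0)))
  expect_true(all(excludedVertices(lv)[c(2, 4, 5)]))

  # each centroid's own column is 0
  cent <- centroidVertices(parcL2)
  expect_equal(labelVectors(lvL2)[cbind(cent, seq_along(cent))],
               rep(0, length(cent)))

  # full matrix equals the all-pairs shortest-path oracle
  m <- randomSmallMesh(7)
  pm <- makeParcellation(m, 5, seed = 8)
  lv2 <- buildLabelVectors(m, pm)
  D <- floydWarshall(m)
  expect_equal(labelVectors(lv2), t(D[centroidVertices(pm), ]),
               tolerance = 1e-12)
})

test_that("anatomical matching: self-match, mirror recovery, brute-force toy", {
  selfm <- matchAnatomical(lvL2, lvL2)
  expect_equal(targetIndex(selfm)[!excludedVertices(lvL2)],
               which(!excludedVertices(lvL2)))
  expect_equal(matchScore(selfm), rep(1, nVertices(lvL2)), tolerance = 1e-12)

  ac <- matchAnatomical(lvL2, lvR2)
  expect_equal(targetIndex(ac), hp2$mirrorMap)
  expect_equal(matchScore(ac), rep(1, nVertices(lvL2)), tolerance = 1e-12)

  # 5-candidate toy: argmax against exhaustive Pearson over all outcomes
  seedRow <- rbind(c(3, 10, 1))
  targets <- rbind(c(2, 9, 0), c(5, 5, 5.1), c(0, 4, 8),
                   c(3.2, 10.3, 0.9), c(1, 1, 7))
  oracle <- apply(targets, 1, function(r) cor(seedRow[1, ], r))
  mkLv <- function(x, hemi) new("LabelVectorSet", distances = x,
                                regionNames = c("a", "b", "c"),
                                hemisphere = hemi,
                                excluded = rep(FALSE, nrow(x)))
  toy <- matchAnatomical(mkLv(seedRow, "left"), mkLv(targets, "right"))
  expect_equal(targetIndex(toy), which.max(oracle))
  expect_equal(matchScore(toy), max(oracle), tolerance = 1e-10)

  # matched-by-name column pairing: permuting target regions changes nothing
  perm <- c(3, 1, 2)
  permLv <- new("LabelVectorSet", distances = targets[, perm],
                regionNames = c("a", "b", "c")[perm], hemisphere = "right",
                excluded = rep(FALSE, 5))
  toy2 <- matchAnatomical(mkLv(seedRow, "left"), permLv)
  expect_equal(targetIndex(toy2), targetIndex(toy))

  expect_error(matchAnatomical(lvL2, mkLv(targets, "right")), "region sets differ")
  degen <- mkLv(rbind(c(1, 1, 1), c(0, 2, 5)), "left")
  expect_error(matchAnatomical(degen, mkLv(targets, "right")),
               "zero-variance label vector at vertex 1")
})

test_that("matrix-product Pearson equals per-pair correlation", {
  set.seed(3)
  A <- matrix(rnorm(60), 10)
  B <- matrix(rnorm(48), 8)
  lvA <- new("LabelVectorSet", distances = abs(A), regionNames = letters[1:6],
             hemisphere = "left", excluded = rep(FALSE, 10))
  lvB <- new("LabelVectorSet", distances = abs(B), regionNames = letters[1:6],
             hemisphere = "right", excluded = rep(FALSE, 8))
  m <- matchAnatomical(lvA, lvB)
  full <- cor(t(abs(A)), t(abs(B)))
  expect_equal(targetIndex(m), apply(full, 1, which.max))
  expect_equal(matchScore(m), apply(full, 1, max), tolerance = 1e-10)
})

test_that("mirror correspondences are near-involutive and edge-continuous", {
  acLR <- matchAnatomical(lvL2, lvR2)
  acRL <- matchAnatomical(lvR2, lvL2)
  roundTrip <- targetIndex(acRL)[targetIndex(acLR)]
  expect_gte(mean(roundTrip == seq_len(nVertices(lvL2))), 0.99)

  # neighbouring seeds map to nearby targets (colour-map continuity)
  mel <- meanEdgeLength(hp2$right)
  f <- faces(hp2$left)
  edges <- unique(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]))
  dTgt <- geodesicPairs(hp2$right,
                        targetIndex(acLR)[edges[, 1]],
                        targetIndex(acLR)[edges[, 2]])
  expect_gte(mean(dTgt <= 3 * mel), 0.95)

  # perturbed mirror: round-trip displacement stays within 2 edge lengths
  hpP <- makeHemispherePair(2, perturb = 1.5, seed = 21)
  pL <- makeParcellation(hpP$left, 8, seed = 12)
  pR <- mirrorParcellation(pL, hpP$mirrorMap, hpP$right)
  aLR <- matchAnatomical(buildLabelVectors(hpP$left, pL),
                         buildLabelVectors(hpP$right, pR))
  aRL <- matchAnatomical(buildLabelVectors(hpP$right, pR),
                         buildLabelVectors(hpP$left, pL))
  rt <- targetIndex(aRL)[targetIndex(aLR)]
  dBack <- geodesicPairs(hpP$left, seq_along(rt), rt)
  expect_lte(median(dBack), 2 * meanEdgeLength(hpP$left))
})

test_that("flip distances: mirror zero, 3-4-5, constructed shift, permutation", {
  expect_equal(flipDistance(rbind(c(10, 5, 5)), rbind(c(-10, 5, 5)))$distance, 0)
  expect_equal(flipDistance(rbind(c(10, 5, 5)), rbind(c(-13, 9, 5)))$distance, 5)

  set.seed(4)
  seeds <- cbind(runif(40, 5, 30), runif(40, -20, 20), runif(40, -20, 20))
  s <- 7.25
  acXyz <- cbind(-seeds[, 1], seeds[, 2] + s, seeds[, 3])
  fd <- flipDistance(seeds, acXyz)
  expect_equal(fd$distance, rep(s, 40), tolerance = 1e-12)
  expect_equal(max(fd$hist$cumFraction), 1)

  perm <- sample(40)
  fdp <- flipDistance(seeds[perm, ], acXyz[perm, ])
  expect_equal(sort(fdp$distance), sort(fd$distance))
  expect_equal(fdp$hist, fd$hist)

  expect_error(flipDistance(matrix(numeric(), 0, 3), matrix(numeric(), 0, 3)),
               "empty input")
})

test_that("flip distance classifies flipped locations against a mask", {
  # default xform: world (x,y,z) sits at voxel (x+1, y+1, z+1)
  # seeds on the negative-x side flip into the grid
  seeds <- rbind(c(-7, 5, 5), c(-8, 4, 6), c(-6, 2, 3))
  acXyz <- cbind(-seeds[, 1], seeds[, 2], seeds[, 3])
  gmEmpty <- RNifti::asNifti(array(0, c(10, 10, 10)))
  gmFull <- RNifti::asNifti(array(1, c(10, 10, 10)))
  expect_equal(flipDistance(seeds, acXyz, mask = gmEmpty)$outsideFraction, 1)
  expect_equal(flipDistance(seeds, acXyz, mask = gmFull)$outsideFraction, 0)
  # seeds flipping beyond the grid are outside regardless of mask values
  far <- rbind(c(-50, 5, 5))
  expect_equal(flipDistance(far, cbind(50, 5, 5),
                            mask = gmFull)$outsideFraction, 1)
})
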