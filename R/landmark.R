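#' Build per-vertex label vectors of geodesic distances to region centroids
#'
#' Each cortical vertex is assigned a K-dimensional label vector whose j-th
#' entry is the geodesic distance (mm) along the surface from the vertex to
#' the centroid landmark of the j-th parcellation region of the same
#' hemisphere. Positions are thereby expressed relative to gyral/sulcal
#' landmarks rather than Cartesian coordinates, which is what makes them
#' comparable across hemispheres.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param parcellation a [Parcellation-class] on the same mesh.
#' @return a [LabelVectorSet-class]; vertices with the reserved label 0 are
#'   flagged excluded (they keep distances, for path continuity, but never
#'   act as seeds or targets).
#' @examples
#' m <- icosphereMesh(2)
#' p <- makeParcellation(m, nRegions = 6, seed = 1)
#' lv <- buildLabelVectors(m, p)
#' lv
#' @export
buildLabelVectors <- function(mesh, parcellation) {
  if (length(parcellation@labels) != nrow(mesh@vertices))
    stop("parcellation vertex count does not match mesh")
  cent <- parcellation@centroidVertex
  if (length(cent) == 0L) stop("parcellation has no regions")
  D <- geodesicRows(mesh, cent)      # K x n
  new("LabelVectorSet",
      distances = t(D),
      regionNames = parcellation@regionNames,
      hemisphere = mesh@hemisphere,
      excluded = parcellation@labels == 0L)
}

## Row-standardize for Pearson-by-matrix-product: subtract row mean,
## divide by row norm. Errors (naming the vertex) on zero-variance
## non-excluded rows.
standardizeRows <- function(x, excluded, what = "row") {
  xc <- x - rowMeans(x)
  nrm <- sqrt(rowSums(xc^2))
  bad <- nrm == 0 & !excluded
  if (any(bad))
    stop(sprintf("zero-variance %s at vertex %d", what, which(bad)[1L]))
  nrm[nrm == 0] <- 1
  xc / nrm
}

#' Construct a CorrespondenceMap
#'
#' Mostly produced by [matchAnatomical()] / [functionalCorrespondence()];
#' the constructor is exported so constructed maps (e.g. hand-built
#' criss-cross patterns) can be analysed with [afcd()] and [fad()].
#'
#' @param targetIndex integer per seed (1-based; `NA` = excluded seed).
#' @param score per-seed match statistic in `[-1, 1]`.
#' @param direction `"LR"` or `"RL"`.
#' @param kind `"anatomical"` or `"functional"`.
#' @param nTarget target-hemisphere vertex count.
#' @return a [CorrespondenceMap-class].
#' @export
CorrespondenceMap <- function(targetIndex, score = rep(NA_real_, length(targetIndex)),
                              direction = "LR", kind = "anatomical",
                              nTarget = max(targetIndex, na.rm = TRUE)) {
  new("CorrespondenceMap", targetIndex = as.integer(targetIndex),
      score = as.numeric(score), direction = direction, kind = kind,
      nTarget = as.integer(nTarget))
}

#' Anatomical correspondence by label-vector matching
#'
#' For every non-excluded seed vertex, finds the contralateral vertex whose
#' label vector has the largest Pearson correlation with the seed's. Region
#' columns are paired across hemispheres by region *name* (annot files may
#' order regions differently per hemisphere). Ties are broken by lowest
#' vertex index, so the map is deterministic.
#'
#' @param seedLV,targetLV [LabelVectorSet-class] objects for the two
#'   hemispheres, with identical region-name sets.
#' @param blockSize seed rows correlated per block (memory control).
#' @return a [CorrespondenceMap-class] of kind `"anatomical"`. Direction is
#'   `"LR"` when the seed set is the left hemisphere, `"RL"` otherwise.
#' @export
matchAnatomical <- function(seedLV, targetLV, blockSize = 2048L) {
  if (length(seedLV@regionNames) != length(targetLV@regionNames) ||
      !setequal(seedLV@regionNames, targetLV@regionNames))
    stop("region sets differ between hemispheres (mismatched counts or names)")
  ord <- match(seedLV@regionNames, targetLV@regionNames)
  Zs <- standardizeRows(seedLV@distances, seedLV@excluded, "label vector")
  Zt <- standardizeRows(targetLV@distances[, ord, drop = FALSE],
                        targetLV@excluded, "label vector")
  am <- blockArgmax(Zs, Zt, seedLV@excluded, targetLV@excluded, blockSize)
  new("CorrespondenceMap", targetIndex = am$index, score = am$value,
      direction = if (seedLV@hemisphere == "left") "LR" else "RL",
      kind = "anatomical", nTarget = nrow(targetLV@distances))
}

## Blockwise argmax of Zs %*% t(Zt) over non-excluded targets; exact.
## Returns lowest index on ties.
blockArgmax <- function(Zs, Zt, exclSeed, exclTarget, blockSize = 2048L) {
  ns <- nrow(Zs)
  keep <- which(!exclTarget)
  if (length(keep) == 0L) stop("all target vertices are excluded")
  Ztk <- Zt[keep, , drop = FALSE]
  idx <- rep(NA_integer_, ns)
  val <- rep(NA_real_, ns)
  seeds <- which(!exclSeed)
  for (start in seq(1L, length(seeds), by = blockSize)) {
    rows <- seeds[start:min(start + blockSize - 1L, length(seeds))]
    C <- Zs[rows, , drop = FALSE] %*% t(Ztk)
    j <- max.col(C, ties.method = "first")
    idx[rows] <- keep[j]
    val[rows] <- C[cbind(seq_along(rows), j)]
  }
  val[!is.na(val)] <- pmin(1, pmax(-1, val[!is.na(val)]))
  list(index = idx, value = val)
}

#' Flip-distance benchmark against x-coordinate mirroring
#'
#' The standard baseline for homotopic localisation negates the x
#' coordinate in a standard volume space. For each seed at `(x, y, z)` this
#' computes the Euclidean distance in volume space between the
#' landmark-based anatomical correspondence `acXyz` and the flipped
#' location `(-x, y, z)`, plus a cumulative histogram (1 mm bins) and,
#' given a grey-matter mask, the fraction of flipped locations that fall
#' outside grey matter.
#'
#' @param seedXyz,acXyz numeric n x 3 matrices of mm coordinates (RAS+);
#'   row i of `acXyz` is the volume-space location of seed i's anatomical
#'   correspondence.
#' @param mask optional grey-matter mask: an `RNifti` image (nonzero =
#'   grey matter) used to classify flipped locations.
#' @return list with `distance` (mm per seed), `hist` (data.frame
#'   `upperMm`, `count`, `cumFraction`), and `outsideFraction` (`NA`
#'   without a mask).
#' @examples
#' flipDistance(matrix(c(10, 5, 5), 1), matrix(c(-13, 9, 5), 1))$distance  # 5
#' @export
flipDistance <- function(seedXyz, acXyz, mask = NULL) {
  seedXyz <- as.matrix(seedXyz); acXyz <- as.matrix(acXyz)
  if (nrow(seedXyz) == 0L) stop("empty input: no seed coordinates")
  if (!all(dim(seedXyz) == dim(acXyz)) || ncol(seedXyz) != 3L)
    stop("seedXyz and acXyz must be matching n x 3 matrices")
  flipped <- seedXyz
  flipped[, 1L] <- -flipped[, 1L]
  d <- sqrt(rowSums((acXyz - flipped)^2))
  upper <- seq_len(max(1, ceiling(max(d))))
  cnt <- vapply(upper, function(u) sum(d > u - 1 & d <= u), numeric(1))
  cnt[1L] <- cnt[1L] + sum(d == 0)
  hist <- data.frame(upperMm = upper, count = cnt,
                     cumFraction = cumsum(cnt) / length(d))
  outside <- NA_real_
  if (!is.null(mask)) {
    vox <- round(RNifti::worldToVoxel(flipped, mask))
    if (!is.matrix(vox)) vox <- matrix(vox, nrow = 1L)
    dims <- dim(mask)[1:3]
    arr <- as.array(mask)
    inGrid <- vox[, 1] >= 1 & vox[, 1] <= dims[1] &
      vox[, 2] >= 1 & vox[, 2] <= dims[2] &
      vox[, 3] >= 1 & vox[, 3] <= dims[3]
    inGm <- inGrid
    if (any(inGrid))
      inGm[inGrid] <- arr[vox[inGrid, , drop = FALSE]] > 0
    outside <- mean(!inGm)
  }
  list(distance = d, hist = hist, outsideFraction = outside)
}
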