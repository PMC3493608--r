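#' Anatomy-to-Functional-Correspondence Distance (AFCD)
#'
#' For each seed vertex, the geodesic distance on the *target* hemisphere
#' between the seed's anatomical correspondence and its functional
#' correspondence. Small AFCD means resting fluctuations are maximally
#' correlated near the homotopic location; large AFCD alone does not imply
#' asymmetry (see [fad()]).
#'
#' @param ac,fc [CorrespondenceMap-class] objects sharing seed hemisphere
#'   and direction (anatomical and functional).
#' @param targetMesh [SurfaceMesh-class] of the target hemisphere.
#' @return numeric per-seed distance (mm); `NA` where either chain member
#'   is excluded.
#' @export
afcd <- function(ac, fc, targetMesh) {
  if (ac@direction != fc@direction)
    stop("direction mismatch between anatomical and functional maps")
  if (length(ac@targetIndex) != length(fc@targetIndex))
    stop("seed counts differ")
  geodesicPairs(targetMesh, ac@targetIndex, fc@targetIndex)
}

#' Functional Asymmetry Distance (FAD)
#'
#' Distinguishes genuinely asymmetric functional organisation from
#' symmetric "criss-cross" patterns (which inflate AFCD): for each left
#' seed `v` with anatomical partner `w = acLR[v]`, the left seed's
#' functional correspondence (a right vertex) is projected back to the
#' left hemisphere through the anatomical mapping, and FAD is the geodesic
#' distance on the left mesh between that projection and the right seed
#' `w`'s functional correspondence (already a left vertex). Symmetric
#' criss-cross patterns yield FAD near 0 however large AFCD is.
#'
#' @param acLR anatomical map, left seeds to right targets.
#' @param fcLR functional map, left seeds to right targets.
#' @param fcRL functional map, right seeds to left targets.
#' @param leftMesh [SurfaceMesh-class] of the reference (left) hemisphere.
#' @param acRL anatomical map, right seeds to left targets (used for the
#'   projection).
#' @return numeric per-left-seed distance (mm); `NA` sentinel (with one
#'   summarising warning) wherever the index chain touches an excluded
#'   vertex.
#' @export
fad <- function(acLR, fcLR, fcRL, leftMesh, acRL) {
  if (acLR@direction != "LR" || fcLR@direction != "LR" ||
      fcRL@direction != "RL" || acRL@direction != "RL")
    stop("map directions inconsistent with LR/RL roles")
  n <- length(acLR@targetIndex)
  if (length(fcLR@targetIndex) != n) stop("seed counts differ")
  w <- acLR@targetIndex                 # right partner of each left seed
  fcLeft <- fcLR@targetIndex            # right vertex
  fcLeftProj <- ifelse(is.na(fcLeft), NA_integer_, acRL@targetIndex[fcLeft])
  fcRight <- ifelse(is.na(w), NA_integer_, fcRL@targetIndex[w])
  bad <- is.na(fcLeftProj) | is.na(fcRight)
  if (any(bad))
    warning(sprintf("%d seeds with excluded chain members set to NA", sum(bad)))
  geodesicPairs(leftMesh, as.integer(fcLeftProj), as.integer(fcRight))
}

#' Clusters of contiguous high-FAD vertices
#'
#' Thresholds the FAD map, takes connected components of the
#' supra-threshold vertex set under mesh edge adjacency, and discards
#' components below the minimum size. The default rule (threshold 100 mm,
#' minimum 20 vertices) isolates the most asymmetric ~5 percent of cortex
#' at full resolution; `threshold` may also be given as a percentile
#' string such as `"p95"`.
#'
#' @param fadValues numeric per-vertex FAD (mm); `NA` never enters clusters.
#' @param mesh the seed-hemisphere [SurfaceMesh-class].
#' @param threshold mm (numeric) or `"pXX"` percentile of non-`NA` values.
#' @param minVertices minimum cluster size in vertices.
#' @return data.frame ordered by descending mean FAD: `cluster`, `size`,
#'   `meanFad`, `areaMm2` (sum of adjacent-face-area thirds, for
#'   reference), and a list column `vertices`.
#' @export
highFadClusters <- function(fadValues, mesh, threshold = 100, minVertices = 20L) {
  if (is.character(threshold)) {
    p <- as.numeric(sub("^p", "", threshold)) / 100
    ## a percentile of a (near-)symmetric map may legitimately be 0 mm
    threshold <- max(0, as.numeric(stats::quantile(fadValues, p, na.rm = TRUE)))
  } else stopifnot(threshold > 0)
  stopifnot(minVertices >= 1L)
  supra <- which(!is.na(fadValues) & fadValues > threshold)
  empty <- data.frame(cluster = integer(), size = integer(),
                      meanFad = numeric(), areaMm2 = numeric())
  empty$vertices <- list()
  if (length(supra) == 0L) return(empty)
  g <- meshGraph(mesh)
  sub <- igraph::induced_subgraph(g, supra)
  comp <- igraph::components(sub)
  varea <- vertexAreas(mesh)
  rows <- lapply(seq_len(comp$no), function(k) {
    vs <- supra[comp$membership == k]
    list(size = length(vs), meanFad = mean(fadValues[vs]),
         areaMm2 = sum(varea[vs]), vertices = vs)
  })
  rows <- Filter(function(r) r$size >= minVertices, rows)
  if (length(rows) == 0L) return(empty)
  ord <- order(vapply(rows, `[[`, numeric(1), "meanFad"), decreasing = TRUE)
  rows <- rows[ord]
  out <- data.frame(cluster = seq_along(rows),
                    size = vapply(rows, `[[`, integer(1), "size"),
                    meanFad = vapply(rows, `[[`, numeric(1), "meanFad"),
                    areaMm2 = vapply(rows, `[[`, numeric(1), "areaMm2"))
  out$vertices <- lapply(rows, `[[`, "vertices")
  out
}

## Per-vertex surface area: one third of each incident triangle's area.
vertexAreas <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 2L], ] - v[f[, 1L], ]
  b <- v[f[, 3L], ] - v[f[, 1L], ]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  fa <- 0.5 * sqrt(rowSums(cr^2))
  out <- numeric(nrow(v))
  for (j in 1:3) {
    s <- tapply(fa, f[, j], sum)
    out[as.integer(names(s))] <- out[as.integer(names(s))] + s / 3
  }
  out
}

#' Average correlation map over a set of seed vertices
#'
#' Arithmetic mean, over the seeds, of each target's correlation value in
#' a dense group correlation block (used to inspect the full graded
#' correlation pattern of a high-FAD cluster rather than only its argmax).
#'
#' @param seedVertices integer seed indices (rows of `dense`).
#' @param dense numeric seeds-by-targets group correlation matrix.
#' @return numeric per-target mean correlation.
#' @export
averageCorrMap <- function(seedVertices, dense) {
  if (length(seedVertices) == 0L) stop("empty seed set")
  colMeans(dense[seedVertices, , drop = FALSE], na.rm = FALSE)
}

#' Similarity of contralateral correlation maps across anatomical pairs
#'
#' For each anatomically corresponding pair `(v, w = ac[v])`, correlates
#' the whole-hemisphere contralateral correlation map of `v` (over right
#' targets) with that of `w` (over left targets) after remapping the left
#' targets to the right hemisphere through the anatomical map: the paired
#' samples are `dense[v, acLR[u]]` vs `dense[u, w]` over non-excluded left
#' vertices `u`. High similarity with high AFCD/FAD indicates
#' quantitative, not qualitative, asymmetry.
#'
#' @param acLR anatomical [CorrespondenceMap-class], left to right.
#' @param dense group left x right correlation matrix.
#' @param threshold positive-similarity display threshold (default 0.2).
#' @return list with `rho` (per left seed) and `mask` (`rho > threshold`).
#' @export
mapSimilarity <- function(acLR, dense, threshold = 0.2) {
  if (is.null(dense)) stop("dense group correlation block required")
  n <- length(acLR@targetIndex)
  u <- which(!is.na(acLR@targetIndex))
  remap <- acLR@targetIndex[u]
  rho <- rep(NA_real_, n)
  for (v in u) {
    a <- dense[v, remap]
    b <- dense[u, acLR@targetIndex[v]]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) >= 3 && stats::sd(a[ok]) > 0 && stats::sd(b[ok]) > 0)
      rho[v] <- stats::cor(a[ok], b[ok])
  }
  list(rho = rho, mask = !is.na(rho) & rho > threshold)
}

#' Temporal-SNR asymmetry test across hemispheres
#'
#' tSNR (temporal mean / temporal SD) is computed per subject per
#' hemisphere; right-hemisphere values are read at each left vertex's
#' anatomically corresponding right vertex, and left-vs-right tSNR pairs
#' are compared across subjects with a Wilcoxon signed-rank test (exact
#' null for small samples, normal approximation with continuity
#' correction otherwise; uncorrected p-values, per the display convention
#' for this check).
#'
#' @param tsLeft,tsRight lists of per-subject [TimeSeriesSet-class]
#'   objects (same subject order).
#' @param ac [CorrespondenceMap-class] with direction `"RL"` (right seeds
#'   to left targets): right vertex `w` contributes to left vertex
#'   `ac[w]`; when several right vertices map to one left vertex the
#'   lowest right index is used. Alternatively direction `"LR"`, in which
#'   case the right partner of left vertex `v` is `ac[v]`.
#' @param alpha significance level for the uncorrected mask (default 0.01).
#' @return data.frame per left vertex: `meanTsnrLeft`, `meanTsnrRight`,
#'   `statistic`, `p`, `flagged`.
#' @export
tsnrAsymmetry <- function(tsLeft, tsRight, ac, alpha = 0.01) {
  stopifnot(length(tsLeft) == length(tsRight))
  nSub <- length(tsLeft)
  if (nSub < 6L) stop("at least 6 subjects required for the signed-rank test")
  nL <- nrow(tsLeft[[1L]]@series)
  if (ac@direction == "RL") {
    partner <- rep(NA_integer_, nL)
    tgt <- ac@targetIndex
    for (w in rev(seq_along(tgt)))      # reverse so lowest w wins collisions
      if (!is.na(tgt[w])) partner[tgt[w]] <- w
  } else {
    partner <- ac@targetIndex
  }
  tsnr <- function(x) {
    s <- apply(x, 1L, stats::sd)
    out <- rowMeans(x) / s
    out[s == 0] <- NA_real_
    out
  }
  TL <- vapply(tsLeft, function(t) tsnr(t@series), numeric(nL))
  TRt <- vapply(tsRight, function(t) tsnr(t@series),
                numeric(nrow(tsRight[[1L]]@series)))
  nzv <- apply(TL, 1L, function(r) any(is.na(r)))
  if (any(nzv))
    warning(sprintf("%d vertices with zero temporal SD excluded", sum(nzv)))
  stat <- p <- rep(NA_real_, nL)
  for (v in seq_len(nL)) {
    w <- partner[v]
    if (is.na(w)) next
    l <- TL[v, ]; r <- TRt[w, ]
    if (any(is.na(l)) || any(is.na(r))) next
    if (all(l == r)) { stat[v] <- 0; p[v] <- 1; next }
    wt <- suppressWarnings(stats::wilcox.test(
      l, r, paired = TRUE, exact = nSub <= 25, correct = TRUE))
    stat[v] <- unname(wt$statistic); p[v] <- wt$p.value
  }
  data.frame(meanTsnrLeft = rowMeans(TL),
             meanTsnrRight = ifelse(is.na(partner), NA_real_,
                                    rowMeans(TRt)[replace(partner, is.na(partner), 1L)]),
             statistic = stat, p = p,
             flagged = !is.na(p) & p < alpha)
}
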