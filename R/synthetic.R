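## Run code with a private, restored RNG stream (generators are
## deterministic given their seed and never disturb the caller's RNG).
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Icosphere mesh (subdivided icosahedron)
#'
#' Unit icosphere with `10 * 4^n + 2` vertices, optionally scaled.
#'
#' @param nSubdiv subdivision level (>= 0).
#' @param radius sphere radius in mm.
#' @param hemisphere tag for the resulting [SurfaceMesh-class].
#' @return a [SurfaceMesh-class].
#' @export
icosphereMesh <- function(nSubdiv = 2L, radius = 1, hemisphere = "left") {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(nSubdiv)) {
    mid <- new.env()
    key <- function(a, b) paste(min(a, b), max(a, b))
    nv <- nrow(v)
    vlist <- list(v)
    midpoint <- function(a, b) {
      k <- key(a, b)
      if (!is.null(mid[[k]])) return(mid[[k]])
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      nv <<- nv + 1L
      vlist[[length(vlist) + 1L]] <<- matrix(m, 1)
      mid[[k]] <- nv
      nv
    }
    nf <- matrix(0L, 4L * nrow(f), 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1L]; b <- f[i, 2L]; cc <- f[i, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[(4L * i - 3L):(4L * i), ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist)
    f <- nf
  }
  SurfaceMesh(v * radius, f, hemisphere = hemisphere)
}

#' Regular planar triangulated grid mesh
#'
#' An `nx` by `ny` grid of vertices at `spacing` mm, each quad split into
#' two triangles. Used for smoothing/FWHM checks where a flat regular
#' tessellation is the natural test bed.
#'
#' @param nx,ny vertex counts along x and y.
#' @param spacing grid spacing in mm.
#' @param hemisphere tag.
#' @return a [SurfaceMesh-class].
#' @export
planarGridMesh <- function(nx, ny, spacing = 1, hemisphere = "left") {
  xy <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  v <- cbind((xy$x - 1) * spacing, (xy$y - 1) * spacing, 0)
  idx <- function(i, j) (j - 1L) * nx + i
  f <- list()
  for (j in seq_len(ny - 1L)) for (i in seq_len(nx - 1L)) {
    f[[length(f) + 1L]] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
    f[[length(f) + 1L]] <- c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  }
  SurfaceMesh(v, do.call(rbind, f), hemisphere = hemisphere)
}

## Smooth random scalar field on a sphere-like mesh: a sum of Gaussian
## bumps at random directions, standardized to unit SD.
smoothRadialField <- function(vertices, nBumps = 12L, width = 0.6) {
  u <- vertices / sqrt(rowSums(vertices^2))
  dirs <- matrix(stats::rnorm(3L * nBumps), nBumps)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  coef <- stats::rnorm(nBumps)
  cosang <- u %*% t(dirs)
  cosang[] <- pmin(1, pmax(-1, cosang))
  ang <- acos(cosang)
  f <- as.numeric(exp(-ang^2 / (2 * width^2)) %*% coef)
  (f - mean(f)) / stats::sd(f)
}

#' Generate a mirrored pair of hemisphere meshes with ground-truth map
#'
#' The left hemisphere is an icosphere scaled to cortical size (default
#' 80 mm radius, matching a human hemisphere's surface area to order of
#' magnitude) with a smooth random radial deformation standing in for
#' folding-scale shape variation. The right hemisphere is its exact mirror
#' (x negated, face orientation fixed), optionally perturbed by an
#' independent smooth radial field of amplitude `perturb` mm. The true
#' homotopic map is returned explicitly (vertex i maps to vertex i by
#' construction).
#'
#' @param nSubdiv icosphere subdivision level (>= 1).
#' @param perturb right-hemisphere radial perturbation amplitude, mm.
#' @param seed RNG seed; output is bitwise reproducible.
#' @param radius nominal sphere radius, mm.
#' @param deformRel relative amplitude of the shared smooth deformation.
#' @return list with `left`, `right` ([SurfaceMesh-class]) and `mirrorMap`
#'   (integer bijection).
#' @export
makeHemispherePair <- function(nSubdiv = 4L, perturb = 0, seed = 1L,
                               radius = 80, deformRel = 0.03) {
  stopifnot(nSubdiv >= 1L, perturb >= 0)
  withSeed(seed, {
    base <- icosphereMesh(nSubdiv, radius = 1, hemisphere = "left")
    u <- vertices(base)
    f <- smoothRadialField(u)
    r <- radius * (1 + deformRel * f)
    vl <- u * r
    left <- SurfaceMesh(vl, faces(base), hemisphere = "left")
    vr <- vl
    vr[, 1L] <- -vr[, 1L]
    if (perturb > 0) {
      f2 <- smoothRadialField(u)
      vr <- vr * (1 + perturb * f2 / sqrt(rowSums(vr^2)))
    }
    fr <- faces(base)[, c(1L, 3L, 2L)]      # restore outward orientation
    right <- SurfaceMesh(vr, fr, hemisphere = "right")
    list(left = left, right = right,
         mirrorMap = seq_len(nrow(vl)))
  })
}

## Farthest-point-sampled geodesic Voronoi labels; returns list(labels, seeds).
voronoiLabels <- function(mesh, k, firstSeed) {
  n <- nrow(vertices(mesh))
  seeds <- integer(k)
  seeds[1L] <- firstSeed
  D <- matrix(NA_real_, k, n)
  D[1L, ] <- geodesicDistance(mesh, seeds[1L])
  if (k > 1L) for (i in 2L:k) {
    dMin <- apply(D[seq_len(i - 1L), , drop = FALSE], 2L, min)
    seeds[i] <- which.max(dMin)
    D[i, ] <- geodesicDistance(mesh, seeds[i])
  }
  labels <- apply(D, 2L, which.min)        # ties: lowest region id
  list(labels = as.integer(labels), seeds = seeds)
}

#' Geodesic Voronoi parcellation with centroid landmarks
#'
#' Region seeds are chosen by farthest-point sampling (first seed random,
#' seeded RNG) and every vertex takes the label of its geodesically
#' nearest seed, which yields connected regions. Stands in for an
#' anatomical gyral/sulcal parcellation at configurable granularity.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param nRegions region count (<= n_vertices / 4).
#' @param seed RNG seed.
#' @param excludeVertices optional vertex indices given the reserved label
#'   0 (a synthetic medial wall).
#' @return a [Parcellation-class].
#' @export
makeParcellation <- function(mesh, nRegions, seed = 1L,
                             excludeVertices = integer()) {
  n <- nrow(vertices(mesh))
  stopifnot(nRegions >= 1L, nRegions <= n / 4)
  withSeed(seed, {
    vl <- voronoiLabels(mesh, nRegions, sample.int(n, 1L))
    labels <- vl$labels
    labels[excludeVertices] <- 0L
    ## an excluded label must not empty a region
    for (r in seq_len(nRegions)) if (!any(labels == r))
      labels[vl$seeds[r]] <- r
    Parcellation(labels, mesh = mesh)
  })
}

#' Mirror a parcellation onto the partner hemisphere
#'
#' Labels are carried across the true homotopic map so that region j of
#' one hemisphere corresponds to region j of the other; centroid landmark
#' vertices are recomputed on the partner's own geometry.
#'
#' @param parcellation a [Parcellation-class] on the source hemisphere.
#' @param mirrorMapping integer bijection, source vertex -> partner vertex.
#' @param mesh the partner [SurfaceMesh-class].
#' @return a [Parcellation-class] on the partner hemisphere.
#' @export
mirrorParcellation <- function(parcellation, mirrorMapping, mesh) {
  labels <- integer(length(mirrorMapping))
  labels[mirrorMapping] <- parcellation@labels
  Parcellation(labels, regionNames = parcellation@regionNames, mesh = mesh)
}

## Assign each patch vertex a displaced loading site: the candidate vertex
## whose geodesic distance from the start is closest to `dist`. Targets are
## unique (a shared target would pool several pair latents and inflate its
## variance, suppressing all their correlations) and are drawn from the
## given candidate set, excluding `forbidden` vertices.
displacementTargets <- function(mesh, starts, dist, candidates, forbidden) {
  D <- geodesicRows(mesh, starts)
  out <- integer(length(starts))
  taken <- forbidden
  for (i in seq_along(starts)) {
    cand <- setdiff(candidates, taken)
    if (length(cand) == 0L) stop("no displacement targets available")
    out[i] <- cand[which.min(abs(D[i, cand] - dist))]
    taken <- c(taken, out[i])
  }
  out
}

#' Simulate multi-subject homotopically coupled time series
#'
#' Latent-network signal model: each network k has a latent Gaussian time
#' course shared by its members, and each homotopic vertex pair
#' additionally shares a pair-specific latent course, so that the
#' correlation between a vertex and its mirror partner equals
#' `rho` in expectation while within-network off-pair correlations stay
#' lower (`(1 - pairFraction) * rho`). Total signal amplitude follows
#' `s = noiseSd * sqrt(rho / (1 - rho))`. An optional Gaussian spatial
#' falloff of the loading (geodesic distance from the network's first
#' vertex) can down-weight network borders; by default loading is uniform
#' so the nominal coupling is attained at every member.
#'
#' Asymmetries:
#' \describe{
#'   \item{shift}{`list(type = "shift", center, radius, displacement,
#'     gammaSym = 0.4, gammaDisp = 0.9)`: for patch vertices (geodesic
#'     ball around `center` on the left mesh), the right hemisphere's
#'     pair-latent loading is split — a reduced symmetric share
#'     (`gammaSym`) stays at the mirror vertex and the dominant share
#'     (`gammaDisp`) is displaced `displacement` mm along the surface —
#'     yielding a left-seed functional correspondence displaced by
#'     `displacement` while right-seed correspondences of the patch stay
#'     symmetric (a one-sided asymmetry). The patch radius should stay
#'     below `displacement / 2` so displaced loadings land outside the
#'     mirrored patch.}
#'   \item{swap}{`list(type = "swap", a, b)`: the right-hemisphere pair
#'     latents of left vertices `a` and `b` are exchanged, producing the
#'     symmetric criss-cross pattern (large AFCD, near-zero FAD).}
#' }
#'
#' @param scene list with `left`, `right`, `mirrorMap` (e.g. from
#'   [makeHemispherePair()]), or a [SyntheticScene-class].
#' @param nSubjects,nTimepoints study size (timepoints >= 20).
#' @param networks list of `list(vertices = <left indices>, rho = <0..1>)`;
#'   must not overlap.
#' @param asymmetry optional asymmetry spec (see Details) or `NULL`.
#' @param noiseSd independent noise SD.
#' @param seed RNG seed.
#' @param pairFraction share of signal variance given to the pair latent.
#' @param falloffScale Gaussian loading falloff scale in mm (`Inf` =
#'   uniform).
#' @param tr sampling interval, seconds.
#' @return list with `subjects` (per-subject `left`/`right`
#'   [TimeSeriesSet-class] pairs) and `truth` (parameters plus, for a
#'   shift, `patch`, `shiftMap`, and achieved displacements).
#' @export
simulateTimeSeries <- function(scene, nSubjects, nTimepoints, networks,
                               asymmetry = NULL, noiseSd = 1, seed = 1L,
                               pairFraction = 0.5, falloffScale = Inf,
                               tr = 3.5) {
  stopifnot(nTimepoints >= 20L, nSubjects >= 1L)
  if (is(scene, "SyntheticScene"))
    scene <- list(left = scene@leftMesh, right = scene@rightMesh,
                  mirrorMap = scene@mirrorMap)
  mm <- scene$mirrorMap
  n <- length(mm)
  allv <- unlist(lapply(networks, `[[`, "vertices"))
  if (anyDuplicated(allv)) stop("overlapping networks are not supported")

  netOf <- rep(NA_integer_, n)
  loading <- numeric(n)
  for (k in seq_along(networks)) {
    vs <- networks[[k]]$vertices
    netOf[vs] <- k
    if (is.finite(falloffScale)) {
      d <- geodesicDistance(scene$left, vs[1L])[vs]
      loading[vs] <- exp(-d^2 / (2 * falloffScale^2))
    } else loading[vs] <- 1
  }

  truth <- list(networks = networks, noiseSd = noiseSd,
                pairFraction = pairFraction, falloffScale = falloffScale,
                seed = seed, asymmetry = asymmetry)
  patch <- integer(); shiftMap <- integer()
  if (!is.null(asymmetry) && identical(asymmetry$type, "shift")) {
    dC <- geodesicDistance(scene$left, asymmetry$center)
    patch <- which(dC <= asymmetry$radius)
    ## displaced loadings must share the seed's network latent (or variance
    ## normalization favours the signal-depleted mirror vertex), so targets
    ## are drawn from the same network, away from the mirrored patch
    k0 <- netOf[asymmetry$center]
    patch <- patch[!is.na(netOf[patch]) & netOf[patch] == k0]
    shiftMap <- displacementTargets(
      scene$right, mm[patch], asymmetry$displacement,
      candidates = mm[networks[[k0]]$vertices],
      forbidden = mm[patch])
    truth$patch <- patch
    truth$shiftMap <- shiftMap
    truth$achievedDisplacement <-
      geodesicPairs(scene$right, mm[patch], shiftMap)
    truth$gammaSym <- gs <- asymmetry$gammaSym %||% 0.4
    truth$gammaDisp <- gd <- asymmetry$gammaDisp %||% 0.9
  }

  subjects <- withSeed(seed, lapply(seq_len(nSubjects), function(s) {
    L <- matrix(0, n, nTimepoints)
    Rg <- matrix(0, n, nTimepoints)
    for (k in seq_along(networks)) {
      vs <- networks[[k]]$vertices
      rho <- networks[[k]]$rho
      if (rho < 0 || rho > 1 || (rho == 1 && noiseSd > 0))
        stop("homotopic coupling rho must be in [0, 1) for noisy data")
      ## noiseSd = 0: pure shared signal, mirror pairs identical whatever rho
      s2 <- if (noiseSd == 0) 1 else noiseSd^2 * rho / (1 - rho)
      a <- sqrt(pairFraction * s2)
      b <- sqrt((1 - pairFraction) * s2)
      z <- stats::rnorm(nTimepoints)
      U <- matrix(stats::rnorm(length(vs) * nTimepoints), length(vs))
      g <- loading[vs]
      net <- outer(g * b, z)
      pairL <- g * a * U
      L[vs, ] <- net + pairL
      Rg[mm[vs], ] <- net                   # network part, always symmetric
      pairR <- pairL
      if (length(patch)) {
        inP <- vs %in% patch
        pairR[inP, ] <- truth$gammaSym * pairR[inP, ]
        ## compensate the removed pair-signal variance at the mirror vertex
        ## so its correlation with the seed is not inflated by a shrunken
        ## denominator
        if (any(inP)) {
          compSd <- g[inP] * a * sqrt(1 - truth$gammaSym^2)
          pairR[inP, ] <- pairR[inP, ] +
            matrix(stats::rnorm(sum(inP) * nTimepoints), sum(inP)) * compSd
        }
      }
      Rg[mm[vs], ] <- Rg[mm[vs], ] + pairR
      if (length(patch)) {
        sel <- which(vs %in% patch)
        for (i in sel) {
          tgt <- shiftMap[match(vs[i], patch)]
          Rg[tgt, ] <- Rg[tgt, ] + truth$gammaDisp * g[i] * a * U[i, ]
        }
      }
    }
    if (!is.null(asymmetry) && identical(asymmetry$type, "swap")) {
      va <- asymmetry$a; vb <- asymmetry$b
      ka <- netOf[va]; kb <- netOf[vb]
      if (is.na(ka) || is.na(kb) || ka != kb)
        stop("swap vertices must belong to the same network")
      ## both rows carry the same network course (uniform loading within a
      ## network), so swapping the whole signal rows exchanges exactly the
      ## pair-specific components.
      Rg[c(mm[va], mm[vb]), ] <- Rg[c(mm[vb], mm[va]), ]
    }
    noiseL <- matrix(stats::rnorm(n * nTimepoints, sd = noiseSd), n)
    noiseR <- matrix(stats::rnorm(n * nTimepoints, sd = noiseSd), n)
    list(left = TimeSeriesSet(L + noiseL, tr = tr,
                              subject = sprintf("s%02d", s), hemisphere = "left"),
         right = TimeSeriesSet(Rg + noiseR, tr = tr,
                               subject = sprintf("s%02d", s), hemisphere = "right"))
  }))
  list(subjects = subjects, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a complete synthetic study scene
#'
#' Convenience constructor combining [makeHemispherePair()],
#' [makeParcellation()] (mirrored to the right hemisphere), a geodesic
#' Voronoi partition of all vertices into `nNetworks` functional networks
#' with uniform homotopic coupling `rho`, and [simulateTimeSeries()]. The
#' defaults reproduce the package's reference study conditions: 2,562
#' vertices per hemisphere, 74 anatomical regions, 10 subjects, 140
#' timepoints, homotopic coupling 0.6.
#'
#' @param nSubdiv icosphere subdivision (default 4: 2,562 vertices).
#' @param nRegions anatomical parcellation size (default 74).
#' @param nSubjects,nTimepoints study size (defaults 10 and 140).
#' @param rho homotopic coupling per network (default 0.6).
#' @param nNetworks number of functional networks tiling the cortex.
#' @param perturb right-hemisphere mesh perturbation, mm.
#' @param asymmetry asymmetry spec passed to [simulateTimeSeries()].
#' @param noiseSd noise SD.
#' @param seed RNG seed (all derived seeds are fixed offsets of it).
#' @return a [SyntheticScene-class].
#' @export
makeScene <- function(nSubdiv = 4L, nRegions = 74L, nSubjects = 10L,
                      nTimepoints = 140L, rho = 0.6, nNetworks = 6L,
                      perturb = 0, asymmetry = NULL, noiseSd = 1,
                      seed = 1L) {
  hp <- makeHemispherePair(nSubdiv, perturb = perturb, seed = seed)
  parcL <- makeParcellation(hp$left, nRegions, seed = seed + 1L)
  parcR <- mirrorParcellation(parcL, hp$mirrorMap, hp$right)
  netLabels <- withSeed(seed + 2L, {
    n <- nrow(vertices(hp$left))
    voronoiLabels(hp$left, nNetworks, sample.int(n, 1L))$labels
  })
  networks <- lapply(seq_len(nNetworks), function(k)
    list(vertices = which(netLabels == k), rho = rho))
  sim <- simulateTimeSeries(hp, nSubjects, nTimepoints, networks,
                            asymmetry = asymmetry, noiseSd = noiseSd,
                            seed = seed + 3L)
  truth <- sim$truth
  truth$networkLabels <- netLabels
  truth$sceneSeed <- seed
  new("SyntheticScene", leftMesh = hp$left, rightMesh = hp$right,
      mirrorMap = as.integer(hp$mirrorMap),
      leftParcellation = parcL, rightParcellation = parcR,
      subjects = sim$subjects, truth = truth)
}
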