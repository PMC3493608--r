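# Shared fixtures and independent oracles, all built in code.

# All-pairs shortest paths on the weighted edge graph, vectorized
# Floyd-Warshall. Independent of the package's Dijkstra path.
floydWarshall <- function(mesh) {
  v <- vertices(mesh)
  f <- faces(mesh)
  n <- nrow(v)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  len <- sqrt(rowSums((v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE])^2))
  D[e] <- pmin(D[e], len)
  D[e[, 2:1]] <- pmin(D[e[, 2:1]], len)
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

# Minimal closed valid mesh.
tetraMesh <- function() {
  SurfaceMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
              rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
}

# n collinear vertices spaced 1 mm, triangulated with a parallel strip so
# the shortest path between chain vertices runs along the chain.
chainMesh <- function(n, spacing = 1, hemisphere = "left") {
  v <- cbind((seq_len(n) - 1) * spacing, 0, 0)
  v <- rbind(v, cbind((seq_len(n - 1) - 0.5) * spacing, spacing, 0))
  f <- do.call(rbind, lapply(seq_len(n - 1), function(i)
    rbind(c(i, i + 1, n + i),
          if (i < n - 1) c(i + 1, n + i + 1, n + i))))
  SurfaceMesh(v, f, hemisphere = hemisphere)
}

# Random small test mesh (perturbed icosphere or jittered planar grid),
# <= 200 vertices, always connected and free of zero-length edges.
randomSmallMesh <- function(seed) {
  set.seed(seed)
  if (runif(1) < 0.5) {
    m <- icosphereMesh(sample(1:2, 1), radius = runif(1, 5, 50))
    v <- vertices(m) * (1 + 0.05 * matrix(runif(length(vertices(m)), -1, 1),
                                          ncol = 3))
    SurfaceMesh(v, faces(m))
  } else {
    nx <- sample(4:13, 1); ny <- sample(4:13, 1)
    m <- planarGridMesh(nx, ny, spacing = runif(1, 0.5, 3))
    v <- vertices(m)
    v <- v + 0.2 * matrix(rnorm(length(v)), ncol = 3)
    SurfaceMesh(v, faces(m))
  }
}

# Hand-built correspondence map for metric tests.
idMap <- function(n, direction = "LR", kind = "anatomical")
  CorrespondenceMap(seq_len(n), rep(1, n), direction, kind, nTarget = n)
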