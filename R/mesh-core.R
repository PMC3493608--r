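#' Construct a SurfaceMesh
#'
#' @param vertices numeric n x 3 matrix of coordinates in mm (RAS+).
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @param hemisphere `"left"` or `"right"`.
#' @param check if `TRUE` (default) reject meshes violating the structural
#'   invariants (face indices in range, no zero-length edges, single
#'   connected component). Use `check = FALSE` to build a deliberately
#'   broken mesh for [validateMesh()].
#' @return a [SurfaceMesh-class] object.
#' @examples
#' m <- icosphereMesh(1)
#' m
#' @export
SurfaceMesh <- function(vertices, faces, hemisphere = "left", check = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  mesh <- new("SurfaceMesh", vertices = vertices, faces = faces,
              hemisphere = hemisphere)
  if (check) {
    rep <- validateMesh(mesh)
    if (nrow(rep) > 0)
      stop("invalid mesh: ", paste(rep$violation, collapse = "; "))
  }
  mesh
}

## Undirected edge list (each edge once) with Euclidean lengths.
meshEdges <- function(mesh) {
  f <- mesh@faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e <- unique(e)
  v <- mesh@vertices
  len <- sqrt(rowSums((v[e[, 1L], , drop = FALSE] - v[e[, 2L], , drop = FALSE])^2))
  list(edges = e, lengths = len)
}

meshGraph <- function(mesh) {
  el <- meshEdges(mesh)
  g <- igraph::graph_from_edgelist(el$edges, directed = FALSE)
  if (igraph::vcount(g) < nrow(mesh@vertices))
    g <- igraph::add_vertices(g, nrow(mesh@vertices) - igraph::vcount(g))
  igraph::E(g)$weight <- el$lengths
  g
}

#' Mean edge length of a mesh (mm)
#'
#' The package's natural resolution unit: tolerance bands for correspondence
#' recovery are quoted in multiples of this value.
#'
#' @param mesh a [SurfaceMesh-class].
#' @return scalar, mm.
#' @export
meanEdgeLength <- function(mesh) mean(meshEdges(mesh)$lengths)

#' Validate a surface mesh, reporting (never raising) violations
#'
#' Checks the SurfaceMesh invariants: every face index refers to an existing
#' vertex, the edge graph forms a single connected component, and no edge
#' has zero length. An empty report means the mesh is valid.
#'
#' @param mesh a [SurfaceMesh-class] (possibly built with `check = FALSE`).
#' @return data.frame with column `violation`; zero rows iff valid.
#' @examples
#' validateMesh(icosphereMesh(1))           # zero rows
#' @export
validateMesh <- function(mesh) {
  viol <- character()
  n <- nrow(mesh@vertices)
  f <- mesh@faces
  if (any(f < 1L) || any(f > n))
    viol <- c(viol, "face index out of range")
  else {
    el <- meshEdges(mesh)
    if (any(el$lengths == 0))
      viol <- c(viol, sprintf("zero-length edges: %d", sum(el$lengths == 0)))
    g <- meshGraph(mesh)
    nc <- igraph::count_components(g)
    if (nc > 1L)
      viol <- c(viol, sprintf("disconnected components: %d", nc))
  }
  data.frame(violation = viol, stringsAsFactors = FALSE)
}

#' Geodesic distance from a source set to every vertex
#'
#' Shortest-path distance along the mesh edge graph (Dijkstra, Euclidean
#' edge weights) from each vertex to its nearest source. On well-tessellated
#' meshes this overestimates the exact polyhedral geodesic by a small,
#' bounded factor; it is deterministic and exactly checkable against an
#' all-pairs shortest-path oracle.
#'
#' @param mesh a [SurfaceMesh-class]; must be connected.
#' @param sources integer vector of source vertex indices (1-based).
#' @return numeric vector, distance in mm per vertex; 0 at the sources.
#' @examples
#' m <- icosphereMesh(1)
#' d <- geodesicDistance(m, 1L)
#' d[1]  # 0
#' @export
geodesicDistance <- function(mesh, sources) {
  if (length(sources) == 0L) stop("no source vertices")
  sources <- as.integer(sources)
  n <- nrow(mesh@vertices)
  if (any(sources < 1L | sources > n)) stop("source vertex index out of range")
  g <- meshGraph(mesh)
  d <- igraph::distances(g, v = sources, algorithm = "dijkstra")
  out <- if (length(sources) > 1L) apply(d, 2L, min) else as.numeric(d)
  if (any(!is.finite(out)))
    stop("mesh is disconnected: some vertices are unreachable from the sources")
  unname(out)
}

## Distance rows from several sources at once: |from| x n matrix.
geodesicRows <- function(mesh, from) {
  g <- meshGraph(mesh)
  d <- igraph::distances(g, v = as.integer(from), algorithm = "dijkstra")
  if (any(!is.finite(d)))
    stop("mesh is disconnected: infinite geodesic distances")
  unname(d)
}

#' Geodesic distances for specific vertex pairs
#'
#' @param mesh a [SurfaceMesh-class].
#' @param from,to equal-length integer vectors; `NA` in either propagates to
#'   an `NA` distance.
#' @return numeric vector of per-pair distances (mm).
#' @export
geodesicPairs <- function(mesh, from, to) {
  stopifnot(length(from) == length(to))
  out <- rep(NA_real_, length(from))
  ok <- !is.na(from) & !is.na(to)
  if (!any(ok)) return(out)
  src <- sort(unique(from[ok]))
  D <- geodesicRows(mesh, src)
  out[ok] <- D[cbind(match(from[ok], src), to[ok])]
  out
}

#' Construct a Parcellation
#'
#' @param labels integer per-vertex region ids; 0 marks excluded vertices.
#' @param regionNames character names for regions `1..K` (defaults to
#'   `"region_1"...`).
#' @param mesh optional [SurfaceMesh-class]; when given, centroid landmark
#'   vertices are computed with [regionCentroid()].
#' @param centroidVertex optional precomputed centroid vertex per region.
#' @return a [Parcellation-class].
#' @export
Parcellation <- function(labels, regionNames = NULL, mesh = NULL,
                         centroidVertex = NULL) {
  labels <- as.integer(labels)
  k <- max(0L, labels)
  if (is.null(regionNames)) regionNames <- sprintf("region_%d", seq_len(k))
  if (is.null(centroidVertex)) {
    if (is.null(mesh))
      stop("supply either a mesh (to compute centroids) or centroidVertex")
    p0 <- new("Parcellation", labels = labels, regionNames = regionNames,
              centroidVertex = vapply(seq_len(k), function(r) {
                which(labels == r)[1L]
              }, integer(1)))
    centroidVertex <- vapply(seq_len(k), function(r)
      regionCentroid(mesh, p0, r), integer(1))
  }
  new("Parcellation", labels = labels, regionNames = regionNames,
      centroidVertex = as.integer(centroidVertex))
}

#' Centroid landmark vertex of a parcellation region
#'
#' The region vertex nearest (Euclidean) to the arithmetic mean of the
#' region's vertex coordinates; ties broken by lowest vertex index.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param parcellation a [Parcellation-class].
#' @param region region id (1-based, non-reserved).
#' @return integer vertex index.
#' @export
regionCentroid <- function(mesh, parcellation, region) {
  region <- as.integer(region)
  if (length(region) != 1L || is.na(region) || region < 1L ||
      region > length(parcellation@regionNames))
    stop("unknown or reserved region id: ", region)
  idx <- which(parcellation@labels == region)
  if (length(idx) == 0L) stop("region has no vertices: ", region)
  xyz <- mesh@vertices[idx, , drop = FALSE]
  ctr <- colMeans(xyz)
  d2 <- rowSums(sweep(xyz, 2L, ctr)^2)
  idx[which.min(d2)]  # which.min takes the first (lowest index) on ties
}
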