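#' @import methods
NULL

#' SurfaceMesh: one hemisphere's triangulated cortical geometry
#'
#' Holds vertex coordinates in millimetres (RAS+ convention) and triangle
#' faces as 1-based vertex index triples, together with a hemisphere tag.
#' All geodesic distances in the package are shortest paths on this mesh's
#' edge graph with Euclidean edge weights.
#'
#' @slot vertices numeric matrix, n x 3, coordinates in mm (RAS+).
#' @slot faces integer matrix, m x 3, 1-based vertex indices.
#' @slot hemisphere `"left"` or `"right"`.
#'
#' @seealso [SurfaceMesh()], [validateMesh()], [geodesicDistance()]
#' @exportClass SurfaceMesh
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix", hemisphere = "character"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@vertices) || ncol(object@vertices) != 3L)
      msg <- c(msg, "vertices must be a numeric n x 3 matrix")
    if (!is.numeric(object@faces) || ncol(object@faces) != 3L)
      msg <- c(msg, "faces must be an integer m x 3 matrix")
    if (length(object@hemisphere) != 1L ||
        !object@hemisphere %in% c("left", "right"))
      msg <- c(msg, "hemisphere must be \"left\" or \"right\"")
    if (length(msg)) msg else TRUE
  })

#' Parcellation: per-vertex region labels with centroid landmarks
#'
#' Region labels are positive integers; label 0 is reserved for excluded
#' vertices (the medial wall / FreeSurfer "unknown"). Each non-reserved
#' region has a centroid landmark vertex: the region vertex closest
#' (Euclidean) to the arithmetic mean of the region's vertex coordinates.
#'
#' @slot labels integer vector, one per vertex; 0 marks excluded vertices.
#' @slot regionNames character vector of region names, one per region id
#'   `1..K`, in region-id order.
#' @slot centroidVertex integer vector of centroid vertex indices, one per
#'   region id `1..K`.
#'
#' @seealso [Parcellation()], [regionCentroid()], [buildLabelVectors()]
#' @exportClass Parcellation
setClass("Parcellation",
  representation(labels = "integer", regionNames = "character",
                 centroidVertex = "integer"),
  validity = function(object) {
    msg <- character()
    k <- length(object@regionNames)
    if (length(object@centroidVertex) != k)
      msg <- c(msg, "centroidVertex and regionNames lengths differ")
    if (any(object@labels < 0L, na.rm = TRUE))
      msg <- c(msg, "labels must be >= 0 (0 = excluded)")
    if (k > 0 && max(object@labels) > k)
      msg <- c(msg, "label id exceeds number of regions")
    for (r in seq_len(k)) {
      if (!any(object@labels == r))
        msg <- c(msg, sprintf("region %d has no vertices", r))
      else if (object@centroidVertex[r] < 1L ||
               object@centroidVertex[r] > length(object@labels) ||
               object@labels[object@centroidVertex[r]] != r)
        msg <- c(msg, sprintf("centroid of region %d does not carry label %d", r, r))
    }
    if (length(msg)) msg else TRUE
  })

#' LabelVectorSet: per-vertex geodesic distances to region centroids
#'
#' Row v holds vertex v's label vector: the geodesic distance (mm) from v
#' to the centroid landmark of each parcellation region in the same
#' hemisphere. These vectors re-express vertex position relative to
#' gyral/sulcal landmarks instead of Cartesian coordinates, and are the
#' objects compared (by Pearson correlation) across hemispheres.
#'
#' @slot distances numeric matrix, n_vertices x n_regions, mm.
#' @slot regionNames character, column names / pairing key across hemispheres.
#' @slot hemisphere `"left"` or `"right"`.
#' @slot excluded logical per vertex; excluded (medial-wall) vertices never
#'   act as seeds or match targets.
#'
#' @seealso [buildLabelVectors()], [matchAnatomical()]
#' @exportClass LabelVectorSet
setClass("LabelVectorSet",
  representation(distances = "matrix", regionNames = "character",
                 hemisphere = "character", excluded = "logical"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@distances) != length(object@regionNames))
      msg <- c(msg, "one column per region required")
    if (nrow(object@distances) != length(object@excluded))
      msg <- c(msg, "excluded flag must have one entry per vertex")
    if (any(!is.finite(object@distances)))
      msg <- c(msg, "all label-vector entries must be finite")
    else if (any(object@distances < 0))
      msg <- c(msg, "label-vector entries must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' CorrespondenceMap: per-seed matched contralateral vertex
#'
#' For every seed vertex of one hemisphere, the index of the matched vertex
#' on the contralateral hemisphere and the match score: the maximal Pearson
#' correlation of label vectors (anatomical correspondence, AC) or of
#' resting time series (functional correspondence, FC). Excluded seeds
#' carry `NA` target and score (serialized as -1 / nan).
#'
#' @slot targetIndex integer per seed; `NA` for excluded seeds.
#' @slot score numeric per seed, in `[-1, 1]`; `NA` for excluded seeds.
#' @slot direction `"LR"` (left seeds, right targets) or `"RL"`.
#' @slot kind `"anatomical"` or `"functional"`.
#' @slot nTarget integer, vertex count of the target hemisphere.
#'
#' @seealso [matchAnatomical()], [functionalCorrespondence()], [afcd()], [fad()]
#' @exportClass CorrespondenceMap
setClass("CorrespondenceMap",
  representation(targetIndex = "integer", score = "numeric",
                 direction = "character", kind = "character",
                 nTarget = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@targetIndex) != length(object@score))
      msg <- c(msg, "targetIndex and score lengths differ")
    if (!object@direction %in% c("LR", "RL"))
      msg <- c(msg, "direction must be \"LR\" or \"RL\"")
    if (!object@kind %in% c("anatomical", "functional"))
      msg <- c(msg, "kind must be \"anatomical\" or \"functional\"")
    ok <- !is.na(object@targetIndex)
    if (any(object@targetIndex[ok] < 1L | object@targetIndex[ok] > object@nTarget))
      msg <- c(msg, "targetIndex out of range")
    if (any(abs(object@score[!is.na(object@score)]) > 1 + 1e-8))
      msg <- c(msg, "score outside [-1, 1]")
    if (length(msg)) msg else TRUE
  })

#' TimeSeriesSet: per-vertex resting time series for one hemisphere
#'
#' @slot series numeric matrix, n_vertices x n_timepoints.
#' @slot tr sampling interval in seconds.
#' @slot subject subject identifier.
#' @slot hemisphere `"left"` or `"right"`.
#'
#' @seealso [heatSmooth()], [crossHemiCorrelation()]
#' @exportClass TimeSeriesSet
setClass("TimeSeriesSet",
  representation(series = "matrix", tr = "numeric", subject = "character",
                 hemisphere = "character"),
  validity = function(object) {
    msg <- character()
    if (any(!is.finite(object@series)))
      msg <- c(msg, "time series must contain only finite values")
    if (ncol(object@series) < 3L)
      msg <- c(msg, "at least 3 timepoints required")
    if (length(object@tr) != 1L || object@tr <= 0)
      msg <- c(msg, "tr must be a positive scalar (seconds)")
    if (!object@hemisphere %in% c("left", "right"))
      msg <- c(msg, "hemisphere must be \"left\" or \"right\"")
    if (length(msg)) msg else TRUE
  })

#' CrossCorrSummary: cross-hemispheric correlation argmax summary
#'
#' Per-seed maximum Pearson correlation against all contralateral vertices
#' and the index attaining it, optionally with the dense seed x target
#' correlation block (kept only for small meshes or on request).
#'
#' @slot maxCorr numeric per seed.
#' @slot argmaxIndex integer per seed (`NA` for excluded seeds).
#' @slot direction `"LR"` or `"RL"`.
#' @slot dense dense correlation block (matrix) or `NULL`.
#' @slot nTarget integer, target vertex count.
#'
#' @seealso [crossHemiCorrelation()], [functionalCorrespondence()]
#' @exportClass CrossCorrSummary
setClass("CrossCorrSummary",
  representation(maxCorr = "numeric", argmaxIndex = "integer",
                 direction = "character", dense = "ANY", nTarget = "integer"))

#' SymmetryReport: per-vertex AFCD/FAD with cluster table and summaries
#'
#' @slot afcdLR,afcdRL per-seed anatomy-to-functional-correspondence
#'   distance in mm (left and right seeds respectively); `NA` sentinel for
#'   excluded chains.
#' @slot fad per-left-seed functional asymmetry distance in mm.
#' @slot clusterTable data.frame of supra-threshold FAD clusters
#'   (cluster, size, meanFad, vertices).
#' @slot summary list of cumulative histograms and scalar summaries.
#'
#' @seealso [runPipeline()], [highFadClusters()]
#' @exportClass SymmetryReport
setClass("SymmetryReport",
  representation(afcdLR = "numeric", afcdRL = "numeric", fad = "numeric",
                 clusterTable = "data.frame", summary = "list"))

#' SyntheticScene: mirrored hemispheres with known ground truth
#'
#' A fully synthetic study scene: a left hemisphere mesh (deformed
#' icosphere), its mirrored right partner, the true homotopic vertex map,
#' mirrored parcellations, per-subject time-series pairs, and the injected
#' ground truth (networks, homotopic coupling, asymmetries).
#'
#' @slot leftMesh,rightMesh [SurfaceMesh-class] objects.
#' @slot mirrorMap integer per left vertex: index of the true homotopic
#'   right vertex (a bijection).
#' @slot leftParcellation,rightParcellation [Parcellation-class] objects.
#' @slot subjects list of per-subject lists with elements `left` and
#'   `right` ([TimeSeriesSet-class]).
#' @slot truth list recording generator parameters and injected asymmetry.
#'
#' @seealso [makeScene()], [makeHemispherePair()], [simulateTimeSeries()]
#' @exportClass SyntheticScene
setClass("SyntheticScene",
  representation(leftMesh = "SurfaceMesh", rightMesh = "SurfaceMesh",
                 mirrorMap = "integer",
                 leftParcellation = "Parcellation",
                 rightParcellation = "Parcellation",
                 subjects = "list", truth = "list"),
  validity = function(object) {
    msg <- character()
    n <- nrow(object@leftMesh@vertices)
    if (length(object@mirrorMap) != n ||
        length(unique(object@mirrorMap)) != n)
      msg <- c(msg, "mirrorMap must be a bijection over vertices")
    if (nrow(object@rightMesh@vertices) != n)
      msg <- c(msg, "hemisphere vertex counts differ")
    if (length(msg)) msg else TRUE
  })
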