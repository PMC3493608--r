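#' Accessors for hemicorr classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))
#' @rdname accessors
#' @export
setGeneric("hemisphere", function(x) standardGeneric("hemisphere"))
#' @rdname accessors
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))
#' @rdname accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))
#' @rdname accessors
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))
#' @rdname accessors
#' @export
setGeneric("centroidVertices", function(x) standardGeneric("centroidVertices"))
#' @rdname accessors
#' @export
setGeneric("targetIndex", function(x) standardGeneric("targetIndex"))
#' @rdname accessors
#' @export
setGeneric("matchScore", function(x) standardGeneric("matchScore"))
#' @rdname accessors
#' @export
setGeneric("direction", function(x) standardGeneric("direction"))
#' @rdname accessors
#' @export
setGeneric("labelVectors", function(x) standardGeneric("labelVectors"))
#' @rdname accessors
#' @export
setGeneric("excludedVertices", function(x) standardGeneric("excludedVertices"))
#' @rdname accessors
#' @export
setGeneric("tsMatrix", function(x) standardGeneric("tsMatrix"))
#' @rdname accessors
#' @export
setGeneric("mirrorMap", function(x) standardGeneric("mirrorMap"))

setMethod("vertices", "SurfaceMesh", function(x) x@vertices)
setMethod("faces", "SurfaceMesh", function(x) x@faces)
setMethod("hemisphere", "SurfaceMesh", function(x) x@hemisphere)
setMethod("nVertices", "SurfaceMesh", function(x) nrow(x@vertices))
setMethod("regionLabels", "Parcellation", function(x) x@labels)
setMethod("regionNames", "Parcellation", function(x) x@regionNames)
setMethod("centroidVertices", "Parcellation", function(x) x@centroidVertex)
setMethod("regionNames", "LabelVectorSet", function(x) x@regionNames)
setMethod("hemisphere", "LabelVectorSet", function(x) x@hemisphere)
setMethod("labelVectors", "LabelVectorSet", function(x) x@distances)
setMethod("excludedVertices", "LabelVectorSet", function(x) x@excluded)
setMethod("nVertices", "LabelVectorSet", function(x) nrow(x@distances))
setMethod("targetIndex", "CorrespondenceMap", function(x) x@targetIndex)
setMethod("matchScore", "CorrespondenceMap", function(x) x@score)
setMethod("direction", "CorrespondenceMap", function(x) x@direction)
setMethod("direction", "CrossCorrSummary", function(x) x@direction)
setMethod("tsMatrix", "TimeSeriesSet", function(x) x@series)
setMethod("hemisphere", "TimeSeriesSet", function(x) x@hemisphere)
setMethod("nVertices", "TimeSeriesSet", function(x) nrow(x@series))
setMethod("mirrorMap", "SyntheticScene", function(x) x@mirrorMap)

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh (%s): %d vertices, %d faces, mean edge %.2f mm\n",
              object@hemisphere, nrow(object@vertices), nrow(object@faces),
              meanEdgeLength(object)))
})

setMethod("show", "Parcellation", function(object) {
  cat(sprintf("Parcellation: %d regions over %d vertices (%d excluded)\n",
              length(object@regionNames), length(object@labels),
              sum(object@labels == 0L)))
})

setMethod("show", "LabelVectorSet", function(object) {
  cat(sprintf("LabelVectorSet (%s): %d vertices x %d region landmarks\n",
              object@hemisphere, nrow(object@distances), ncol(object@distances)))
})

setMethod("show", "CorrespondenceMap", function(object) {
  ok <- !is.na(object@score)
  cat(sprintf("CorrespondenceMap (%s, %s): %d seeds, median score %.3f\n",
              object@kind, object@direction, length(object@targetIndex),
              stats::median(object@score[ok])))
})

setMethod("show", "TimeSeriesSet", function(object) {
  cat(sprintf("TimeSeriesSet (%s, subject %s): %d vertices x %d timepoints, TR %.2f s\n",
              object@hemisphere, object@subject, nrow(object@series),
              ncol(object@series), object@tr))
})

setMethod("show", "CrossCorrSummary", function(object) {
  cat(sprintf("CrossCorrSummary (%s): %d seeds, dense block %s\n",
              object@direction, length(object@maxCorr),
              if (is.null(object@dense)) "not kept" else "kept"))
})

setMethod("show", "SymmetryReport", function(object) {
  ok <- !is.na(object@fad)
  cat(sprintf("SymmetryReport: median AFCD(LR) %.1f mm, median FAD %.1f mm, %d clusters\n",
              stats::median(object@afcdLR, na.rm = TRUE),
              stats::median(object@fad, na.rm = TRUE),
              nrow(object@clusterTable)))
})

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf("SyntheticScene: %d vertices/hemisphere, %d regions, %d subjects\n",
              nrow(object@leftMesh@vertices),
              length(object@leftParcellation@regionNames),
              length(object@subjects)))
})
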