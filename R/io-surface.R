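## Fixed float formatting for bit-exact tabular output across runs.
fmtNum <- function(x) {
  out <- sprintf("%.9g", x)
  out[is.na(x)] <- "nan"
  out
}

giftiTypeInfo <- list(
  NIFTI_TYPE_FLOAT32 = list(what = "double", size = 4L),
  NIFTI_TYPE_FLOAT64 = list(what = "double", size = 8L),
  NIFTI_TYPE_INT32 = list(what = "integer", size = 4L),
  NIFTI_TYPE_UINT8 = list(what = "integer", size = 1L))

decodeGiftiData <- function(node) {
  enc <- xml2::xml_attr(node, "Encoding")
  dtype <- xml2::xml_attr(node, "DataType")
  dims <- as.integer(c(xml2::xml_attr(node, "Dim0"), xml2::xml_attr(node, "Dim1")))
  dims[is.na(dims)] <- 1L
  order <- xml2::xml_attr(node, "ArrayIndexingOrder")
  txt <- xml2::xml_text(xml2::xml_find_first(node, ".//*[local-name()='Data']"))
  ti <- giftiTypeInfo[[dtype]]
  if (is.null(ti)) stop("unsupported GIFTI DataType: ", dtype)
  vals <- switch(enc,
    ASCII = scan(text = txt, quiet = TRUE),
    Base64Binary = readBin(jsonlite::base64_dec(gsub("\\s", "", txt)),
                           ti$what, n = prod(dims), size = ti$size,
                           endian = tolower(sub("Endian$", "",
                             xml2::xml_attr(node, "Endian") %||% "Little"))),
    GZipBase64Binary = readBin(
      memDecompress(jsonlite::base64_dec(gsub("\\s", "", txt)), type = "gzip"),
      ti$what, n = prod(dims), size = ti$size,
      endian = tolower(sub("Endian$", "",
        xml2::xml_attr(node, "Endian") %||% "Little"))),
    stop("unsupported GIFTI encoding: ", enc))
  if (length(vals) != prod(dims))
    stop("GIFTI data array length mismatch")
  if (dims[2L] > 1L) {
    if (identical(order, "ColumnMajorOrder")) matrix(vals, dims[1L], dims[2L])
    else matrix(vals, dims[1L], dims[2L], byrow = TRUE)
  } else as.numeric(vals)
}

giftiArrays <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed GIFTI file ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  nodes <- xml2::xml_find_all(doc, "//*[local-name()='DataArray']")
  if (length(nodes) == 0L) stop("no DataArray elements in ", path)
  lapply(nodes, function(nd)
    list(intent = xml2::xml_attr(nd, "Intent"), data = decodeGiftiData(nd)))
}

#' Read a surface mesh (GIFTI or FreeSurfer ASCII)
#'
#' Supports GIFTI `.surf.gii`/`.gii` (ASCII, Base64Binary or
#' GZipBase64Binary encodings; POINTSET + TRIANGLE arrays, 0-based face
#' indices on disk) and FreeSurfer ASCII `.asc` surfaces. Coordinates are
#' taken to be mm.
#'
#' @param path file path.
#' @param hemisphere hemisphere tag; default guessed from the file name
#'   (`lh`/`L.` prefix conventions), falling back to `"left"`.
#' @return a [SurfaceMesh-class] (validated).
#' @export
readSurface <- function(path, hemisphere = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(hemisphere))
    hemisphere <- if (grepl("(^|[._/])(rh|R)[._]", basename(path))) "right" else "left"
  if (grepl("\\.gii$", path)) {
    arrs <- giftiArrays(path)
    pts <- Filter(function(a) identical(a$intent, "NIFTI_INTENT_POINTSET"), arrs)
    tri <- Filter(function(a) identical(a$intent, "NIFTI_INTENT_TRIANGLE"), arrs)
    if (length(pts) == 0L || length(tri) == 0L)
      stop("GIFTI surface needs POINTSET and TRIANGLE arrays: ", path)
    SurfaceMesh(pts[[1L]]$data, tri[[1L]]$data + 1L, hemisphere = hemisphere)
  } else if (grepl("\\.asc$", path)) {
    ln <- readLines(path)
    ln <- ln[!grepl("^#", ln)]
    hdr <- scan(text = ln[1L], quiet = TRUE)
    nv <- hdr[1L]; nf <- hdr[2L]
    if (length(ln) < 1L + nv + nf) stop("truncated FreeSurfer ASCII file: ", path)
    vv <- matrix(scan(text = ln[2:(1 + nv)], quiet = TRUE), nv, byrow = TRUE)[, 1:3]
    ff <- matrix(scan(text = ln[(2 + nv):(1 + nv + nf)], quiet = TRUE),
                 nf, byrow = TRUE)[, 1:3]
    SurfaceMesh(vv, ff + 1L, hemisphere = hemisphere)
  } else stop("unknown surface file extension: ", path)
}

giftiXml <- function(arrays) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = as.character(length(arrays)))
  for (a in arrays) {
    x <- a$data
    dim0 <- if (is.matrix(x)) nrow(x) else length(x)
    dim1 <- if (is.matrix(x)) ncol(x) else 1L
    da <- xml2::xml_add_child(doc, "DataArray",
      Intent = a$intent, DataType = a$dtype,
      ArrayIndexingOrder = "RowMajorOrder",
      Dimensionality = if (is.matrix(x)) "2" else "1",
      Dim0 = as.character(dim0), Dim1 = as.character(dim1),
      Encoding = "ASCII", Endian = "LittleEndian",
      ExternalFileName = "", ExternalFileOffset = "")
    vals <- if (is.matrix(x)) as.vector(t(x)) else x
    txt <- if (a$dtype == "NIFTI_TYPE_INT32")
      paste(as.integer(vals), collapse = " ") else
      paste(fmtNum(vals), collapse = " ")
    xml2::xml_add_child(da, "Data", txt)
  }
  doc
}

#' Write a surface mesh as GIFTI
#'
#' ASCII-encoded GIFTI with POINTSET and TRIANGLE data arrays (0-based
#' face indices on disk). Coordinates round-trip at 9 significant digits.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param path output `.surf.gii` path.
#' @return `path`, invisibly.
#' @export
writeSurface <- function(mesh, path) {
  doc <- giftiXml(list(
    list(intent = "NIFTI_INTENT_POINTSET", dtype = "NIFTI_TYPE_FLOAT32",
         data = vertices(mesh)),
    list(intent = "NIFTI_INTENT_TRIANGLE", dtype = "NIFTI_TYPE_INT32",
         data = faces(mesh) - 1L)))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read per-vertex time series (TSV matrix or functional GIFTI)
#'
#' TSV: a plain numeric matrix, one row per vertex, one column per
#' timepoint, no header. Functional GIFTI: one DataArray per timepoint.
#'
#' @param path file path.
#' @param tr sampling interval (seconds) to record.
#' @param subject,hemisphere metadata for the [TimeSeriesSet-class].
#' @return a [TimeSeriesSet-class].
#' @export
readTimeSeries <- function(path, tr = 3.5, subject = "s1", hemisphere = "left") {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- if (grepl("\\.gii$", path)) {
    arrs <- giftiArrays(path)
    do.call(cbind, lapply(arrs, `[[`, "data"))
  } else {
    as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  }
  TimeSeriesSet(x, tr = tr, subject = subject, hemisphere = hemisphere)
}

#' Write per-vertex time series
#'
#' @param ts a [TimeSeriesSet-class].
#' @param path output path: `.tsv` (plain matrix) or `.gii` (one
#'   DataArray per timepoint, `NIFTI_INTENT_TIME_SERIES`).
#' @return `path`, invisibly.
#' @export
writeTimeSeries <- function(ts, path) {
  x <- tsMatrix(ts)
  if (grepl("\\.gii$", path)) {
    doc <- giftiXml(lapply(seq_len(ncol(x)), function(j)
      list(intent = "NIFTI_INTENT_TIME_SERIES", dtype = "NIFTI_TYPE_FLOAT32",
           data = x[, j])))
    xml2::write_xml(doc, path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(apply(x, 1L, function(r) paste(fmtNum(r), collapse = "\t")),
               con, sep = "\n")
  }
  invisible(path)
}
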