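#' Read a parcellation (FreeSurfer .annot or TSV fallback)
#'
#' TSV fallback format: tab-separated with header, columns `vertex`
#' (0-based), `label` (0 = excluded/unknown, regions numbered from 1) and
#' optionally `region_name`. FreeSurfer `.annot` is the binary format with
#' an embedded colour table (version-2 table supported); the colour-table
#' entry named `unknown` (or with a zero annotation value) becomes the
#' reserved label 0.
#'
#' @param path file path.
#' @param mesh the [SurfaceMesh-class] the labels belong to (vertex count
#'   check, centroid computation).
#' @return a [Parcellation-class] with centroids computed via
#'   [regionCentroid()].
#' @export
readParcellation <- function(path, mesh) {
  if (!file.exists(path)) stop("file not found: ", path)
  n <- nrow(vertices(mesh))
  if (grepl("\\.annot$", path)) {
    an <- readAnnotFile(path)
    if (length(an$labels) != n)
      stop(sprintf("label count mismatch: %d labels for %d vertices",
                   length(an$labels), n))
    Parcellation(an$labels, regionNames = an$regionNames, mesh = mesh)
  } else {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    if (!all(c("vertex", "label") %in% names(tab)))
      stop("parcellation TSV needs 'vertex' and 'label' columns: ", path)
    if (any(tab$vertex < 0L) || any(tab$vertex >= n))
      stop("parcellation references vertex beyond mesh size: ", path)
    if (nrow(tab) != n)
      stop(sprintf("label count mismatch: %d rows for %d vertices", nrow(tab), n))
    labels <- integer(n)
    labels[tab$vertex + 1L] <- tab$label
    regionNames <- NULL
    if ("region_name" %in% names(tab)) {
      m <- unique(tab[tab$label > 0L, c("label", "region_name")])
      regionNames <- m$region_name[order(m$label)]
    }
    Parcellation(labels, regionNames = regionNames, mesh = mesh)
  }
}

#' Write a parcellation as TSV
#'
#' @param parcellation a [Parcellation-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeParcellation <- function(parcellation, path) {
  lab <- regionLabels(parcellation)
  nm <- c("unknown", regionNames(parcellation))[lab + 1L]
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("vertex\tlabel\tregion_name",
               sprintf("%d\t%d\t%s", seq_along(lab) - 1L, lab, nm)),
             con, sep = "\n")
  invisible(path)
}

## FreeSurfer .annot: big-endian int32s; labels stored as packed RGB.
readAnnotFile <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  int1 <- function() readBin(con, "integer", 1L, size = 4L, endian = "big")
  nv <- int1()
  if (length(nv) == 0L || is.na(nv) || nv <= 0L)
    stop("malformed .annot file: ", path)
  dat <- readBin(con, "integer", 2L * nv, size = 4L, endian = "big")
  vtx <- dat[seq(1L, 2L * nv, by = 2L)]
  ann <- dat[seq(2L, 2L * nv, by = 2L)]
  hasTab <- int1()
  if (length(hasTab) == 0L || hasTab != 1L)
    stop("missing colour table in .annot file: ", path)
  version <- int1()
  if (version >= 0L) stop("only version-2 .annot colour tables supported")
  rawStr <- function(len) {
    b <- readBin(con, "raw", len)
    z <- which(b == as.raw(0L))
    rawToChar(if (length(z)) b[seq_len(z[1L] - 1L)] else b)
  }
  nEntries <- int1()
  fnLen <- int1(); rawStr(fnLen)
  nRead <- int1()
  names <- character(nRead); annotVal <- integer(nRead)
  for (i in seq_len(nRead)) {
    int1()                                  # structure id
    len <- int1()
    names[i] <- rawStr(len)
    rgba <- readBin(con, "integer", 4L, size = 4L, endian = "big")
    annotVal[i] <- rgba[1L] + rgba[2L] * 256L + rgba[3L] * 65536L
  }
  unknown <- annotVal == 0L | names == "unknown"
  regionNames <- names[!unknown]
  labels <- integer(nv)
  labels[vtx + 1L] <- match(ann, annotVal[!unknown], nomatch = 0L)
  list(labels = labels, regionNames = regionNames)
}

#' Write a parcellation as FreeSurfer .annot (version-2 colour table)
#'
#' Regions get arbitrary distinct colours; the reserved label 0 maps to an
#' `unknown` entry with a zero annotation value.
#'
#' @param parcellation a [Parcellation-class].
#' @param path output `.annot` path.
#' @return `path`, invisibly.
#' @export
writeParcellationAnnot <- function(parcellation, path) {
  lab <- regionLabels(parcellation)
  nms <- regionNames(parcellation)
  k <- length(nms)
  ## distinct packed-RGB annotation values per region (avoid 0)
  rgb <- cbind((seq_len(k) * 37L) %% 256L,
               (seq_len(k) * 101L) %% 256L,
               (seq_len(k) * 151L) %% 256L)
  av <- rgb[, 1L] + rgb[, 2L] * 256L + rgb[, 3L] * 65536L
  while (anyDuplicated(av) || any(av == 0L)) {
    bad <- duplicated(av) | av == 0L
    rgb[bad, 1L] <- (rgb[bad, 1L] + 1L) %% 256L
    av <- rgb[, 1L] + rgb[, 2L] * 256L + rgb[, 3L] * 65536L
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "big")
  wStr <- function(s) {
    wInt(nchar(s) + 1L)
    writeBin(c(charToRaw(s), as.raw(0L)), con)
  }
  nv <- length(lab)
  wInt(nv)
  ann <- c(0L, av)[lab + 1L]
  wInt(as.vector(rbind(seq_len(nv) - 1L, ann)))
  wInt(1L)                                  # colour table present
  wInt(-2L)                                 # version 2
  wInt(k + 1L)
  wStr("synthetic.ctab")
  wInt(k + 1L)
  writeEntry <- function(id, name, r, g, b) {
    wInt(id); wStr(name); wInt(c(r, g, b, 0L))
  }
  writeEntry(0L, "unknown", 0L, 0L, 0L)
  for (i in seq_len(k))
    writeEntry(i, nms[i], rgb[i, 1L], rgb[i, 2L], rgb[i, 3L])
  invisible(path)
}
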