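#' Write a correspondence map as TSV
#'
#' Columns: `seed_index`, `target_index` (0-based on disk; -1 sentinel for
#' excluded seeds), `score` (9 significant digits; `nan` for excluded),
#' `direction`, `kind`. Tab-separated, LF line endings, UTF-8 — bit-exact
#' across platforms.
#'
#' @param map a [CorrespondenceMap-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCorrespondence <- function(map, path) {
  ti <- targetIndex(map)
  tgt <- ifelse(is.na(ti), -1L, ti - 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("seed_index\ttarget_index\tscore\tdirection\tkind",
               sprintf("%d\t%d\t%s\t%s\t%s",
                       seq_along(tgt) - 1L, tgt, fmtNum(matchScore(map)),
                       map@direction, map@kind)),
             con, sep = "\n")
  invisible(path)
}

#' Read a correspondence map from TSV
#'
#' @param path path written by [writeCorrespondence()].
#' @param nTarget vertex count of the target hemisphere; defaults to the
#'   largest target index present.
#' @return a [CorrespondenceMap-class].
#' @export
readCorrespondence <- function(path, nTarget = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  ti <- ifelse(tab$target_index < 0L, NA_integer_, tab$target_index + 1L)
  sc <- suppressWarnings(as.numeric(tab$score))
  if (is.null(nTarget)) nTarget <- max(ti, na.rm = TRUE)
  new("CorrespondenceMap", targetIndex = as.integer(ti), score = sc,
      direction = tab$direction[1L], kind = tab$kind[1L],
      nTarget = as.integer(nTarget))
}

#' Write a per-vertex metric as TSV
#'
#' @param values numeric per-vertex values (`NA` written as `nan`).
#' @param path output path.
#' @param name column name for the value column.
#' @return `path`, invisibly.
#' @export
writeVertexMetric <- function(values, path, name = "value") {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(sprintf("vertex\t%s", name),
               sprintf("%d\t%s", seq_along(values) - 1L, fmtNum(values))),
             con, sep = "\n")
  invisible(path)
}

#' Write a synthetic scene to a directory
#'
#' Writes GIFTI surfaces, parcellation TSVs, per-subject time-series TSV
#' matrices, the mirror map, and `truth.json` recording the generator
#' parameters, so a scene can be consumed through the file-based pipeline.
#'
#' @param scene a [SyntheticScene-class].
#' @param dir output directory (created).
#' @return the config list that [runPipeline()] accepts, invisibly.
#' @export
writeScene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  writeSurface(scene@leftMesh, p("lh.surf.gii"))
  writeSurface(scene@rightMesh, p("rh.surf.gii"))
  writeParcellation(scene@leftParcellation, p("lh.parc.tsv"))
  writeParcellation(scene@rightParcellation, p("rh.parc.tsv"))
  writeVertexMetric(scene@mirrorMap - 1L, p("mirror_map.tsv"), "right_vertex")
  subjects <- lapply(seq_along(scene@subjects), function(i) {
    lp <- p(sprintf("ts_s%02d_lh.tsv", i)); rp <- p(sprintf("ts_s%02d_rh.tsv", i))
    writeTimeSeries(scene@subjects[[i]]$left, lp)
    writeTimeSeries(scene@subjects[[i]]$right, rp)
    list(left = lp, right = rp)
  })
  truth <- scene@truth
  truth$networks <- lapply(truth$networks, function(nw)
    list(vertices = nw$vertices - 1L, rho = nw$rho))
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  cfg <- list(leftSurf = p("lh.surf.gii"), rightSurf = p("rh.surf.gii"),
              leftParc = p("lh.parc.tsv"), rightParc = p("rh.parc.tsv"),
              subjects = subjects)
  invisible(cfg)
}
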