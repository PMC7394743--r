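# Plain-text interchange formats: per-subject series and motion TSV,
# covariates CSV, connectivity and edge-list TSV, JSON manifests.

#' Write / read a region-by-volume series TSV
#'
#' Regions are rows (row labels = region index), volumes are columns.
#'
#' @param series an [RoiTimeSeries-class].
#' @param path output file.
#' @export
writeSeriesTSV <- function(series, path) {
  v <- seriesValues(series)
  rownames(v) <- regionIds(series)
  utils::write.table(v, path, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = TRUE)
  invisible(path)
}

#' @rdname writeSeriesTSV
#' @param trSeconds repetition time to attach on read.
#' @export
readSeriesTSV <- function(path, trSeconds = 2) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           row.names = 1, check.names = FALSE)
  roiTimeSeries(as.matrix(tab), trSeconds = trSeconds,
                regionIds = as.integer(rownames(tab)))
}

#' Write / read a motion-parameter TSV
#'
#' Volumes x 6 table; a leading comment line documents the column order
#' (three rotations in radians, then three translations in mm).
#'
#' @param motion a [MotionRecord-class].
#' @param path output file.
#' @export
writeMotionTSV <- function(motion, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# columns: rot_x rot_y rot_z (rad),",
                   "trans_x trans_y trans_z (mm)"), con)
  utils::write.table(motionParams(motion), con, sep = "\t", quote = FALSE,
                     col.names = TRUE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMotionTSV
#' @export
readMotionTSV <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "#")
  motionRecord(as.matrix(tab))
}

#' Write / read a connectivity matrix TSV
#'
#' Square tab-separated table with region ids as both header row and first
#' column.
#'
#' @param conn a [ConnectivityMatrix-class].
#' @param path output file.
#' @export
writeConnectivityTSV <- function(conn, path) {
  v <- connValues(conn)
  dimnames(v) <- list(regionIds(conn), regionIds(conn))
  utils::write.table(v, path, sep = "\t", quote = FALSE,
                     col.names = NA, row.names = TRUE)
  invisible(path)
}

#' @rdname writeConnectivityTSV
#' @export
readConnectivityTSV <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE)
  connectivityMatrix(as.matrix(tab), regionIds = as.integer(rownames(tab)))
}

#' Write a spanning tree as a 3-column edge list TSV
#'
#' @param tree a [SpanningTree-class].
#' @param path output file.
#' @export
writeTreeTSV <- function(tree, path) {
  utils::write.table(treeEdges(tree), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Emits the interchange files of a [simulateCohort()] result under
#' \code{dir}: \code{covariates.csv}, per-subject \code{<id>_series.tsv} and
#' \code{<id>_motion.tsv}, and \code{manifest.json} echoing the seed and
#' configuration.
#'
#' @param cohort result of [simulateCohort()].
#' @param dir output directory (created if missing).
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  for (id in names(cohort$subjects)) {
    s <- cohort$subjects[[id]]
    writeSeriesTSV(s$series, file.path(dir, paste0(id, "_series.tsv")))
    writeMotionTSV(s$motion, file.path(dir, paste0(id, "_motion.tsv")))
  }
  manifest <- list(seed = cohort$config$seed,
                   config = unclass(cohort$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
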