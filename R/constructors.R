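#' Construct an RoiTimeSeries
#'
#' @param values numeric matrix, regions x volumes.
#' @param trSeconds repetition time in seconds. Default 2, the acquisition
#'   interval of a typical resting-state EPI sequence.
#' @param retainedMask logical per-volume retention mask; defaults to all
#'   retained.
#' @param regionIds integer region labels; defaults to 1..nrow(values).
#' @return an [RoiTimeSeries-class] object.
#' @examples
#' ts <- roiTimeSeries(matrix(rnorm(40), nrow = 4), trSeconds = 2)
#' nRegions(ts)
#' retainedSeconds(ts)
#' @export
roiTimeSeries <- function(values, trSeconds = 2,
                          retainedMask = rep(TRUE, ncol(values)),
                          regionIds = seq_len(nrow(values))) {
  storage.mode(values) <- "double"
  new("RoiTimeSeries", values = values, trSeconds = as.numeric(trSeconds),
      retainedMask = retainedMask, regionIds = as.integer(regionIds))
}

#' Construct a MotionRecord
#'
#' Framewise displacement is computed from the parameters unless an explicit
#' trace is supplied.
#'
#' @param params numeric matrix, volumes x 6: three rotations (radians) then
#'   three translations (mm).
#' @param fd optional precomputed framewise displacement trace (mm).
#' @param meanRelDisplacement mean relative displacement (mm) as reported by
#'   the realignment tool; \code{NA} if unavailable.
#' @param headRadiusMm rotation-to-arc conversion radius used when deriving
#'   \code{fd}; 50 mm by convention.
#' @return a [MotionRecord-class] object.
#' @export
motionRecord <- function(params, fd = NULL, meanRelDisplacement = NA_real_,
                         headRadiusMm = 50) {
  storage.mode(params) <- "double"
  if (is.null(fd)) fd <- computeFD(params, headRadiusMm = headRadiusMm)
  new("MotionRecord", params = params, fd = as.numeric(fd),
      meanRelDisplacement = as.numeric(meanRelDisplacement))
}

#' Construct a ConnectivityMatrix
#'
#' @param values symmetric correlation matrix with unit diagonal.
#' @param regionIds integer region labels; defaults to 1..n.
#' @return a [ConnectivityMatrix-class] object.
#' @export
connectivityMatrix <- function(values, regionIds = seq_len(nrow(values))) {
  storage.mode(values) <- "double"
  values <- (values + t(values)) / 2  # kill asymmetric rounding noise
  diag(values) <- 1
  new("ConnectivityMatrix", values = values, regionIds = as.integer(regionIds))
}

# Internal: build a SpanningTree from an edge table, deriving degrees.
.spanningTree <- function(nNodes, i, j, weight) {
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  o <- order(i, j)
  edges <- data.frame(i = as.integer(i[o]), j = as.integer(j[o]),
                      weight = as.numeric(weight[o]))
  deg <- tabulate(c(edges$i, edges$j), nbins = nNodes)
  new("SpanningTree", nNodes = as.integer(nNodes), edges = edges,
      degree = as.integer(deg))
}
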