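#' @rdname RoiTimeSeries-class
#' @export
setMethod("seriesValues", "RoiTimeSeries", function(x) x@values)

#' @rdname RoiTimeSeries-class
#' @export
setMethod("trSeconds", "RoiTimeSeries", function(x) x@trSeconds)

#' @rdname RoiTimeSeries-class
#' @export
setMethod("retainedMask", "RoiTimeSeries", function(x) x@retainedMask)

#' @rdname RoiTimeSeries-class
#' @export
setMethod("regionIds", "RoiTimeSeries", function(x) x@regionIds)

#' @rdname ConnectivityMatrix-class
#' @export
setMethod("regionIds", "ConnectivityMatrix", function(x) x@regionIds)

#' @rdname RoiTimeSeries-class
#' @export
setMethod("nVolumes", "RoiTimeSeries", function(x) ncol(x@values))

#' @rdname RoiTimeSeries-class
#' @export
setMethod("nRegions", "RoiTimeSeries", function(x) nrow(x@values))

#' @rdname RoiTimeSeries-class
#' @export
setMethod("retainedSeconds", "RoiTimeSeries",
          function(x) sum(x@retainedMask) * x@trSeconds)

#' @rdname MotionRecord-class
#' @export
setMethod("motionParams", "MotionRecord", function(x) x@params)

#' @rdname MotionRecord-class
#' @export
setMethod("fdTrace", "MotionRecord", function(x) x@fd)

#' @rdname MotionRecord-class
#' @export
setMethod("meanRelDisplacement", "MotionRecord",
          function(x) x@meanRelDisplacement)

#' @rdname ConnectivityMatrix-class
#' @export
setMethod("connValues", "ConnectivityMatrix", function(x) x@values)

#' @rdname SpanningTree-class
#' @export
setMethod("treeEdges", "SpanningTree", function(x) x@edges)

#' @rdname SpanningTree-class
#' @export
setMethod("nodeDegree", "SpanningTree", function(x) x@degree)

setMethod("show", "RoiTimeSeries", function(object) {
  cat("RoiTimeSeries:", nrow(object@values), "regions x",
      ncol(object@values), "volumes (TR =", object@trSeconds, "s)\n")
  cat("  retained:", sum(object@retainedMask), "volumes (",
      format(retainedSeconds(object)), "s )\n")
})

setMethod("show", "MotionRecord", function(object) {
  cat("MotionRecord:", nrow(object@params), "volumes\n")
  if (length(object@fd)) {
    cat("  FD (mm): mean", format(mean(object@fd), digits = 3),
        "max", format(max(object@fd), digits = 3), "\n")
  }
  cat("  mean relative displacement:",
      ifelse(is.na(object@meanRelDisplacement), "not supplied",
             format(object@meanRelDisplacement, digits = 3)), "\n")
})

setMethod("show", "ConnectivityMatrix", function(object) {
  n <- nrow(object@values)
  off <- object@values[upper.tri(object@values)]
  cat("ConnectivityMatrix:", n, "x", n, "\n")
  if (length(off)) {
    cat("  off-diagonal r: mean", format(mean(off), digits = 3),
        "range [", format(min(off), digits = 3), ",",
        format(max(off), digits = 3), "]\n")
  }
})

setMethod("show", "SpanningTree", function(object) {
  cat("SpanningTree:", object@nNodes, "nodes,", nrow(object@edges),
      "edges\n")
  cat("  strength", format(globalStrength(object), digits = 4),
      "| diameter", treeDiameter(object),
      "| leaf fraction", format(leafFraction(object), digits = 4), "\n")
})
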