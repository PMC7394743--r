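#' @rdname RoiTimeSeries-class
#' @param object,x an object.
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))

#' @rdname RoiTimeSeries-class
#' @export
setGeneric("trSeconds", function(x) standardGeneric("trSeconds"))

#' @rdname RoiTimeSeries-class
#' @export
setGeneric("retainedMask", function(x) standardGeneric("retainedMask"))

#' @rdname RoiTimeSeries-class
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' @rdname RoiTimeSeries-class
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))

#' @rdname RoiTimeSeries-class
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @rdname RoiTimeSeries-class
#' @export
setGeneric("retainedSeconds", function(x) standardGeneric("retainedSeconds"))

#' @rdname MotionRecord-class
#' @export
setGeneric("motionParams", function(x) standardGeneric("motionParams"))

#' @rdname MotionRecord-class
#' @export
setGeneric("fdTrace", function(x) standardGeneric("fdTrace"))

#' @rdname MotionRecord-class
#' @export
setGeneric("meanRelDisplacement",
           function(x) standardGeneric("meanRelDisplacement"))

#' @rdname ConnectivityMatrix-class
#' @export
setGeneric("connValues", function(x) standardGeneric("connValues"))

#' @rdname SpanningTree-class
#' @export
setGeneric("treeEdges", function(x) standardGeneric("treeEdges"))

#' @rdname SpanningTree-class
#' @export
setGeneric("nodeDegree", function(x) standardGeneric("nodeDegree"))

#' @rdname SpanningTree-class
#' @export
setGeneric("globalStrength", function(x) standardGeneric("globalStrength"))

#' @rdname SpanningTree-class
#' @export
setGeneric("treeDiameter", function(x) standardGeneric("treeDiameter"))

#' @rdname SpanningTree-class
#' @export
setGeneric("leafFraction", function(x) standardGeneric("leafFraction"))
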