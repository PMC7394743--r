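#' @import methods
NULL

#' ROI-by-volume BOLD time series for one subject
#'
#' Container for a single subject's region-averaged BOLD signal. Rows are
#' parcellation regions, columns are acquired volumes. Carries the repetition
#' time and a per-volume retention mask so that motion scrubbing can censor
#' volumes without destroying their values.
#'
#' @slot values numeric matrix, regions x volumes.
#' @slot trSeconds repetition time in seconds (scan interval between volumes).
#' @slot retainedMask logical vector, one entry per volume; \code{FALSE} marks
#'   a censored volume.
#' @slot regionIds integer region labels (Power parcellation indices, 1-based).
#'
#' @seealso [roiTimeSeries()] for the user-facing constructor,
#'   [censorVolumes()], [pearsonMatrix()]
#' @export
setClass("RoiTimeSeries",
  representation(
    values = "matrix",
    trSeconds = "numeric",
    retainedMask = "logical",
    regionIds = "integer"
  )
)

setValidity("RoiTimeSeries", function(object) {
  msg <- character()
  if (!is.numeric(object@values)) {
    msg <- c(msg, "'values' must be a numeric matrix")
  }
  if (length(object@trSeconds) != 1L || !is.finite(object@trSeconds) ||
      object@trSeconds <= 0) {
    msg <- c(msg, "'trSeconds' must be a single positive number")
  }
  if (length(object@retainedMask) != ncol(object@values)) {
    msg <- c(msg, "'retainedMask' length must equal the number of volumes")
  }
  if (anyNA(object@retainedMask)) {
    msg <- c(msg, "'retainedMask' must not contain NA")
  }
  if (length(object@regionIds) != nrow(object@values)) {
    msg <- c(msg, "'regionIds' length must equal the number of regions")
  }
  if (anyDuplicated(object@regionIds)) {
    msg <- c(msg, "'regionIds' must be distinct")
  }
  if (length(msg)) msg else TRUE
})

#' Rigid-body motion record for one subject
#'
#' Six realignment parameters per volume (three rotations in radians followed
#' by three translations in millimetres) together with the derived framewise
#' displacement trace. \code{meanRelDisplacement} holds the realignment tool's
#' mean relative displacement when available; when absent the subject-level
#' motion gate falls back to mean framewise displacement as a proxy.
#'
#' @slot params numeric matrix, volumes x 6 (rot_x, rot_y, rot_z in radians;
#'   trans_x, trans_y, trans_z in mm).
#' @slot fd numeric framewise displacement per volume in mm; \code{fd[1] == 0}.
#' @slot meanRelDisplacement single numeric (mm) or \code{NA_real_}.
#'
#' @seealso [motionRecord()], [computeFD()], [subjectMotionGate()]
#' @export
setClass("MotionRecord",
  representation(
    params = "matrix",
    fd = "numeric",
    meanRelDisplacement = "numeric"
  )
)

setValidity("MotionRecord", function(object) {
  msg <- character()
  if (ncol(object@params) != 6L) {
    msg <- c(msg, "'params' must have exactly 6 columns")
  }
  if (length(object@fd) != nrow(object@params)) {
    msg <- c(msg, "'fd' length must equal the number of volumes")
  }
  if (length(object@fd) > 0L) {
    if (any(!is.finite(object@fd)) || any(object@fd < 0)) {
      msg <- c(msg, "'fd' must be finite and non-negative")
    } else if (object@fd[1L] != 0) {
      msg <- c(msg, "'fd' must start at 0 (first volume has no predecessor)")
    }
  }
  if (length(object@meanRelDisplacement) != 1L) {
    msg <- c(msg, "'meanRelDisplacement' must be a single number (or NA)")
  }
  if (length(msg)) msg else TRUE
})

#' Functional connectivity matrix
#'
#' Symmetric Pearson correlation matrix over parcellation regions, with unit
#' diagonal and entries in [-1, 1].
#'
#' @slot values symmetric numeric correlation matrix.
#' @slot regionIds integer region labels matching the matrix order.
#'
#' @seealso [connectivityMatrix()], [pearsonMatrix()], [kruskalMST()]
#' @export
setClass("ConnectivityMatrix",
  representation(
    values = "matrix",
    regionIds = "integer"
  )
)

setValidity("ConnectivityMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) {
    msg <- c(msg, "'values' must be square")
  } else {
    if (!isTRUE(all.equal(v, t(v), tolerance = 1e-12, scale = 1))) {
      msg <- c(msg, "'values' must be symmetric within 1e-12")
    }
    if (any(diag(v) != 1)) {
      msg <- c(msg, "diagonal must be exactly 1")
    }
    if (any(!is.finite(v)) || any(v < -1) || any(v > 1)) {
      msg <- c(msg, "entries must be finite and within [-1, 1]")
    }
  }
  if (length(object@regionIds) != nrow(v)) {
    msg <- c(msg, "'regionIds' length must equal matrix dimension")
  }
  if (anyDuplicated(object@regionIds)) {
    msg <- c(msg, "'regionIds' must be distinct")
  }
  if (length(msg)) msg else TRUE
})

#' Spanning-tree backbone of a connectivity matrix
#'
#' The acyclic backbone connecting all regions through their strongest
#' positive correlations: n - 1 positive-weight edges, no cycles, a single
#' connected component. Following the resting-state network literature the
#' object is called an MST even though it maximizes total weight.
#'
#' @slot nNodes number of nodes (regions).
#' @slot edges data.frame with integer columns \code{i}, \code{j} (1-based
#'   node positions, i < j) and numeric \code{weight} (> 0); n - 1 rows.
#' @slot degree integer degree sequence over the n nodes.
#'
#' @seealso [kruskalMST()], [globalStrength()], [treeDiameter()],
#'   [leafFraction()]
#' @export
setClass("SpanningTree",
  representation(
    nNodes = "integer",
    edges = "data.frame",
    degree = "integer"
  )
)

setValidity("SpanningTree", function(object) {
  n <- object@nNodes
  e <- object@edges
  msg <- character()
  if (!all(c("i", "j", "weight") %in% names(e))) {
    return("'edges' must have columns i, j, weight")
  }
  if (nrow(e) != n - 1L) {
    msg <- c(msg, "a spanning tree on n nodes must have n - 1 edges")
  }
  if (nrow(e) > 0L) {
    if (any(e$i < 1L | e$i > n | e$j < 1L | e$j > n | e$i >= e$j)) {
      msg <- c(msg, "edge endpoints must satisfy 1 <= i < j <= n")
    }
    if (any(e$weight <= 0)) {
      msg <- c(msg, "all edge weights must be strictly positive")
    }
  }
  if (length(object@degree) != n) {
    msg <- c(msg, "'degree' must have one entry per node")
  } else if (sum(object@degree) != 2L * (n - 1L)) {
    msg <- c(msg, "degree sum must equal 2(n - 1)")
  }
  # connectivity + acyclicity: n-1 edges and a single component
  if (n > 0L && nrow(e) == n - 1L) {
    comp <- .unionFindComponents(n, e$i, e$j)
    if (length(unique(comp)) != 1L) {
      msg <- c(msg, "edges must form a single connected component")
    }
  }
  if (length(msg)) msg else TRUE
})

# Component labels by union-find; used by the SpanningTree validity check.
.unionFindComponents <- function(n, i, j) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(i)) {
    ri <- find(i[k]); rj <- find(j[k])
    if (ri != rj) parent[rj] <- ri
  }
  vapply(seq_len(n), find, integer(1))
}
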