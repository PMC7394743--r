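#' Pearson functional connectivity matrix
#'
#' Correlates every pair of region time series over the retained volumes,
#' yielding the subject's functional connectivity matrix (unit diagonal,
#' symmetric). A region with zero variance over the retained volumes has no
#' defined correlation and is an error.
#'
#' @param series an [RoiTimeSeries-class]; only volumes with
#'   \code{retainedMask == TRUE} enter the correlation.
#' @return a [ConnectivityMatrix-class].
#' @export
pearsonMatrix <- function(series) {
  stopifnot(is(series, "RoiTimeSeries"))
  keep <- retainedMask(series)
  if (sum(keep) < 3L) stop("need at least 3 retained volumes")
  v <- seriesValues(series)[, keep, drop = FALSE]
  sds <- apply(v, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance region(s) over retained volumes: ",
         paste(regionIds(series)[sds == 0], collapse = ", "))
  }
  r <- stats::cor(t(v))
  r[r > 1] <- 1; r[r < -1] <- -1
  connectivityMatrix(r, regionIds = regionIds(series))
}

#' Default PCC and DLPFC region sets
#'
#' The posterior cingulate cortex and left/right dorsolateral prefrontal
#' cortex node sets over the Power 264-region parcellation, with the MNI
#' centres (mm) of each member region for documentation:
#' PCC = regions 77 (-11/-56/16), 78 (-3/-49/13), 82 (11/-54/17);
#' DLPFC left = 167 (-42/38/21), 176 (-34/55/4);
#' DLPFC right = 168 (38/43/15), 175 (40/18/40).
#'
#' @return a named list of region sets; each is a list with \code{name},
#'   \code{members} (Power indices) and \code{mni} (members x 3 matrix).
#' @export
powerRegionSets <- function() {
  list(
    pcc = list(name = "PCC", members = c(77L, 78L, 82L),
               mni = matrix(c(-11, -56, 16, -3, -49, 13, 11, -54, 17),
                            ncol = 3, byrow = TRUE,
                            dimnames = list(NULL, c("x", "y", "z")))),
    dlpfc_left = list(name = "DLPFC left", members = c(167L, 176L),
                      mni = matrix(c(-42, 38, 21, -34, 55, 4),
                                   ncol = 3, byrow = TRUE,
                                   dimnames = list(NULL, c("x", "y", "z")))),
    dlpfc_right = list(name = "DLPFC right", members = c(168L, 175L),
                       mni = matrix(c(38, 43, 15, 40, 18, 40),
                                    ncol = 3, byrow = TRUE,
                                    dimnames = list(NULL, c("x", "y", "z"))))
  )
}

#' Regional connectivity between two region sets
#'
#' Averages the member time series within each set, then correlates the two
#' set-mean series over the retained volumes (average-then-correlate). Used
#' for the PCC-DLPFC secondary outcomes; see [powerRegionSets()] for the
#' default node sets.
#'
#' @param series an [RoiTimeSeries-class].
#' @param setA,setB region sets: either lists with a \code{members} element
#'   (as returned by [powerRegionSets()]) or plain integer vectors of region
#'   ids. Sets must be disjoint and all members present in the series.
#' @param meanOfPairwise alternative estimator for sensitivity analysis:
#'   average the pairwise correlations between members instead of correlating
#'   the set means (default FALSE).
#' @return a single Pearson correlation.
#' @export
regionalConnectivity <- function(series, setA, setB,
                                 meanOfPairwise = FALSE) {
  stopifnot(is(series, "RoiTimeSeries"))
  a <- if (is.list(setA)) setA$members else as.integer(setA)
  b <- if (is.list(setB)) setB$members else as.integer(setB)
  if (length(intersect(a, b))) stop("region sets must be disjoint")
  ids <- regionIds(series)
  if (!all(c(a, b) %in% ids)) {
    stop("region set member(s) absent from the series: ",
         paste(setdiff(c(a, b), ids), collapse = ", "))
  }
  keep <- retainedMask(series)
  v <- seriesValues(series)[, keep, drop = FALSE]
  ia <- match(a, ids); ib <- match(b, ids)
  if (meanOfPairwise) {
    r <- stats::cor(t(v[c(ia, ib), , drop = FALSE]))
    return(mean(r[seq_along(ia), length(ia) + seq_along(ib)]))
  }
  ma <- colMeans(v[ia, , drop = FALSE])
  mb <- colMeans(v[ib, , drop = FALSE])
  if (stats::sd(ma) == 0 || stats::sd(mb) == 0) {
    stop("zero-variance set average")
  }
  stats::cor(ma, mb)
}
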