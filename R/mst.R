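#' Maximum-weight spanning tree by Kruskal's algorithm
#'
#' Extracts the spanning backbone of a connectivity matrix from its strictly
#' positive correlations: candidate edges are ranked by descending weight and
#' added one at a time, skipping any edge that would close a loop
#' (union-find), until all n regions are connected by n - 1 edges. The
#' result attains the maximum total weight over all spanning trees of the
#' positive-correlation graph. Ties in weight are broken deterministically by
#' lexicographic (i, j) order. Zero and negative correlations are treated as
#' absent edges; if they disconnect the graph, the subject is not analyzable
#' under this rule and an error lists the components.
#'
#' In keeping with the resting-state literature the returned object is called
#' an MST although it is formally a maximum spanning tree.
#'
#' @param x a [ConnectivityMatrix-class] or a symmetric numeric matrix.
#' @return a [SpanningTree-class].
#' @examples
#' r <- matrix(c(1, 0.9, 0.5, 0.9, 1, 0.2, 0.5, 0.2, 1), 3, 3)
#' tr <- kruskalMST(r)
#' treeEdges(tr)           # edges (1,2) and (1,3)
#' globalStrength(tr)      # (0.9 + 0.5) / 2 = 0.7
#' @export
kruskalMST <- function(x) {
  m <- if (is(x, "ConnectivityMatrix")) connValues(x) else x
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("'x' must be a ConnectivityMatrix or a square numeric matrix")
  }
  sel <- .kruskalCore(m)
  .spanningTree(nrow(m), sel$i, sel$j, sel$weight)
}

# Kruskal on the strictly positive upper triangle; returns the selected
# edges without constructing the S4 container (hot path of the calibration
# simulations). Errors with the component decomposition on disconnection.
.kruskalCore <- function(m) {
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 nodes")
  up <- upper.tri(m)
  w <- m[up]
  pos <- which(w > 0)
  idx <- which(up)[pos] - 1L
  ei <- idx %% n + 1L
  ej <- idx %/% n + 1L
  ew <- w[pos]
  o <- order(-ew, ei, ej)
  ei <- ei[o]; ej <- ej[o]; ew <- ew[o]

  parent <- seq_len(n)
  rnk <- integer(n)
  selI <- integer(n - 1L); selJ <- integer(n - 1L); selW <- numeric(n - 1L)
  nSel <- 0L
  for (k in seq_along(ew)) {
    a <- ei[k]
    while (parent[a] != a) {
      parent[a] <- parent[parent[a]]  # path halving
      a <- parent[a]
    }
    b <- ej[k]
    while (parent[b] != b) {
      parent[b] <- parent[parent[b]]
      b <- parent[b]
    }
    if (a == b) next
    if (rnk[a] < rnk[b]) { tmp <- a; a <- b; b <- tmp }
    parent[b] <- a
    if (rnk[a] == rnk[b]) rnk[a] <- rnk[a] + 1L
    nSel <- nSel + 1L
    selI[nSel] <- ei[k]; selJ[nSel] <- ej[k]; selW[nSel] <- ew[k]
    if (nSel == n - 1L) break
  }
  if (nSel < n - 1L) {
    root <- function(a) {
      while (parent[a] != a) a <- parent[a]
      a
    }
    comp <- vapply(seq_len(n), root, integer(1))
    comp <- match(comp, unique(comp))
    groups <- split(seq_len(n), comp)
    stop("positive-correlation graph is disconnected (",
         length(groups), " components): ",
         paste(vapply(groups, function(g)
           paste0("{", paste(g, collapse = ","), "}"), character(1)),
           collapse = " "))
  }
  list(i = selI, j = selJ, weight = selW)
}

#' @describeIn SpanningTree-class Global functional connectivity strength:
#'   the arithmetic mean of the n - 1 MST edge weights (correlation units).
#' @export
setMethod("globalStrength", "SpanningTree", function(x) {
  mean(x@edges$weight)
})

#' @describeIn SpanningTree-class MST diameter: the number of edges on the
#'   longest shortest path between any two nodes (network-efficiency
#'   measure; computed by double breadth-first traversal).
#' @export
setMethod("treeDiameter", "SpanningTree", function(x) {
  n <- x@nNodes
  if (n < 2L) return(0L)
  adj <- .adjacencyList(x)
  far1 <- .bfsFarthest(adj, 1L, n)
  far2 <- .bfsFarthest(adj, far1$node, n)
  far2$dist
})

#' @describeIn SpanningTree-class Leaf fraction: the proportion of nodes with
#'   degree one (network-integration measure).
#' @export
setMethod("leafFraction", "SpanningTree", function(x) {
  sum(x@degree == 1L) / x@nNodes
})

.adjacencyList <- function(tree) {
  adj <- vector("list", tree@nNodes)
  e <- tree@edges
  for (k in seq_len(nrow(e))) {
    adj[[e$i[k]]] <- c(adj[[e$i[k]]], e$j[k])
    adj[[e$j[k]]] <- c(adj[[e$j[k]]], e$i[k])
  }
  adj
}

# BFS from 'start'; returns the farthest node and its distance in edges.
.bfsFarthest <- function(adj, start, n) {
  dist <- rep(-1L, n)
  dist[start] <- 0L
  queue <- integer(n); queue[1L] <- start
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    for (u in adj[[v]]) {
      if (dist[u] < 0L) {
        dist[u] <- dist[v] + 1L
        tail <- tail + 1L
        queue[tail] <- u
      }
    }
  }
  far <- which.max(dist)
  list(node = far, dist = dist[far])
}

#' Network outcome measures for one subject
#'
#' Computes the five outcomes analysed at the group level: global MST
#' strength, MST diameter, MST leaf fraction, and the PCC-DLPFC left/right
#' regional connectivities. The regional outcomes require the corresponding
#' Power regions to be present in the series; when they are absent (e.g.
#' reduced-parcellation simulations) they are returned as \code{NA}.
#'
#' @param series a denoised [RoiTimeSeries-class].
#' @param regionSets list of region sets as [powerRegionSets()]; must contain
#'   \code{pcc}, \code{dlpfc_left}, \code{dlpfc_right}.
#' @return a one-row data.frame with columns \code{strength},
#'   \code{diameter}, \code{leaf_fraction}, \code{pcc_dlpfc_left},
#'   \code{pcc_dlpfc_right}.
#' @export
networkOutcomes <- function(series, regionSets = powerRegionSets()) {
  conn <- pearsonMatrix(series)
  tree <- kruskalMST(conn)
  ids <- regionIds(series)
  regional <- function(set) {
    if (all(regionSets$pcc$members %in% ids) &&
        all(set$members %in% ids)) {
      regionalConnectivity(series, regionSets$pcc, set)
    } else NA_real_
  }
  data.frame(
    strength = globalStrength(tree),
    diameter = treeDiameter(tree),
    leaf_fraction = leafFraction(tree),
    pcc_dlpfc_left = regional(regionSets$dlpfc_left),
    pcc_dlpfc_right = regional(regionSets$dlpfc_right)
  )
}
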