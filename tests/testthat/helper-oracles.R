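# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: tree enumeration goes through Prufer sequences,
# the FDR oracle is the literal step-up definition, and regression residuals
# come from the normal equations.

# Decode a Prufer sequence into the n-1 edges of its labeled tree.
pruferDecode <- function(pr, n) {
  deg <- rep(1L, n)
  for (v in pr) deg[v] <- deg[v] + 1L
  edges <- matrix(0L, nrow = n - 1L, ncol = 2L)
  for (k in seq_along(pr)) {
    leaf <- which(deg == 1L)[1L]
    edges[k, ] <- c(leaf, pr[k])
    deg[leaf] <- 0L
    deg[pr[k]] <- deg[pr[k]] - 1L
  }
  edges[n - 1L, ] <- which(deg == 1L)
  edges
}

# All labeled trees on n nodes (Cayley: n^(n-2)), as a list of edge
# matrices. Cached per n because the enumeration is weight-independent.
.treeCache <- new.env()
allLabeledTrees <- function(n) {
  key <- as.character(n)
  if (!is.null(.treeCache[[key]])) return(.treeCache[[key]])
  trees <- if (n == 2L) {
    list(matrix(c(1L, 2L), 1L, 2L))
  } else {
    prufer <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
    lapply(seq_len(nrow(prufer)), function(r) {
      pruferDecode(as.integer(prufer[r, ]), n)
    })
  }
  .treeCache[[key]] <- trees
  trees
}

# Exhaustive maximum-weight spanning tree over the strictly positive edges
# of a symmetric matrix. Returns NULL when no spanning tree is feasible.
enumMaxSpanningTree <- function(m) {
  n <- nrow(m)
  trees <- allLabeledTrees(n)
  best <- NULL
  bestW <- -Inf
  for (e in trees) {
    w <- m[cbind(e[, 1L], e[, 2L])]
    if (any(w <= 0)) next
    tot <- sum(w)
    if (tot > bestW) {
      bestW <- tot
      best <- e
    }
  }
  if (is.null(best)) return(NULL)
  o <- t(apply(best, 1, sort))
  list(edges = o[order(o[, 1L], o[, 2L]), , drop = FALSE], total = bestW)
}

# Brute-force tree diameter: all-pairs shortest paths by repeated BFS over
# an edge matrix.
bruteDiameter <- function(edges, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1L]; j <- edges[k, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  maxd <- 0L
  for (s in seq_len(n)) {
    dist <- rep(-1L, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (u in adj[[v]]) {
        if (dist[u] < 0L) {
          dist[u] <- dist[v] + 1L
          queue <- c(queue, u)
        }
      }
    }
    maxd <- max(maxd, max(dist))
  }
  maxd
}

# Prim-style maximum spanning tree (independent of the Kruskal route):
# grows the tree from node 1, always adding the heaviest positive edge
# leaving the tree. Returns total weight and sorted edge matrix.
primMaxSpanningTree <- function(m) {
  n <- nrow(m)
  m2 <- m
  m2[m2 <= 0] <- -Inf
  diag(m2) <- -Inf
  inTree <- c(1L, rep(0L, n - 1L))
  bestW <- m2[, 1L]
  bestFrom <- rep(1L, n)
  edges <- matrix(0L, n - 1L, 2L)
  total <- 0
  for (k in seq_len(n - 1L)) {
    cand <- which(inTree == 0L)
    v <- cand[which.max(bestW[cand])]
    if (!is.finite(bestW[v])) return(NULL)  # disconnected
    edges[k, ] <- sort(c(bestFrom[v], v))
    total <- total + bestW[v]
    inTree[v] <- 1L
    upd <- which(inTree == 0L & m2[, v] > bestW)
    bestW[upd] <- m2[upd, v]
    bestFrom[upd] <- v
  }
  list(edges = edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE],
       total = total)
}

# Literal Benjamini-Hochberg step-up definition.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[o[i]] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  adj
}

# Random symmetric matrix with strictly positive, distinct off-diagonal
# weights (a complete graph, so always connected).
randomPositiveMatrix <- function(n) {
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  vals <- stats::runif(sum(up), 0.01, 0.99)
  w[up] <- vals
  w + t(w) + diag(n)
}

edgeMatrix <- function(tree) {
  e <- treeEdges(tree)
  as.matrix(e[order(e$i, e$j), c("i", "j")])
}

# Path and star connectivity matrices: the path/star edges get high
# correlation, everything else a low positive floor so the graph stays
# connected but the intended tree is the unique maximum.
pathMatrix <- function(n, hi = 0.9, lo = 0.05) {
  m <- matrix(lo, n, n)
  for (k in seq_len(n - 1L)) m[k, k + 1L] <- m[k + 1L, k] <- hi
  diag(m) <- 1
  m
}

starMatrix <- function(n, hi = 0.9, lo = 0.05) {
  m <- matrix(lo, n, n)
  m[1L, 2:n] <- m[2:n, 1L] <- hi
  diag(m) <- 1
  m
}
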