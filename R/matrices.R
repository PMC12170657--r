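## All-pairs shortest-path and detour (longest simple path) distances.
##
## Shortest paths are unit-weight BFS distances from igraph.  Detour
## distances are exact: the graph is decomposed into biconnected blocks;
## between two vertices the detour distance is the sum of per-block
## longest-path segments along the unique path in the block-cut tree, and
## within each block longest paths between all vertex pairs are found by
## exhaustive depth-first enumeration.  A per-block expansion budget
## guards against pathological (dense) inputs; molecule-like graphs with
## low cyclomatic number finish in milliseconds.

#' All-pairs shortest-path distance matrix
#'
#' Unit-weight breadth-first distances; symmetric with zero diagonal.
#'
#' @param g a [MolecularGraph-class] object.
#' @return an integer n-by-n matrix.
#' @export
shortestPathMatrix <- function(g) {
  stopifnot(is(g, "MolecularGraph"))
  d <- igraph::distances(.asIgraph(g))
  if (any(!is.finite(d)))
    .stopf("tcaQSPR_structural_error", "graph is disconnected")
  storage.mode(d) <- "integer"
  dimnames(d) <- NULL
  d
}

#' All-pairs detour (longest simple path) distance matrix
#'
#' Exact longest-simple-path lengths for every vertex pair, computed by
#' block-cut-tree decomposition: per biconnected block, all-pairs longest
#' paths by exhaustive DFS; across blocks, segments add along the unique
#' block path.  Identical to naive whole-graph enumeration, but feasible
#' for all-hydrogen molecular graphs (~60+ vertices) because pendant
#' hydrogens and bridges form trivial two-vertex blocks.
#'
#' @param g a [MolecularGraph-class] object.
#' @param budget maximum number of DFS expansions allowed per block
#'   before an explicit resource error is raised (never a silent
#'   approximation).
#' @return an integer n-by-n matrix.
#' @export
detourMatrix <- function(g, budget = 1e7) {
  stopifnot(is(g, "MolecularGraph"))
  n <- g@n
  if (n == 1L) return(matrix(0L, 1, 1))
  ig <- .asIgraph(g)
  if (igraph::components(ig)$no != 1)
    .stopf("tcaQSPR_structural_error", "graph is disconnected")

  bc <- igraph::biconnected_components(ig)
  blocks <- lapply(bc$components, function(v) sort(as.integer(v)))

  ## adjacency list of the whole graph
  adj <- vector("list", n)
  for (k in seq_len(nrow(g@edges))) {
    a <- g@edges[k, 1]; b <- g@edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }

  ## per-block all-pairs longest simple paths (exhaustive DFS)
  blockLP <- lapply(blocks, function(vs) {
    k <- length(vs)
    if (k == 2L) return(matrix(c(0L, 1L, 1L, 0L), 2, 2))
    pos <- integer(n); pos[vs] <- seq_len(k)
    ladj <- lapply(vs, function(v) pos[intersect(adj[[v]], vs)])
    .allPairsLongestPaths(ladj, k, budget)
  })

  ## bipartite block-cut tree: vertex nodes 1..n, block nodes n+1..n+k
  treeEdges <- do.call(rbind, lapply(seq_along(blocks), function(bi) {
    cbind(blocks[[bi]], n + bi)
  }))
  tree <- igraph::make_empty_graph(n = n + length(blocks), directed = FALSE)
  tree <- igraph::add_edges(tree, as.vector(t(treeEdges)))

  D <- matrix(0L, n, n)
  for (u in seq_len(n - 1L)) {
    paths <- igraph::shortest_paths(tree, from = u,
                                    to = seq.int(u + 1L, n),
                                    output = "vpath")$vpath
    for (j in seq_along(paths)) {
      p <- as.integer(paths[[j]])
      v <- p[length(p)]
      tot <- 0L
      ## path alternates vertex, block, vertex, block, ..., vertex
      for (k in seq(1L, length(p) - 2L, by = 2L)) {
        bi <- p[k + 1L] - n
        vs <- blocks[[bi]]
        tot <- tot + blockLP[[bi]][match(p[k], vs), match(p[k + 2L], vs)]
      }
      D[u, v] <- D[v, u] <- tot
    }
  }
  D
}

## exhaustive DFS over simple paths within one biconnected block;
## ladj is a local adjacency list over 1..k
.allPairsLongestPaths <- function(ladj, k, budget) {
  best <- matrix(0L, k, k)
  left <- budget
  visited <- logical(k)
  for (start in seq_len(k)) {
    ## iterative DFS: stack of (vertex, depth); explicit neighbour cursors
    stack <- integer(k + 1L); ptr <- vector("list", k + 1L)
    depth <- 1L
    stack[1L] <- start; ptr[[1L]] <- ladj[[start]]
    visited[start] <- TRUE
    while (depth > 0L) {
      nb <- ptr[[depth]]
      if (length(nb) == 0L) {
        visited[stack[depth]] <- FALSE
        depth <- depth - 1L
        next
      }
      w <- nb[1L]
      ptr[[depth]] <- nb[-1L]
      if (!visited[w]) {
        left <- left - 1L
        if (left < 0L)
          .stopf("tcaQSPR_resource_error",
                 "detour search budget exhausted within a block of %d vertices; raise `budget`",
                 k)
        depth <- depth + 1L
        stack[depth] <- w
        ptr[[depth]] <- ladj[[w]]
        visited[w] <- TRUE
        if (depth - 1L > best[start, w]) best[start, w] <- depth - 1L
      }
    }
  }
  best
}

#' Shortest-path and detour matrices of a graph
#'
#' Convenience constructor computing both matrices and wrapping them in a
#' validated [PairMatrices-class].
#'
#' @inheritParams detourMatrix
#' @return a [PairMatrices-class] object.
#' @export
pairMatrices <- function(g, budget = 1e7) {
  new("PairMatrices", d = shortestPathMatrix(g),
      D = detourMatrix(g, budget = budget))
}

#' Accessors for PairMatrices
#'
#' @param x a [PairMatrices-class] object.
#' @name pairAccessors
#' @aliases distanceMatrix detourDistances
NULL

#' @rdname pairAccessors
#' @export
setGeneric("distanceMatrix", function(x) standardGeneric("distanceMatrix"))

#' @rdname pairAccessors
#' @export
setGeneric("detourDistances", function(x) standardGeneric("detourDistances"))

#' @rdname pairAccessors
#' @export
setMethod("distanceMatrix", "PairMatrices", function(x) x@d)

#' @rdname pairAccessors
#' @export
setMethod("detourDistances", "PairMatrices", function(x) x@D)
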