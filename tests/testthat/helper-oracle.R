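# Independent oracles, deliberately naive: whole-graph DFS over all
# simple paths for detour distances, and boolean matrix powering for
# shortest-path distances.  Both stay independent of the package's
# block-decomposition / BFS code paths they are used to check.

oracleDetour <- function(g) {
  n <- vertexCount(g)
  e <- g@edges
  adj <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    adj[[e[k, 1]]] <- c(adj[[e[k, 1]]], e[k, 2])
    adj[[e[k, 2]]] <- c(adj[[e[k, 2]]], e[k, 1])
  }
  D <- matrix(0L, n, n)
  visited <- logical(n)
  dfs <- function(v, len, start) {
    if (len > D[start, v]) D[start, v] <<- len
    visited[v] <<- TRUE
    for (w in adj[[v]]) if (!visited[w]) dfs(w, len + 1L, start)
    visited[v] <<- FALSE
  }
  for (u in seq_len(n)) dfs(u, 0L, u)
  D
}

oracleShortestPaths <- function(g) {
  n <- vertexCount(g)
  A <- matrix(0, n, n)
  for (k in seq_len(nrow(g@edges))) {
    A[g@edges[k, 1], g@edges[k, 2]] <- 1
    A[g@edges[k, 2], g@edges[k, 1]] <- 1
  }
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  walk <- diag(n)
  for (s in seq_len(n - 1)) {
    walk <- (walk %*% A) > 0
    d[walk & is.infinite(d)] <- s
  }
  storage.mode(d) <- "integer"
  d
}
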