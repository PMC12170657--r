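# Shared fixtures, computed once per test run.

.fixtureCache <- new.env(parent = emptyenv())

fixtureDrugs <- function() {
  if (is.null(.fixtureCache$drugs)) .fixtureCache$drugs <- loadDrugs()
  .fixtureCache$drugs
}

fixtureMolecules <- function() {
  if (is.null(.fixtureCache$mols))
    .fixtureCache$mols <- loadMolecules(fixtureDrugs())
  .fixtureCache$mols
}

fixtureIndexTable <- function(mode) {
  key <- paste0("tab_", mode)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- computeIndexTable(fixtureMolecules(), mode)
  .fixtureCache[[key]]
}

# small hand-built graph
mkGraph <- function(n, edges, mode = "heavy") {
  e <- if (is.matrix(edges)) edges else
    matrix(as.integer(edges), ncol = 2, byrow = TRUE)
  storage.mode(e) <- "integer"
  new("MolecularGraph", n = as.integer(n), edges = e,
      mode = mode, vertexLabels = rep("C", n))
}

pathGraph <- function(n) mkGraph(n, as.vector(rbind(1:(n - 1), 2:n)))

cycleGraph <- function(n)
  mkGraph(n, c(as.vector(rbind(1:(n - 1), 2:n)), n, 1))

# sorted upper-triangle multiset of a distance matrix
distMultiset <- function(m) sort(m[upper.tri(m)])
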