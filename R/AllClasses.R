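## S4 containers for the molecular-graph pipeline.

#' Molecule: parsed chemical structure
#'
#' Heavy-atom connectivity of one compound plus per-atom implicit-hydrogen
#' counts, as produced by [parseSmiles()].  Bond orders, aromaticity and
#' charges are discarded after parsing: every chemical bond contributes one
#' edge of the underlying simple graph, which is all the distance-based
#' indices see.
#'
#' @slot name full compound name.
#' @slot abbreviation short code (three-letter code for the fixture drugs).
#' @slot smiles the input SMILES string.
#' @slot elements element symbol per heavy atom.
#' @slot hydrogens implicit-hydrogen count per heavy atom (non-negative).
#' @slot bonds two-column integer matrix of heavy-atom index pairs.
#'
#' @seealso [parseSmiles()], [buildGraph()], [molecularFormula()]
#' @export
setClass("Molecule",
  representation(
    name         = "character",
    abbreviation = "character",
    smiles       = "character",
    elements     = "character",
    hydrogens    = "integer",
    bonds        = "matrix"
  )
)

setValidity("Molecule", function(object) {
  n <- length(object@elements)
  b <- object@bonds
  if (length(object@hydrogens) != n)
    return("hydrogens must have one entry per heavy atom")
  if (any(object@hydrogens < 0))
    return("implicit-hydrogen counts must be non-negative")
  if (ncol(b) != 2)
    return("bonds must be a two-column matrix")
  if (nrow(b) > 0) {
    if (any(b < 1) || any(b > n))
      return("bond indices out of range")
    if (any(b[, 1] == b[, 2]))
      return("self-bonds are not allowed")
    key <- paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
    if (anyDuplicated(key))
      return("duplicate bonds are not allowed")
  }
  ## the heavy-atom graph must be one covalent entity
  if (n > 1) {
    if (nrow(b) == 0) return("a multi-atom molecule must have bonds")
    g <- igraph::graph_from_edgelist(b, directed = FALSE)
    if (igraph::vcount(g) < n || igraph::components(g)$no != 1)
      return("heavy-atom graph is disconnected")
  }
  TRUE
})

#' MolecularGraph: simple undirected connected graph under a hydrogen mode
#'
#' The graph object every index is computed from.  `mode` records the
#' hydrogen representation: `"heavy"` (H-suppressed skeleton), `"all-h"`
#' (every hydrogen a pendant vertex), or the diagnostic `"polar-h"`
#' (only heteroatom-bound hydrogens attached; see
#' [polarHydrogenGraph()]).  Vertex labels are informational element
#' symbols; vertices labelled `"H"` must be pendant (degree one).
#'
#' @slot n vertex count.
#' @slot edges two-column integer matrix of vertex pairs.
#' @slot mode one of `"heavy"`, `"all-h"`, `"polar-h"`.
#' @slot vertexLabels element symbol per vertex.
#'
#' @seealso [buildGraph()], [shortestPathMatrix()], [detourMatrix()]
#' @export
setClass("MolecularGraph",
  representation(
    n            = "integer",
    edges        = "matrix",
    mode         = "character",
    vertexLabels = "character"
  )
)

setValidity("MolecularGraph", function(object) {
  n <- object@n
  e <- object@edges
  if (!object@mode %in% c("heavy", "all-h", "polar-h"))
    return("mode must be 'heavy', 'all-h' or 'polar-h'")
  if (length(object@vertexLabels) != n)
    return("vertexLabels must have one entry per vertex")
  if (ncol(e) != 2)
    return("edges must be a two-column matrix")
  if (n > 1 && nrow(e) == 0)
    return("a multi-vertex graph must have edges")
  if (nrow(e) > 0) {
    if (any(e < 1) || any(e > n)) return("edge indices out of range")
    if (any(e[, 1] == e[, 2])) return("self-loops are not allowed")
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    if (anyDuplicated(key)) return("parallel edges are not allowed")
  }
  if (n > 1) {
    g <- igraph::graph_from_edgelist(e, directed = FALSE)
    if (igraph::vcount(g) < n || igraph::components(g)$no != 1)
      return("graph is disconnected")
    deg <- tabulate(as.vector(e), nbins = n)
    if (any(object@vertexLabels == "H" & deg != 1))
      return("hydrogen vertices must have degree exactly 1")
  }
  TRUE
})

#' PairMatrices: all-pairs shortest-path and detour distances
#'
#' Both matrices are symmetric with zero diagonal and integer edge-count
#' entries; detour distances dominate shortest-path distances, with
#' equality on every pair exactly when the graph is a tree.
#'
#' @slot d shortest-path distance matrix.
#' @slot D detour (longest simple path) distance matrix.
#'
#' @seealso [pairMatrices()], [indexVector()]
#' @export
setClass("PairMatrices",
  representation(d = "matrix", D = "matrix")
)

setValidity("PairMatrices", function(object) {
  d <- object@d; D <- object@D
  if (!all(dim(d) == dim(D)) || nrow(d) != ncol(d))
    return("d and D must be square matrices of equal dimension")
  for (m in list(d, D)) {
    if (any(diag(m) != 0)) return("diagonals must be zero")
    if (any(m != t(m))) return("matrices must be symmetric")
    if (nrow(m) > 1 && any(m[upper.tri(m)] < 1))
      return("off-diagonal distances must be at least 1")
    if (any(m != round(m))) return("distances must be integer edge counts")
  }
  if (any(D < d)) return("detour distances must dominate shortest-path distances")
  TRUE
})

setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule: %s (%s)\n", object@name, object@abbreviation))
  cat(sprintf("  SMILES: %s\n", object@smiles))
  cat(sprintf("  %d heavy atoms, %d bonds, %d implicit hydrogens [%s]\n",
              length(object@elements), nrow(object@bonds),
              sum(object@hydrogens), molecularFormula(object)))
  invisible(object)
})

setMethod("show", "MolecularGraph", function(object) {
  cat(sprintf("MolecularGraph (%s): %d vertices, %d edges, cyclomatic number %d\n",
              object@mode, object@n, nrow(object@edges),
              nrow(object@edges) - object@n + 1L))
  invisible(object)
})

setMethod("show", "PairMatrices", function(object) {
  n <- nrow(object@d)
  cat(sprintf("PairMatrices: %d vertices\n", n))
  if (n > 1) {
    ut <- upper.tri(object@d)
    cat(sprintf("  d in [%d, %d]; D in [%d, %d]; tree-like: %s\n",
                min(object@d[ut]), max(object@d[ut]),
                min(object@D[ut]), max(object@D[ut]),
                all(object@d == object@D)))
  }
  invisible(object)
})
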