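## Molecule -> MolecularGraph under a hydrogen representation.

.appendPendants <- function(elements, bonds, hyd, keep) {
  ## attach `hyd[i]` pendant "H" vertices to heavy atom i where keep[i]
  n <- length(elements)
  extra <- sum(hyd[keep])
  labels <- c(elements, rep("H", extra))
  if (extra > 0) {
    at <- rep(seq_len(n)[keep], hyd[keep])
    newIdx <- n + seq_len(extra)
    bonds <- rbind(bonds, cbind(at, newIdx))
  }
  list(n = n + extra, edges = bonds, labels = labels)
}

#' Build the molecular graph of a molecule under a hydrogen mode
#'
#' `mode = "heavy"` yields the H-suppressed skeleton: vertices are heavy
#' atoms, one edge per chemical bond (bond orders and aromaticity are
#' ignored).  `mode = "all-h"` additionally attaches every implicit
#' hydrogen as a pendant vertex, so the vertex count grows by the total
#' hydrogen count and every hydrogen vertex has degree one.
#'
#' @param mol a [Molecule-class] object.
#' @param mode `"heavy"` or `"all-h"`.
#' @return a [MolecularGraph-class] object.
#' @examples
#' \dontrun{
#' eth <- parseSmiles("CC", "ethane")
#' buildGraph(eth, "heavy")   # 2 vertices, 1 edge
#' buildGraph(eth, "all-h")   # 8 vertices, 7 edges (a tree)
#' }
#' @export
buildGraph <- function(mol, mode = c("heavy", "all-h")) {
  stopifnot(is(mol, "Molecule"))
  mode <- match.arg(mode)
  if (mode == "heavy") {
    parts <- list(n = length(mol@elements), edges = mol@bonds,
                  labels = mol@elements)
  } else {
    parts <- .appendPendants(mol@elements, mol@bonds, mol@hydrogens,
                             rep(TRUE, length(mol@elements)))
  }
  new("MolecularGraph", n = as.integer(parts$n),
      edges = .canonEdges(parts$edges), mode = mode,
      vertexLabels = parts$labels)
}

#' Diagnostic graph with heteroatom-bound hydrogens attached
#'
#' Builds the skeleton plus one pendant vertex per hydrogen carried by a
#' non-carbon atom (the O-H/N-H hydrogens that skeletal structure drawings
#' show explicitly).  This construction is not one of the two hydrogen
#' modes of the index pipeline; it exists because it reproduces several
#' published reference rows that the plain skeleton does not, and it is
#' what [discrepancyReport()] uses to classify those rows.
#'
#' @param mol a [Molecule-class] object.
#' @return a [MolecularGraph-class] object with mode `"polar-h"`.
#' @seealso [discrepancyReport()]
#' @export
polarHydrogenGraph <- function(mol) {
  stopifnot(is(mol, "Molecule"))
  parts <- .appendPendants(mol@elements, mol@bonds, mol@hydrogens,
                           mol@elements != "C")
  new("MolecularGraph", n = as.integer(parts$n),
      edges = .canonEdges(parts$edges), mode = "polar-h",
      vertexLabels = parts$labels)
}

## store edges as (min, max) integer pairs
.canonEdges <- function(e) {
  e <- matrix(as.integer(e), ncol = 2)
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Accessors for MolecularGraph
#'
#' `vertexCount()`, `edgeCount()`, `hydrogenMode()` and `vertexLabels()`
#' expose the slots of a [MolecularGraph-class] without direct slot access.
#'
#' @param x a [MolecularGraph-class] object.
#' @name graphAccessors
#' @aliases vertexCount edgeCount hydrogenMode vertexLabels
NULL

#' @rdname graphAccessors
#' @export
setGeneric("vertexCount", function(x) standardGeneric("vertexCount"))

#' @rdname graphAccessors
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' @rdname graphAccessors
#' @export
setGeneric("hydrogenMode", function(x) standardGeneric("hydrogenMode"))

#' @rdname graphAccessors
#' @export
setGeneric("vertexLabels", function(x) standardGeneric("vertexLabels"))

#' @rdname graphAccessors
#' @export
setMethod("vertexCount", "MolecularGraph", function(x) x@n)

#' @rdname graphAccessors
#' @export
setMethod("edgeCount", "MolecularGraph", function(x) nrow(x@edges))

#' @rdname graphAccessors
#' @export
setMethod("hydrogenMode", "MolecularGraph", function(x) x@mode)

#' @rdname graphAccessors
#' @export
setMethod("vertexLabels", "MolecularGraph", function(x) x@vertexLabels)

## MolecularGraph -> igraph
.asIgraph <- function(g) {
  ig <- igraph::make_empty_graph(n = g@n, directed = FALSE)
  if (nrow(g@edges) > 0)
    ig <- igraph::add_edges(ig, as.vector(t(g@edges)))
  ig
}
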