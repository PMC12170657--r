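## The five distance-based topological indices.  All are sums over
## unordered vertex pairs of functions of the shortest-path distance d or
## the detour distance D:
##   W  = sum d          (Wiener)
##   WW = sum (d + d^2)/2 (hyper-Wiener)
##   H  = sum 1/d        (Harary)
##   D  = sum D          (detour index)
##   DH = sum 1/D        (detour-Harary)
## Internal arithmetic is full precision; rounding to 4 decimals happens
## only at serialization.

.checkDistMatrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    .stopf("tcaQSPR_config_error", "expected a square distance matrix")
  if (any(diag(m) != 0) || any(m != t(m)))
    .stopf("tcaQSPR_config_error",
           "distance matrix must be symmetric with zero diagonal")
  if (nrow(m) > 1 && any(m[upper.tri(m)] < 1))
    .stopf("tcaQSPR_config_error",
           "off-diagonal distances must be positive")
  invisible(m)
}

.upper <- function(m) m[upper.tri(m)]

#' Wiener index: sum of shortest-path distances over unordered pairs
#' @param d shortest-path distance matrix (symmetric, zero diagonal).
#' @return a single number.
#' @export
wienerIndex <- function(d) {
  .checkDistMatrix(d)
  sum(.upper(d))
}

#' Hyper-Wiener index: half-sum of d + d^2 over unordered pairs
#' @inheritParams wienerIndex
#' @return a single number.
#' @export
hyperWienerIndex <- function(d) {
  .checkDistMatrix(d)
  u <- .upper(d)
  sum(u + u^2) / 2
}

#' Harary index: sum of reciprocal shortest-path distances
#' @inheritParams wienerIndex
#' @return a single number.
#' @export
hararyIndex <- function(d) {
  .checkDistMatrix(d)
  sum(1 / .upper(d))
}

#' Detour index: sum of detour distances over unordered pairs
#' @param D detour (longest simple path) distance matrix.
#' @return a single number.
#' @export
detourIndex <- function(D) {
  .checkDistMatrix(D)
  sum(.upper(D))
}

#' Detour-Harary index: sum of reciprocal detour distances
#' @inheritParams detourIndex
#' @return a single number.
#' @export
detourHararyIndex <- function(D) {
  .checkDistMatrix(D)
  sum(1 / .upper(D))
}

#' The five topological indices of a graph
#'
#' Computes (W, WW, H, D, DH) from a [MolecularGraph-class] or from
#' precomputed [PairMatrices-class].
#'
#' @param x a [MolecularGraph-class] or [PairMatrices-class] object.
#' @param ... passed to [pairMatrices()] (e.g. `budget`) for the graph
#'   method.
#' @return a named numeric vector with elements `W`, `WW`, `H`, `D`, `DH`.
#' @export
setGeneric("indexVector", function(x, ...) standardGeneric("indexVector"))

#' @rdname indexVector
#' @export
setMethod("indexVector", "PairMatrices", function(x, ...) {
  c(W  = wienerIndex(x@d),
    WW = hyperWienerIndex(x@d),
    H  = hararyIndex(x@d),
    D  = detourIndex(x@D),
    DH = detourHararyIndex(x@D))
})

#' @rdname indexVector
#' @export
setMethod("indexVector", "MolecularGraph", function(x, ...) {
  indexVector(pairMatrices(x, ...))
})

#' Index table for a set of molecules under one hydrogen mode
#'
#' One row per molecule in the reference column order
#' (`drug, W, WW, H, D, DH`); deterministic and CSV-serializable.
#'
#' @param molecules a list of [Molecule-class] objects (default: the
#'   fifteen fixture drugs via [loadMolecules()]).
#' @param mode hydrogen mode, `"heavy"` or `"all-h"`.
#' @param budget per-block detour search budget, see [detourMatrix()].
#' @return a data.frame with columns `drug, W, WW, H, D, DH`.
#' @examples
#' \dontrun{
#' tab <- computeIndexTable(mode = "all-h")
#' tab[tab$drug == "OZP", ]   # 2142 7027 139.4702 5038 62.4229
#' }
#' @export
computeIndexTable <- function(molecules = loadMolecules(),
                              mode = c("heavy", "all-h"),
                              budget = 1e7) {
  mode <- match.arg(mode)
  stopifnot(length(molecules) > 0,
            all(vapply(molecules, is, logical(1), "Molecule")))
  rows <- lapply(molecules, function(m) {
    iv <- indexVector(buildGraph(m, mode), budget = budget)
    data.frame(drug = m@abbreviation, W = iv[["W"]], WW = iv[["WW"]],
               H = iv[["H"]], D = iv[["D"]], DH = iv[["DH"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
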