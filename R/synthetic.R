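## Synthetic molecule-like graphs and property vectors with known
## structure, so every pipeline stage is testable offline.

#' Random connected molecule-like graph
#'
#' Builds a random spanning tree (each new vertex attaches to a uniformly
#' chosen earlier vertex) and adds extra edges up to a requested
#' cyclomatic number, giving sparse connected simple graphs in the regime
#' of heavy-atom molecular skeletons.  Optionally augments each core
#' vertex with a pendant degree-1 vertex (labelled `"H"`) with probability
#' `pendantProb`, emulating the all-hydrogen representation.
#'
#' @param nVertices range (length-2 vector or scalar) for the number of
#'   core vertices.
#' @param cyclomatic range (length-2 vector or scalar) for the cyclomatic
#'   number, i.e. edges - vertices + 1.
#' @param pendantProb per-core-vertex probability of attaching a pendant.
#' @param seed integer seed; identical seeds give identical graphs.
#' @return a [MolecularGraph-class] object.
#' @examples
#' \dontrun{
#' g <- randomMolGraph(nVertices = 10, cyclomatic = 0, seed = 1)
#' edgeCount(g) == vertexCount(g) - 1   # a tree
#' }
#' @export
randomMolGraph <- function(nVertices = c(20, 30), cyclomatic = c(1, 4),
                           pendantProb = 0, seed = NULL) {
  nVertices <- round(range(nVertices))
  cyclomatic <- round(range(cyclomatic))
  if (nVertices[1] < 2)
    .stopf("tcaQSPR_config_error", "need at least 2 vertices")
  if (cyclomatic[1] < 0)
    .stopf("tcaQSPR_config_error", "cyclomatic number cannot be negative")
  if (pendantProb < 0 || pendantProb > 1)
    .stopf("tcaQSPR_config_error", "pendantProb must be in [0, 1]")
  .withSeed(seed, {
    n <- if (nVertices[1] == nVertices[2]) nVertices[1] else
      sample(nVertices[1]:nVertices[2], 1)
    ## the cyclomatic range adapts to the drawn vertex count, but the
    ## lower bound must always be achievable
    maxExtra <- n * (n - 1) / 2 - (n - 1)
    if (cyclomatic[1] > maxExtra)
      .stopf("tcaQSPR_config_error",
             "cyclomatic number %d infeasible for %d vertices",
             cyclomatic[1], n)
    hi <- min(cyclomatic[2], maxExtra)
    cyc <- if (cyclomatic[1] == hi) cyclomatic[1] else
      sample(cyclomatic[1]:hi, 1)
    ## random recursive spanning tree
    edges <- cbind(vapply(2:n, function(v) sample.int(v - 1L, 1), integer(1)),
                   2:n)
    if (cyc > 0) {
      all <- t(utils::combn(n, 2))
      key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
      free <- which(!(paste(all[, 1], all[, 2]) %in% key))
      pick <- free[sample.int(length(free), cyc)]
      edges <- rbind(edges, all[pick, , drop = FALSE])
    }
    labels <- rep("C", n)
    if (pendantProb > 0) {
      host <- which(stats::runif(n) < pendantProb)
      if (length(host) > 0) {
        newIdx <- n + seq_along(host)
        edges <- rbind(edges, cbind(host, newIdx))
        labels <- c(labels, rep("H", length(host)))
        n <- n + length(host)
      }
    }
    new("MolecularGraph", n = as.integer(n), edges = .canonEdges(edges),
        mode = if (any(labels == "H")) "all-h" else "heavy",
        vertexLabels = labels)
  })
}

#' Synthetic property vector from an index column
#'
#' Generates `property = law(index) + Gaussian noise`.  The linear law is
#' `intercept + slope * index`; the nonlinear law is a monotone
#' exponential ramp `intercept + slope * exp(rate * z)` where `z` is the
#' index rescaled to [0, 1].  With `noiseSd = 0` the generating law is
#' exactly recoverable.  Noise is homoscedastic Gaussian, the implicit
#' assumption of R^2/RMSE model evaluation.
#'
#' @param x numeric index values.
#' @param law `"linear"` or `"nonlinear"`.
#' @param intercept,slope law parameters.
#' @param rate curvature of the nonlinear ramp (ignored for linear).
#' @param noiseSd standard deviation of the additive Gaussian noise.
#' @param seed integer seed for the noise draw.
#' @return numeric vector of property values with the generating
#'   configuration attached as attribute `"config"`.
#' @export
synthProperties <- function(x, law = c("linear", "nonlinear"),
                            intercept = 300, slope = 0.5, rate = 3,
                            noiseSd = 0, seed = NULL) {
  law <- match.arg(law)
  if (length(x) == 0)
    .stopf("tcaQSPR_config_error", "index column is empty")
  if (noiseSd < 0)
    .stopf("tcaQSPR_config_error", "noiseSd cannot be negative")
  mu <- if (law == "linear") {
    intercept + slope * x
  } else {
    if (max(x) == min(x))
      .stopf("tcaQSPR_degenerate_error",
             "nonlinear law needs a non-constant index column")
    z <- (x - min(x)) / (max(x) - min(x))
    intercept + slope * exp(rate * z)
  }
  y <- .withSeed(seed, mu + stats::rnorm(length(x), 0, noiseSd))
  attr(y, "config") <- list(law = law, intercept = intercept, slope = slope,
                            rate = rate, noiseSd = noiseSd, seed = seed)
  y
}
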