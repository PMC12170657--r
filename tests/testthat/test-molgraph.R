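# SMILES parsing, graph construction under the two hydrogen modes, and
# the distance/detour matrix machinery.

test_that("parseSmiles recovers heavy-atom connectivity and implicit hydrogens", {
  methane <- parseSmiles("C", "methane")
  expect_length(methane@elements, 1)
  expect_equal(sum(methane@hydrogens), 4)
  expect_equal(nrow(methane@bonds), 0)
  expect_equal(molecularFormula(methane), "CH4")

  ethane <- parseSmiles("CC", "ethane")
  expect_length(ethane@elements, 2)
  expect_equal(nrow(ethane@bonds), 1)
  expect_equal(sum(ethane@hydrogens), 6)

  dzm <- parseSmiles("CN1c2ccc(Cl)cc2C(=NCC1=O)c1ccccc1", "diazepam", "DZM")
  expect_length(dzm@elements, 20)
  expect_equal(sum(dzm@hydrogens), 13)
  expect_equal(molecularFormula(dzm), "C16H13ClN2O")
})

test_that("parseSmiles rejects bad input with informative classed errors", {
  expect_error(parseSmiles("C1CC", "openring"),
               class = "tcaQSPR_parse_error")
  expect_error(parseSmiles("not a smiles !!", "junk"),
               class = "tcaQSPR_parse_error")
  err <- tryCatch(parseSmiles("C1CC", "openring"), error = identity)
  expect_match(conditionMessage(err), "C1CC", fixed = TRUE)
  # disconnected output is a structural error, not a parse error
  expect_error(parseSmiles("C.C", "saltpair"),
               class = "tcaQSPR_structural_error")
})

test_that("buildGraph realises the two hydrogen modes", {
  eth <- parseSmiles("CC", "ethane")
  gh <- buildGraph(eth, "heavy")
  ga <- buildGraph(eth, "all-h")
  expect_equal(vertexCount(gh), 2)
  expect_equal(edgeCount(gh), 1)
  expect_equal(vertexCount(ga), 8)
  expect_equal(edgeCount(ga), 7)
  # pendant hydrogens have degree one and the edge count grows by the
  # hydrogen count
  expect_equal(edgeCount(ga), edgeCount(gh) + sum(eth@hydrogens))
  deg <- tabulate(as.vector(ga@edges), vertexCount(ga))
  expect_true(all(deg[vertexLabels(ga) == "H"] == 1))

  dzm <- parseSmiles("CN1c2ccc(Cl)cc2C(=NCC1=O)c1ccccc1", "diazepam")
  expect_equal(vertexCount(buildGraph(dzm, "all-h")), 33)  # 20 heavy + 13 H
  expect_equal(hydrogenMode(buildGraph(dzm, "heavy")), "heavy")
})

test_that("shortest-path matrix equals BFS expectations and a powering oracle", {
  p4 <- shortestPathMatrix(pathGraph(4))
  expect_equal(p4[1, 4], 3L)
  c6 <- shortestPathMatrix(cycleGraph(6))
  expect_equal(max(c6), 3L)
  expect_true(all(diag(c6) == 0) && isSymmetric(c6))

  for (s in 1:25) {
    g <- randomMolGraph(nVertices = c(3, 10), cyclomatic = c(0, 3), seed = s)
    expect_identical(shortestPathMatrix(g), oracleShortestPaths(g))
  }
})

test_that("detour matrix is exact on trees, cycles and random graphs", {
  # trees: unique paths, so detour == distance
  tr <- randomMolGraph(nVertices = 9, cyclomatic = 0, seed = 3)
  expect_identical(detourMatrix(tr), shortestPathMatrix(tr))

  c4 <- cycleGraph(4)
  D4 <- detourMatrix(c4)
  expect_equal(D4[1, 2], 3L)        # adjacent vertices detour the long way
  # on a cycle, D(a,b) = n - d(a,b)
  c7 <- cycleGraph(7)
  d7 <- shortestPathMatrix(c7); D7 <- detourMatrix(c7)
  off <- upper.tri(d7)
  expect_true(all(D7[off] == 7 - d7[off]))

  for (s in 26:65) {
    g <- randomMolGraph(nVertices = c(4, 12), cyclomatic = c(0, 3), seed = s)
    expect_identical(detourMatrix(g), oracleDetour(g))
  }
})

test_that("detour dominates distance, with equality exactly on trees", {
  for (s in 1:10) {
    g <- randomMolGraph(nVertices = c(5, 12), cyclomatic = c(0, 3), seed = 100 + s)
    pm <- pairMatrices(g)
    d <- distanceMatrix(pm); D <- detourDistances(pm)
    expect_true(all(D >= d))
    isTree <- edgeCount(g) == vertexCount(g) - 1
    expect_identical(all(D == d), isTree)
  }
})

test_that("distance multisets are invariant under vertex relabeling", {
  g <- randomMolGraph(nVertices = 10, cyclomatic = 2, seed = 77)
  perm <- sample(vertexCount(g))
  relab <- mkGraph(vertexCount(g),
                   t(apply(g@edges, 1, function(e) perm[e])))
  expect_equal(distMultiset(shortestPathMatrix(g)),
               distMultiset(shortestPathMatrix(relab)))
  expect_equal(distMultiset(detourMatrix(g)),
               distMultiset(detourMatrix(relab)))
})

test_that("the per-block search budget raises an explicit resource error", {
  g <- cycleGraph(12)
  expect_error(detourMatrix(g, budget = 5),
               class = "tcaQSPR_resource_error")
})

test_that("pair matrices of substitution-isomorphic drugs coincide", {
  # lorazepam is oxazepam with one ring hydrogen replaced by chlorine:
  # their all-hydrogen graphs are isomorphic
  mols <- fixtureMolecules()
  lrz <- pairMatrices(buildGraph(mols$LRZ, "all-h"))
  ozp <- pairMatrices(buildGraph(mols$OZP, "all-h"))
  expect_equal(distMultiset(distanceMatrix(lrz)),
               distMultiset(distanceMatrix(ozp)))
  expect_equal(distMultiset(detourDistances(lrz)),
               distMultiset(detourDistances(ozp)))
})
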