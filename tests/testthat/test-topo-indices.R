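# The five distance-based indices and the per-mode index tables.

test_that("index formulas match closed-form values on small graphs", {
  dP4 <- shortestPathMatrix(pathGraph(4))
  expect_equal(wienerIndex(dP4), 10)          # 3*1 + 2*2 + 1*3
  expect_equal(hyperWienerIndex(dP4), 15)

  dK2 <- shortestPathMatrix(mkGraph(2, c(1, 2)))
  expect_equal(hyperWienerIndex(dK2), 1)
  expect_equal(hararyIndex(dK2), 1)

  dP3 <- shortestPathMatrix(pathGraph(3))
  expect_equal(hararyIndex(dP3), 2.5)

  c6 <- cycleGraph(6)
  expect_equal(wienerIndex(shortestPathMatrix(c6)), 27)   # n^3/8 for even n
  expect_equal(detourIndex(detourMatrix(c6)), 63)
  expect_equal(detourHararyIndex(detourMatrix(c6)), 3.7)  # 6/5 + 6/4 + 3/3
})

test_that("detour-based indices collapse to distance-based ones on trees", {
  g <- randomMolGraph(nVertices = 11, cyclomatic = 0, seed = 5)
  iv <- indexVector(g)
  expect_equal(iv[["D"]], iv[["W"]])
  expect_equal(iv[["DH"]], iv[["H"]])
})

test_that("index inequalities hold and pendant growth is strict", {
  for (s in 1:8) {
    g <- randomMolGraph(nVertices = c(6, 12), cyclomatic = c(1, 3),
                        seed = 300 + s)
    iv <- indexVector(g)
    expect_true(all(iv > 0))
    expect_gte(iv[["D"]], iv[["W"]])   # detour distances dominate
    expect_lte(iv[["DH"]], iv[["H"]])  # so reciprocal sums are dominated
    expect_gte(iv[["WW"]], iv[["W"]])

    # adding a pendant vertex strictly increases every index
    n <- vertexCount(g)
    g2 <- mkGraph(n + 1, rbind(g@edges, c(1L, n + 1L)))
    iv2 <- indexVector(g2)
    expect_true(all(iv2 > iv))
  }
  # WW == W exactly when all distances are 1 (complete graph)
  k3 <- mkGraph(3, c(1, 2, 2, 3, 1, 3))
  ivK <- indexVector(k3)
  expect_equal(ivK[["WW"]], ivK[["W"]])
})

test_that("the fixture index tables have the reference layout and rows", {
  th <- fixtureIndexTable("heavy")
  ta <- fixtureIndexTable("all-h")
  expect_equal(names(th), c("drug", "W", "WW", "H", "D", "DH"))
  expect_equal(nrow(th), 15)
  expect_equal(th$W[th$drug == "IMP"], 882)

  dzm <- unlist(th[th$drug == "DZM", -1])
  expect_equal(unname(dzm), c(726, 2077, 69.4905, 1901, 24.9069),
               tolerance = 1e-6)

  ozp <- unlist(ta[ta$drug == "OZP", -1])
  expect_equal(unname(ozp), c(2142, 7027, 139.4702, 5038, 62.4229),
               tolerance = 1e-6)
  expect_equal(unlist(ta[ta$drug == "LRZ", -1]), unlist(ta[ta$drug == "OZP", -1]))
})

test_that("malformed distance matrices are rejected", {
  m <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(wienerIndex(m), class = "tcaQSPR_config_error")
  m2 <- diag(2)
  expect_error(hararyIndex(m2), class = "tcaQSPR_config_error")
})
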