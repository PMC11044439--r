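makeAnnotatedModule <- function(nFeatures = 6, seed = 31) {
  m <- randomOmics(nFeatures + 4, 15, seed = seed)
  asg <- setNames(c(rep("ME1", nFeatures), rep("ME0", 4)), featureIds(m))
  net <- computeTOM(buildNetwork(m, beta = 2))
  ms <- computeEigengenes(m, asg, network = net)
  list(m = m, ms = ms, feats = featureIds(m)[1:nFeatures])
}

test_that("buildEdgeTermMap builds canonical edges with intersection terms", {
  fx <- makeAnnotatedModule(5)
  gs <- GeneSets(c("TA", "TB"),
                 list(c("g1", "g2", "g3"), c("g2", "g3", "g4", "g9")))
  etm <- buildEdgeTermMap(fx$ms, "ME1", gs)
  expect_identical(nrow(etm@edges), 10L)
  expect_true(all(etm@edges$feature1 < etm@edges$feature2))
  tom <- tomMatrix(fx$ms@network)
  for (i in seq_len(nrow(etm@edges)))
    expect_equal(etm@edges$weight[i],
                 tom[etm@edges$feature1[i], etm@edges$feature2[i]])
  # TA edges: pairs within {g1,g2,g3}; TB within {g2,g3,g4} (g9 not in
  # the module); g5 edges carry nothing
  edgeKey <- paste(etm@edges$feature1, etm@edges$feature2)
  expect_setequal(edgeKey[etm@termEdges$TA], c("g1 g2", "g1 g3", "g2 g3"))
  expect_setequal(edgeKey[etm@termEdges$TB], c("g2 g3", "g2 g4", "g3 g4"))

  etmA <- buildEdgeTermMap(fx$ms, "ME1", gs, weightSource = "adjacency",
                           minWeight = 0.2)
  adj <- adjacencyMatrix(fx$ms@network)
  expect_true(all(etmA@edges$weight >= 0.2))
  expect_identical(nrow(etmA@edges),
                   sum(adj[fx$feats, fx$feats][upper.tri(adj[fx$feats,
                                                             fx$feats])] >= 0.2))
})

test_that("edgeShuffleTest: valid p range, determinism, full-coverage p = 1", {
  fx <- makeAnnotatedModule(6)
  gs <- GeneSets(c("Tall", "Tsub"),
                 list(paste0("g", 1:6), c("g1", "g2")))
  etm <- buildEdgeTermMap(fx$ms, "ME1", gs)
  r1 <- edgeShuffleTest(etm, nShuffle = 300, seed = 4)
  r2 <- edgeShuffleTest(etm, nShuffle = 300, seed = 4)
  expect_identical(r1, r2)
  expect_true(all(r1$p >= 1 / 301 & r1$p <= 1))
  # a term covering every edge has permutation-invariant weight
  expect_equal(r1$p[r1$term == "Tall"], 1)
  expect_equal(r1$pAdj, p.adjust(r1$p, "BH"))
})

test_that("edgeHypergeomTest matches a direct phyper computation", {
  fx <- makeAnnotatedModule(5)
  gs <- GeneSets(c("TA", "TB"), list(c("g1", "g2", "g3"), c("g4", "g5")))
  etm <- buildEdgeTermMap(fx$ms, "ME1", gs)
  res <- edgeHypergeomTest(etm, etm)  # module as its own background
  for (i in seq_len(nrow(res))) {
    expect_equal(res$p[i],
                 phyper(res$k[i] - 1, res$K[i], res$N[i] - res$K[i],
                        res$n[i], lower.tail = FALSE))
    expect_equal(res$k[i], res$K[i])  # self-background
  }
  small <- new("EdgeTermMap", edges = etm@edges[1:2, ],
               termEdges = list(TA = 1L), moduleLabel = "x")
  expect_error(edgeHypergeomTest(etm, small), "fewer edges")
})

test_that("geneHypergeomEnrich agrees with exact combinatorics", {
  universe <- paste0("g", 1:20)
  gs <- GeneSets("T1", list(paste0("g", 1:6)))
  genes <- c("g1", "g2", "g3", "g10")
  res <- geneHypergeomEnrich(genes, universe, gs)
  # P(X >= 3), X ~ Hypergeom(K = 6, N - K = 14, n = 4)
  exact <- sum(vapply(3:4, function(k)
    choose(6, k) * choose(14, 4 - k), 0)) / choose(20, 4)
  expect_equal(res$p, exact, tolerance = 1e-12)
  expect_error(geneHypergeomEnrich(c("g1", "zz"), universe, gs),
               "subset of universe")
  expect_error(geneHypergeomEnrich(character(0), universe, gs), "empty")
})
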