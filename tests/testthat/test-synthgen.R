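test_that("simulateModularExpression plants the requested correlation", {
  sim <- simulateModularExpression(400, data.frame(size = c(25, 15),
                                                   rho = c(0.7, 0.3)),
                                   nBackground = 10, seed = 51)
  v <- assayValues(sim$matrix)
  expect_identical(dim(v), c(50L, 400L))
  expect_identical(as.vector(table(sim$truth)[c("ME1", "ME2", "ME0")]),
                   c(25L, 15L, 10L))
  c1 <- cor(t(v[grepl("^blk1", rownames(v)), ]))
  expect_equal(mean(c1[upper.tri(c1)]), 0.7, tolerance = 0.05)
  c2 <- cor(t(v[grepl("^blk2", rownames(v)), ]))
  expect_lt(abs(mean(c2[upper.tri(c2)]) - 0.3), 0.08)
  cb <- cor(t(v[grepl("^bg", rownames(v)), ]))
  expect_lt(max(abs(cb[upper.tri(cb)])), 0.25)
  expect_identical(assayValues(simulateModularExpression(
    400, data.frame(size = 25, rho = 0.7), seed = 51)$matrix)[1, 1],
    v[1, 1])
})

test_that("simulateMediationScenario: shape, roles, prevalence, confounding", {
  sim <- simulateMediationScenario(seed = 52)
  v <- assayValues(sim$matrix)
  expect_identical(dim(v), c(51L, 300L))
  expect_identical(as.vector(table(sim$truth$role)[c("driver", "passenger",
                                                  "null")]),
                   c(1L, 20L, 30L))
  g <- responseValues(sim$phenotypes)
  expect_identical(levels(g), c("case", "ctrl"))
  expect_equal(mean(g == "case"), 0.4, tolerance = 0.1)
  expect_identical(sim$phenotypes@confounders, "conf")
  # confounder really shifts features
  cf <- confounderFrame(sim$phenotypes)$conf
  shifts <- rowMeans(v[, cf == "c1", drop = FALSE]) -
    rowMeans(v[, cf == "c0", drop = FALSE])
  expect_gt(mean(shifts), 0.15)
  # determinism
  sim2 <- simulateMediationScenario(seed = 52)
  expect_identical(v, assayValues(sim2$matrix))
  # module labels cover the module features only
  expect_identical(unname(sim$moduleLabels[sim$truth$role != "background"]),
                   rep("ME1", 51))
})

test_that("simulateMultiomicsClusters shares the partition across omics", {
  sim <- simulateMultiomicsClusters(clusterSizes = c(30, 20), seed = 53)
  expect_identical(as.vector(table(sim$truth)), c(30L, 20L))
  expect_identical(names(sim$omics), c("RNA", "DNAm"))
  for (om in sim$omics)
    expect_identical(sampleIds(om), names(sim$truth))
})

test_that("simulateImbalancedClasses has the requested sizes and separation", {
  sim <- simulateImbalancedClasses(classSizes = c(100, 10), nFeatures = 40,
                                   nInformative = 5, classSep = 2, seed = 54)
  expect_identical(as.vector(table(sim$labels)), c(100L, 10L))
  v <- assayValues(sim$matrix)
  d <- rowMeans(v[1:5, sim$labels == "class2", drop = FALSE]) -
    rowMeans(v[1:5, sim$labels == "class1", drop = FALSE])
  expect_equal(mean(d), 2, tolerance = 0.5)
  dNull <- rowMeans(v[6:40, sim$labels == "class2", drop = FALSE]) -
    rowMeans(v[6:40, sim$labels == "class1", drop = FALSE])
  expect_lt(abs(mean(dNull)), 0.3)
})
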