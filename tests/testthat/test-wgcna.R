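test_that("buildNetwork produces a valid adjacency with the right formula", {
  m <- randomOmics(15, 12, seed = 3)
  cc <- cor(t(assayValues(m)))

  net <- buildNetwork(m, beta = 4)
  a <- adjacencyMatrix(net)
  expect_equal(a[2, 7], abs(cc[2, 7])^4, tolerance = 1e-12)
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(diag(a), setNames(rep(1, 15), featureIds(m)))
  expect_equal(a, t(a))

  nets <- buildNetwork(m, beta = 4, signed = TRUE)
  expect_equal(adjacencyMatrix(nets)[3, 9], ((1 + cc[3, 9]) / 2)^4,
               tolerance = 1e-12)

  x <- assayValues(m); x[1, ] <- 5
  expect_error(buildNetwork(OmicsMatrix(x)), "constant")
})

test_that("computeTOM matches the brute-force definition", {
  m <- randomOmics(10, 14, seed = 4)
  net <- computeTOM(buildNetwork(m, beta = 5))
  expect_lt(max(abs(tomMatrix(net) - bruteTOM(adjacencyMatrix(net)))),
            1e-12)
  expect_true(all(tomMatrix(net) >= 0 & tomMatrix(net) <= 1 + 1e-12))
})

test_that("scaleFreeFit conventions and pickSoftPower selection", {
  sim <- simulateModularExpression(80, data.frame(size = c(30, 15, 8, 4),
                                                  rho = c(0.5, 0.65,
                                                          0.8, 0.9)),
                                   nBackground = 250, seed = 7)
  sf <- scaleFreeFit(sim$matrix, beta = 6)
  expect_true(sf$rSquared >= 0 && sf$rSquared <= 1)
  expect_gt(sf$meanConnectivity, 0)

  # selection contract: smallest candidate whose fit reaches the cut
  p <- pickSoftPower(sim$matrix, candidates = 1:12, r2Cut = 0.3)
  r2 <- attr(p, "rSquared")
  expect_length(r2, 12)
  expect_gte(r2[p], 0.3)
  expect_identical(which(r2 >= 0.3)[1L], which(1:12 == p))
  # the chosen candidate's value agrees with scaleFreeFit directly
  # (the search stops at the first hit, so later entries stay 0)
  expect_equal(unname(r2[which(1:12 == p)]),
               scaleFreeFit(sim$matrix, beta = p)$rSquared,
               tolerance = 1e-12)
  expect_warning(pickSoftPower(sim$matrix, candidates = 1:2, r2Cut = 0.999),
                 "best-fitting")

  expect_error(scaleFreeFit(randomOmics(10, 10)), "at least 20 features")
})

test_that("detectModules recovers planted blocks and labels by size", {
  sim <- simulateModularExpression(50, data.frame(size = c(45, 30),
                                                  rho = c(0.85, 0.85)),
                                   nBackground = 40, seed = 6)
  ms <- buildModules(sim$matrix, power = 6, minSize = 20)
  asg <- moduleAssignment(ms)
  expect_true(samePartition(asg[names(sim$truth)], sim$truth))
  # ME1 is the larger block
  expect_identical(sum(asg == "ME1") >= sum(asg == "ME2"), TRUE)
  expect_true(all(grepl("^blk1", names(asg)[asg == "ME1"])))
})

test_that("module labels are invariant to feature order", {
  sim <- simulateModularExpression(40, data.frame(size = c(35, 25),
                                                  rho = c(0.85, 0.85)),
                                   nBackground = 30, seed = 7)
  ms1 <- buildModules(sim$matrix, power = 6, minSize = 15)
  vals <- assayValues(sim$matrix)
  set.seed(1)
  perm <- sample(nrow(vals))
  ms2 <- buildModules(OmicsMatrix(vals[perm, , drop = FALSE]),
                      power = 6, minSize = 15)
  a1 <- moduleAssignment(ms1)
  a2 <- moduleAssignment(ms2)[names(a1)]
  expect_identical(a1, a2)
})

test_that("eigengenes are unit-variance, sign-aligned, SVD-consistent", {
  sim <- simulateModularExpression(30, data.frame(size = 25, rho = 0.8),
                                   seed = 8)
  labels <- sim$truth
  ms <- computeEigengenes(sim$matrix, labels)
  eg <- eigengenes(ms)["ME1", ]
  expect_equal(sd(eg), 1, tolerance = 1e-10)
  z <- medwgcna:::.standardizeRows(assayValues(sim$matrix))
  expect_gte(cor(eg, colMeans(z)), 0)
  ve <- varianceExplained(ms)[["ME1"]]
  sv <- svd(z)
  expect_equal(ve, sv$d[1]^2 / sum(sv$d^2), tolerance = 1e-10)
  expect_lt(min(sum((eg - sv$v[, 1] / sd(sv$v[, 1]))^2),
                sum((eg + sv$v[, 1] / sd(sv$v[, 1]))^2)), 1e-16)
})

test_that("computeEigengenes drops zero-variance features with a warning", {
  x <- matrix(rnorm(5 * 10), 5, 10,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  x[5, ] <- 2
  asg <- setNames(rep("ME1", 5), rownames(x))
  expect_warning(ms <- computeEigengenes(OmicsMatrix(x), asg),
                 "zero-variance")
  expect_identical(nrow(eigengenes(ms)), 1L)
})
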