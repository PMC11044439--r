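test_that("pairwiseCCA finds shared structure and clips correlations", {
  set.seed(41)
  n <- 60
  shared <- rnorm(n)
  a <- cbind(sapply(1:20, function(i) shared + rnorm(n, sd = 0.3)))
  b <- cbind(sapply(1:25, function(i) shared + rnorm(n, sd = 0.3)))
  cc <- pairwiseCCA(a, b, nCC = 5)
  expect_identical(ncol(cc$u), 5L)
  expect_true(all(diff(cc$correlations) <= 1e-10))
  expect_true(all(cc$correlations >= 0 & cc$correlations <= 1))
  expect_gt(cc$correlations[1], 0.9)
  expect_gt(abs(cor(cc$u[, 1], shared)), 0.9)
  expect_warning(pairwiseCCA(a[, 1:3], b, nCC = 5), "truncating")
})

test_that("multiccaMerge: single omic is PCA, output standardized", {
  m <- randomOmics(30, 25, seed = 42)
  mr <- multiccaMerge(list(m), nCC = 4)
  x <- mr@matrix
  expect_identical(dim(x), c(25L, 4L))
  expect_equal(unname(colMeans(x)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(apply(x, 2, sd)), rep(1, 4), tolerance = 1e-10)
  expect_identical(mr@provenance$method, "pca")
  # scores proportional to SVD scores up to sign
  z <- t(assayValues(scaleFeatures(m)))[sampleIds(m), ]
  sv <- svd(scale(z, center = TRUE, scale = FALSE))
  for (j in 1:4)
    expect_gt(abs(cor(x[, j], sv$u[, j])), 1 - 1e-8)
})

test_that("multiccaMerge and wgcnaMerge carry cluster structure", {
  sim <- simulateMultiomicsClusters(clusterSizes = c(40, 40, 40), seed = 43)
  mr <- multiccaMerge(sim$omics, nCC = 8)
  expect_identical(rownames(mr@matrix), paste0("s", 1:120))
  sel <- clusterSelectK(mr, kCandidates = 2:5, seed = 1)
  expect_identical(sel$chosenK, 3L)
  expect_true(samePartition(sel$labels, sim$truth))
  expect_identical(ncol(mr@matrix), 16L)
})

test_that("clusterSelectK validates candidates and returns indices", {
  m <- matrix(rnorm(40 * 3), 40, 3)
  expect_error(clusterSelectK(m, kCandidates = c(1, 2)), "kCandidates")
  sel <- clusterSelectK(m, kCandidates = 2:3, seed = 2)
  expect_identical(sel$indices$k, 2:3)
  expect_true(all(sel$indices$valid))
  expect_true(all(is.finite(sel$indices$silhouette)))
})

test_that("anovaScreenFeatures keeps informative features", {
  set.seed(44)
  lab <- factor(rep(c("a", "b"), each = 30))
  x <- matrix(rnorm(50 * 60), 50, 60,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:60)))
  x[1:5, lab == "b"] <- x[1:5, lab == "b"] + 3
  kept <- anovaScreenFeatures(x, lab, alpha = 0.01)
  expect_true(all(paste0("g", 1:5) %in% kept))
  expect_lt(length(kept), 20)
  p <- attr(kept, "p")
  expect_identical(length(p), 50L)
  # oracle: classic one-way ANOVA for one feature
  expect_equal(unname(p["g7"]),
               anova(lm(x["g7", ] ~ lab))[["Pr(>F)"]][1], tolerance = 1e-10)
})

test_that("smote interpolates within the minority neighbourhood", {
  set.seed(45)
  x <- matrix(runif(8 * 3), 8, 3)
  syn <- smote(x, nSynthetic = 20, k = 3)
  expect_identical(dim(syn), c(20L, 3L))
  expect_true(all(syn >= min(x) - 1e-12 & syn <= max(x) + 1e-12))
  # with two identical points, synthetics are that point
  x2 <- matrix(rep(c(0.5, 0.2), each = 2), 2, 2)
  expect_equal(unname(smote(x2, 5, k = 5)),
               matrix(rep(c(0.5, 0.2), each = 5), 5, 2))
})

test_that("buildBaseDatasets: balance and counts per mode", {
  set.seed(46)
  lab <- factor(c(rep("big", 60), rep("small", 8)))
  x <- matrix(rnorm(68 * 5), 68, 5,
              dimnames = list(paste0("s", 1:68), paste0("f", 1:5)))
  b1 <- buildBaseDatasets(x, lab, mode = 1, seed = 1)
  expect_length(b1, 10)
  for (bd in b1) {
    expect_identical(as.vector(table(bd$y)), c(60L, 60L))
    expect_identical(nrow(bd$x), 120L)
  }
  b2 <- buildBaseDatasets(x, lab, mode = 2, seed = 1)
  expect_length(b2, 10)
  expect_identical(nrow(b2[[1]]$x), 68L)
  b3 <- buildBaseDatasets(x, lab, mode = 3, seed = 1)
  expect_length(b3, 1)
  expect_identical(b3[[1]]$x, x)
  expect_error(buildBaseDatasets(x[c(1:60, 61), ],
                                 droplevels(lab[c(1:60, 61)]), mode = 1),
               "at least 2 samples")
})

test_that("trainEnsemble / predictEnsemble respect structure and alignment", {
  sim <- simulateImbalancedClasses(classSizes = c(80, 40), nFeatures = 60,
                                   nInformative = 8, classSep = 1.5,
                                   seed = 47)
  m <- sim$matrix; lab <- sim$labels
  model <- trainEnsemble(list(RNA = m), lab, mode = 1, learner = "svm",
                         seed = 2)
  expect_s4_class(model, "EnsembleModel")
  expect_length(model@omics$RNA$learners, 10L)
  expect_true(all(model@omics$RNA$recurrent %in%
                    model@omics$RNA$screened))

  pr <- predictEnsemble(model, list(RNA = m))
  expect_identical(names(pr$labels), sampleIds(m))
  expect_equal(unname(rowSums(pr$probabilities)), rep(1, ncol(m)),
               tolerance = 1e-8)
  expect_gt(mean(pr$labels == lab), 0.8)

  # feature/sample order must not matter
  vals <- assayValues(m)
  perm <- OmicsMatrix(vals[rev(seq_len(nrow(vals))),
                           rev(seq_len(ncol(vals)))], omicLabel = "RNA")
  pr2 <- predictEnsemble(model, list(RNA = perm))
  expect_identical(pr2$labels[names(pr$labels)], pr$labels)

  expect_error(predictEnsemble(model, list(other = m)), "omic")
  expect_error(predictEnsemble(model,
                               list(RNA = OmicsMatrix(vals[1:3, ],
                                                      omicLabel = "RNA"))),
               "feature")

  m3 <- trainEnsemble(list(RNA = m), lab, mode = 3, learner = "mlr",
                      seed = 2)
  expect_length(m3@omics$RNA$learners, 1L)
  pr3 <- predictEnsemble(m3, list(RNA = m))
  expect_identical(levels(pr3$labels), levels(lab))
  expect_gt(mean(pr3$labels == lab), 0.7)
})
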