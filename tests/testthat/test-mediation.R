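test_that("the internal IRLS logistic solver matches glm.fit", {
  set.seed(21)
  for (r in 1:5) {
    n <- 150
    X <- cbind(1, rnorm(n), rnorm(n))
    y <- rbinom(n, 1, plogis(drop(X %*% c(-0.2, 1, -0.7))))
    w <- runif(n, 0.5, 2)
    ours <- medwgcna:::.irlsLogit(X, y, w)
    ref <- suppressWarnings(glm.fit(X, y, weights = w,
                                    family = quasibinomial()))
    expect_true(ours$converged)
    expect_lt(max(abs(ours$coef - ref$coefficients)), 1e-6)
  }
})

test_that("IPW weights: identity without confounders, manual oracle with", {
  set.seed(22)
  n <- 400
  expect_equal(estimateIpwWeights(rnorm(n)), rep(1, n))

  U <- factor(sample(c("u0", "u1"), n, TRUE))
  e <- rbinom(n, 1, ifelse(U == "u1", 0.7, 0.3))
  w <- estimateIpwWeights(e, data.frame(U = U),
                          truncate = c(0, 1))
  ph <- fitted(glm(e ~ U, family = binomial()))
  manual <- ifelse(e == 1, mean(e) / ph, (1 - mean(e)) / (1 - ph))
  expect_equal(w, unname(manual), tolerance = 1e-6)

  wt <- estimateIpwWeights(e, data.frame(U = U), truncate = c(0.1, 0.9))
  expect_lte(max(wt), quantile(manual, 0.9) + 1e-8)
  expect_gte(min(wt), quantile(manual, 0.1) - 1e-8)

  sep <- c(rep(0, 200), rep(1, 200))
  expect_error(estimateIpwWeights(sep, data.frame(U = factor(sep))),
               "separation")
})

test_that("testMediation recovers a planted chain and is deterministic", {
  set.seed(23)
  n <- 300
  E <- rnorm(n)
  M <- 0.8 * E + rnorm(n)
  Y <- 0.7 * M + rnorm(n)
  r1 <- testMediation(E, M, Y, nBoot = 300, seed = 5)
  expect_equal(r1$indirect, r1$a * r1$b)
  expect_equal(r1$a, 0.8, tolerance = 0.15)
  expect_equal(r1$b, 0.7, tolerance = 0.15)
  expect_gt(r1$ciLow, 0)
  expect_lte(r1$p, 0.01)
  expect_gte(r1$p, 2 / 301)
  r2 <- testMediation(E, M, Y, nBoot = 300, seed = 5)
  expect_identical(r1, r2)
  r3 <- testMediation(E, M, Y, nBoot = 300, seed = 6)
  expect_false(identical(r1$p, r3$p) && identical(r1$ciLow, r3$ciLow))
})

test_that("testMediation handles binary outcomes and validates input", {
  set.seed(24)
  n <- 300
  E <- rnorm(n)
  M <- 0.8 * E + rnorm(n)
  Y <- factor(ifelse(plogis(1.2 * M + rnorm(n)) > 0.5, "case", "ctrl"))
  r <- testMediation(E, M, Y, nBoot = 200, seed = 1)
  expect_lt(r$p, 0.05)
  expect_false(r$unstable)
  expect_error(testMediation(E, M, Y, nBoot = 50), "at least 100")
  expect_error(testMediation(E, rep(1, n), Y, nBoot = 200), "constant")
})

test_that("causalScreen returns an empty frame when nothing is significant", {
  sim <- simulateMediationScenario(nSamples = 60, seed = 25)
  ms <- computeEigengenes(sim$matrix, sim$moduleLabels)
  dft <- diffFeaturesWithinModule(sim$matrix, ms, "ME1", sim$phenotypes)
  dft$significant <- FALSE
  out <- causalScreen(sim$matrix, ms, dft, "ME1", sim$phenotypes,
                      nBoot = 100)
  expect_identical(nrow(out), 0L)
  expect_true(all(c("module", "feature", "direction", "indirect", "pAdj",
                    "label") %in% colnames(out)))
})

test_that("causalScreen labels are consistent with the per-direction BH calls", {
  sim <- simulateMediationScenario(nSamples = 150, nPassengers = 8,
                                   nNull = 10, seed = 26)
  ms <- computeEigengenes(sim$matrix, sim$moduleLabels)
  dft <- diffFeaturesWithinModule(sim$matrix, ms, "ME1", sim$phenotypes)
  scr <- causalScreen(sim$matrix, ms, dft, "ME1", sim$phenotypes,
                      nBoot = 150, seed = 3)
  expect_identical(nrow(scr), 2L * sum(dft$significant))
  for (f in unique(scr$feature)) {
    rows <- scr[scr$feature == f, ]
    sigF <- any(rows$direction == "forward" & !is.na(rows$pAdj) &
                  rows$pAdj < 0.05)
    sigR <- any(rows$direction == "reverse" & !is.na(rows$pAdj) &
                  rows$pAdj < 0.05)
    want <- if (sigF && sigR) "ambiguous" else if (sigF) "driver"
            else if (sigR) "passenger" else "none"
    expect_identical(unique(rows$label), want)
  }
  # BH happens within direction
  for (dd in c("forward", "reverse")) {
    sel <- scr$direction == dd & !is.na(scr$p)
    expect_equal(scr$pAdj[sel], p.adjust(scr$p[sel], "BH"))
  }
})
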