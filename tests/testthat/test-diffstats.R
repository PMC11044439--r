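test_that("moderatedFit agrees with the limma oracle", {
  set.seed(11)
  n <- 16; nf <- 400
  grp <- rep(0:1, each = n / 2)
  y <- matrix(rnorm(nf * n), nf, n,
              dimnames = list(paste0("g", 1:nf), paste0("s", 1:n)))
  y[1:40, grp == 1] <- y[1:40, grp == 1] + 1.5
  X <- cbind(1, group = grp)

  ours <- moderatedFit(y, X, coef = "group")
  fit <- limma::eBayes(limma::lmFit(y, X))
  expect_lt(max(abs(ours$t - fit$t[, "group"])), 0.02)
  expect_lt(max(abs(ours$p - fit$p.value[, "group"])), 0.005)
  # the prior df estimate is flat in its objective once d0 is large;
  # agreement matters on the shrinkage scale 1/d0, not on d0 itself
  expect_lt(abs(1 / attr(ours, "d0") - 1 / fit$df.prior), 5e-4)
  expect_equal(attr(ours, "s02"), fit$s2.prior, tolerance = 0.01)
  expect_equal(ours$effect, unname(fit$coefficients[, "group"]),
               tolerance = 1e-10)
})

test_that("priorDf limits recover the ordinary and pooled t-tests", {
  set.seed(12)
  y <- matrix(rnorm(50 * 12), 50, 12,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:12)))
  X <- cbind(1, group = rep(0:1, 6))

  plain <- moderatedFit(y, X, coef = "group", priorDf = 0)
  classic <- apply(y, 1, function(v)
    t.test(v[X[, 2] == 1], v[X[, 2] == 0], var.equal = TRUE)$p.value)
  expect_equal(plain$p, unname(classic), tolerance = 1e-10)

  pooled <- moderatedFit(y, X, coef = "group", priorDf = Inf)
  expect_true(all(is.finite(pooled$t)))
  # pooled variance: all units share one residual sd
  tRatio <- pooled$t / pooled$effect
  expect_lt(diff(range(tRatio)), 1e-10)
})

test_that("type-III ANOVA screen matches car::Anova on unbalanced data", {
  set.seed(13)
  n <- 40
  d <- data.frame(group = factor(sample(c("a", "b"), n, TRUE,
                                        prob = c(0.7, 0.3))),
                  sex = factor(sample(c("m", "f"), n, TRUE)),
                  age = rnorm(n),
                  row.names = paste0("s", 1:n))
  x <- matrix(rnorm(6 * n), 6, n,
              dimnames = list(paste0("g", 1:6), rownames(d)))
  x[1, ] <- x[1, ] + 2 * (d$group == "b") + 0.5 * d$age
  ph <- PhenotypeTable(d, response = "group",
                       confounders = c("sex", "age"))
  scr <- type3AnovaScreen(OmicsMatrix(x), ph)

  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  for (feat in c("g1", "g4")) {
    fit <- lm(x[feat, ] ~ group + sex + age, data = d)
    a3 <- car::Anova(fit, type = 3)
    for (v in c("group", "sex", "age")) {
      row <- scr$perFeature[scr$perFeature$feature == feat &
                              scr$perFeature$variable == v, ]
      expect_equal(row$F, a3[v, "F value"], tolerance = 1e-8)
      expect_equal(row$p, a3[v, "Pr(>F)"], tolerance = 1e-8)
    }
  }
  expect_identical(scr$summary$variable, c("group", "sex", "age"))
})

test_that("type3AnovaScreen reports aliased variables", {
  d <- data.frame(group = factor(rep(c("a", "b"), 10)),
                  copy = factor(rep(c("a", "b"), 10)),
                  row.names = paste0("s", 1:20))
  x <- matrix(rnorm(3 * 20), 3, 20,
              dimnames = list(paste0("g", 1:3), rownames(d)))
  ph <- PhenotypeTable(d, response = "group", confounders = "copy")
  expect_error(type3AnovaScreen(OmicsMatrix(x), ph), "rank deficient")
})

test_that("diffModules and diffFeaturesWithinModule flag the planted module", {
  set.seed(14)
  sim <- simulateModularExpression(60, data.frame(size = c(30, 30),
                                                  rho = c(0.8, 0.8)),
                                   seed = 14)
  vals <- assayValues(sim$matrix)
  grp <- rep(c("case", "ctrl"), each = 30)
  # shift block 1 by the group
  vals[grepl("^blk1", rownames(vals)), grp == "case"] <-
    vals[grepl("^blk1", rownames(vals)), grp == "case"] + 1.2
  m <- OmicsMatrix(vals)
  ph <- PhenotypeTable(data.frame(group = grp, row.names = colnames(vals)),
                       response = "group")
  ms <- computeEigengenes(m, sim$truth)
  dm <- diffModules(ms, ph)
  expect_true(dm$significant[dm$unit == "ME1"])
  expect_false(dm$significant[dm$unit == "ME2"])
  expect_true(all(dm$pAdj >= dm$p - 1e-12))

  df1 <- diffFeaturesWithinModule(m, ms, "ME1", ph)
  expect_gt(mean(df1$significant), 0.9)
  df2 <- diffFeaturesWithinModule(m, ms, "ME2", ph)
  expect_lt(mean(df2$significant), 0.2)
  expect_error(diffFeaturesWithinModule(m, ms, "ME9", ph), "absent")
})
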