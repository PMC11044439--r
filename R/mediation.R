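## Causal core: product-method mediation with stabilized inverse-
## probability weights. Confounders are adjusted through the weights
## (optionally also as covariates, doubly-robust mode); significance of
## the indirect effect a*b comes from a nonparametric bootstrap that
## re-estimates the weights inside every resample.

.isBinary <- function(x) {
  if (is.factor(x)) return(nlevels(x) == 2L)
  length(unique(x)) == 2L
}

.toNumeric01 <- function(x) {
  if (is.factor(x)) return(as.integer(x) - 1L)
  u <- sort(unique(x))
  if (length(u) == 2L && !all(u == c(0, 1))) return(as.integer(x == u[2L]))
  as.numeric(x)
}

.confModelMatrix <- function(confounders) {
  if (is.null(confounders) || (is.data.frame(confounders) && !ncol(confounders)))
    return(NULL)
  if (!is.data.frame(confounders)) confounders <- as.data.frame(confounders)
  model.matrix(~ ., data = confounders)
}

## Newton/IRLS logistic solver for the small design matrices fitted
## thousands of times inside the bootstrap; same MLE as glm.fit but
## without the per-call family/model overhead (~10x faster here).
.irlsLogit <- function(X, y, w = NULL, maxit = 30L, tol = 1e-8) {
  if (is.null(w)) w <- rep(1, length(y))
  beta <- numeric(ncol(X))
  mu0 <- min(max(sum(w * y) / sum(w), 1e-6), 1 - 1e-6)
  beta[1L] <- log(mu0 / (1 - mu0))
  conv <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    eta[eta > 30] <- 30
    eta[eta < -30] <- -30
    mu <- plogis(eta)
    W <- w * mu * (1 - mu)
    A <- crossprod(X, X * W)
    rhs <- crossprod(X, W * eta + w * (y - mu))
    newBeta <- tryCatch(drop(solve(A, rhs)), error = function(e) NULL)
    if (is.null(newBeta))
      return(list(coef = beta, fitted = mu, converged = FALSE))
    done <- max(abs(newBeta - beta)) < tol * (1 + max(abs(beta)))
    beta <- newBeta
    if (done) { conv <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  eta[eta > 30] <- 30
  eta[eta < -30] <- -30
  list(coef = beta, fitted = plogis(eta), converged = conv)
}

## stabilized IPW from a numeric exposure (binary coded 0/1), a
## precomputed binary flag and a precomputed confounder model matrix
## (with intercept); the exported estimateIpwWeights wraps this.
.ipwCore <- function(e, eBinary, X, truncate) {
  n <- length(e)
  if (is.null(X)) return(rep(1, n))
  if (eBinary) {
    fit <- .irlsLogit(X, e)
    ph <- fit$fitted
    if (any(ph < 1e-10 | ph > 1 - 1e-10))
      stop("perfect separation in the propensity model; ",
           "remove the offending confounder")
    pmarg <- mean(e)
    one <- e == 1
    w <- numeric(n)
    w[one] <- pmarg / ph[one]
    w[!one] <- (1 - pmarg) / (1 - ph[!one])
  } else {
    fit <- lm.fit(X, e)
    sigC <- sqrt(sum(fit$residuals^2) / (n - fit$rank))
    w <- dnorm(e, mean(e), sd(e)) / dnorm(e, fit$fitted.values, sigC)
  }
  q <- quantile(w, truncate, names = FALSE)
  w[w < q[1L]] <- q[1L]
  w[w > q[2L]] <- q[2L]
  w
}

#' Stabilized inverse-probability-of-exposure weights
#'
#' Binary exposure: propensity by logistic regression of exposure on
#' confounders, stabilized weight \eqn{P(E = e_i)/\hat p(e_i | x_i)}.
#' Continuous exposure: generalized propensity by a Gaussian linear
#' model, weight = marginal density / conditional density. Without
#' confounders all weights are exactly 1. Weights are truncated at
#' their own (1st, 99th) percentiles.
#'
#' @param exposure binary (factor or two-valued) or continuous vector.
#' @param confounders data.frame of confounders (or NULL).
#' @param truncate percentile pair for weight truncation.
#' @return numeric weight vector, one per sample.
#' @export
estimateIpwWeights <- function(exposure, confounders = NULL,
                               truncate = c(0.01, 0.99)) {
  eBinary <- .isBinary(exposure)
  e <- if (eBinary) .toNumeric01(exposure) else as.numeric(exposure)
  .ipwCore(e, eBinary, .confModelMatrix(confounders), truncate)
}

.wlsSlope <- function(x, y, w) {
  xw <- sum(w * x) / sum(w)
  yw <- sum(w * y) / sum(w)
  sum(w * (x - xw) * (y - yw)) / sum(w * (x - xw)^2)
}

.wlsCoef2 <- function(x1, x2, y, w, extra = NULL) {
  # coefficient of x1 in weighted regression y ~ x1 + x2 (+ extra)
  X <- cbind(1, x1, x2, extra)
  A <- crossprod(X * w, X)
  b <- crossprod(X * w, y)
  solve(A, b)[2L]
}

.logisticCoef <- function(x1, x2, y, w, extra = NULL) {
  X <- cbind(1, x1, x2, extra)
  fit <- .irlsLogit(X, y, w)
  list(coef = fit$coef[2L], converged = fit$converged)
}

## En/Yn: exposure and outcome already coded numeric (binary as 0/1);
## Xconf: full confounder model matrix (with intercept) or NULL. All
## precomputed once so the bootstrap loop stays matrix-only.
.fitPaths <- function(En, eBinary, M, Yn, yBinary, Xconf, truncate,
                      covariates) {
  w <- .ipwCore(En, eBinary, Xconf, truncate)
  Xc <- if (covariates && !is.null(Xconf))
    Xconf[, -1L, drop = FALSE] else NULL
  if (is.null(Xc)) {
    a <- .wlsSlope(En, M, w)
  } else {
    X <- cbind(1, En, Xc)
    A <- crossprod(X * w, X)
    a <- solve(A, crossprod(X * w, M))[2L]
  }
  if (yBinary) {
    bf <- .logisticCoef(M, En, Yn, w, extra = Xc)
    b <- bf$coef; conv <- bf$converged
  } else {
    b <- .wlsCoef2(M, En, Yn, w, extra = Xc)
    conv <- TRUE
  }
  list(a = a, b = b, converged = conv)
}

#' Test one mediation model with the product method and IPW
#'
#' The a-path is the weighted regression of the mediator on the
#' exposure, the b-path the weighted regression of the outcome on the
#' mediator and exposure (weighted logistic when the outcome is binary);
#' both use the same stabilized IPW weights, so confounders are handled
#' by weighting, not as covariates (set \code{doublyRobust = TRUE} to
#' include them in both places). The indirect effect is \eqn{a \cdot b};
#' its percentile confidence interval and two-sided p come from a
#' nonparametric bootstrap that resamples the samples with replacement
#' and re-estimates the weights inside each resample, with the add-one
#' correction \eqn{p = 2 (r + 1)/(B + 1)}.
#'
#' @param exposure binary or continuous exposure vector.
#' @param mediator numeric mediator vector (one feature's values).
#' @param outcome binary or continuous outcome vector.
#' @param confounders data.frame of confounders or NULL.
#' @param nBoot number of bootstrap resamples (>= 100; default 500).
#' @param seed RNG seed for the bootstrap.
#' @param truncate weight truncation percentiles.
#' @param doublyRobust also include confounders as covariates.
#' @param level confidence level for the percentile CI.
#' @return one-row data.frame (a, b, indirect, ciLow, ciHigh, p,
#'   unstable) where \code{unstable} flags >20\% non-converged logistic
#'   fits among the resamples.
#' @export
testMediation <- function(exposure, mediator, outcome, confounders = NULL,
                          nBoot = 500, seed = 1, truncate = c(0.01, 0.99),
                          doublyRobust = FALSE, level = 0.95) {
  if (nBoot < 100) stop("nBoot must be at least 100")
  if (sd(mediator) == 0) stop("mediator is constant")
  n <- length(mediator)
  yBinary <- .isBinary(outcome)
  eBinary <- .isBinary(exposure)
  En <- if (eBinary) .toNumeric01(exposure) else as.numeric(exposure)
  Yn <- if (yBinary) .toNumeric01(outcome) else as.numeric(outcome)
  Xconf <- .confModelMatrix(confounders)
  fit <- .fitPaths(En, eBinary, mediator, Yn, yBinary, Xconf,
                   truncate, doublyRobust)
  set.seed(seed)
  ab <- numeric(nBoot)
  bad <- 0L
  for (bidx in seq_len(nBoot)) {
    idx <- sample.int(n, n, replace = TRUE)
    cf <- if (is.null(Xconf)) NULL else Xconf[idx, , drop = FALSE]
    fb <- tryCatch(.fitPaths(En[idx], eBinary, mediator[idx], Yn[idx],
                             yBinary, cf, truncate, doublyRobust),
                   error = function(e) NULL)
    if (is.null(fb)) { ab[bidx] <- NA; bad <- bad + 1L; next }
    if (!fb$converged) bad <- bad + 1L
    ab[bidx] <- fb$a * fb$b
  }
  ab <- ab[is.finite(ab)]
  B <- length(ab)
  alpha <- 1 - level
  ci <- quantile(ab, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  p <- 2 * min((1 + sum(ab <= 0)) / (B + 1), (1 + sum(ab >= 0)) / (B + 1))
  data.frame(a = fit$a, b = fit$b, indirect = fit$a * fit$b,
             ciLow = ci[1L], ciHigh = ci[2L], p = min(p, 1),
             unstable = bad > 0.2 * nBoot)
}

#' Screen a module's differential features for drivers and passengers
#'
#' For each significant feature of one differential module, fits two
#' mediation models: forward (exposure = module eigengene, mediator =
#' feature, outcome = group) asking whether the module drives the
#' phenotype through the feature, and reverse (exposure = group,
#' mediator = feature, outcome = eigengene) asking whether the phenotype
#' changes the feature and thereby the module. P-values are BH-adjusted
#' within each direction across the module's tested features, and each
#' feature is labelled \code{driver} (forward only significant),
#' \code{passenger} (reverse only), \code{ambiguous} (both) or
#' \code{none}.
#'
#' @param m the \linkS4class{OmicsMatrix}.
#' @param ms a \linkS4class{ModuleSet}.
#' @param diff DiffTable restricted to one module's features (as from
#'   \code{\link{diffFeaturesWithinModule}}); only rows with
#'   \code{significant == TRUE} are tested.
#' @param moduleLabel the module being screened.
#' @param ph a \linkS4class{PhenotypeTable} with a binary response; its
#'   confounders enter through IPW.
#' @param nBoot bootstrap resamples per model (default 500).
#' @param seed base seed; each feature gets a deterministic sub-seed.
#' @param pAdjCut significance threshold on adjusted p.
#' @param looEigengene recompute the eigengene excluding the tested
#'   feature (avoids mediator-in-exposure leakage; default FALSE).
#' @param refineBoot optional larger bootstrap size: models whose
#'   first-stage p is at most \code{refineCut} and whose BH-adjusted p
#'   lies above half the significance cut (i.e. the call could move
#'   either way within Monte Carlo resolution) are re-run at this size.
#'   The bootstrap p cannot go below 2/(nBoot + 1), so with many tested
#'   features a true positive can be unable to clear BH adjustment at
#'   moderate nBoot, and a floor-censored p can look more significant
#'   than it is; refinement buys resolution only where it can matter.
#' @param refineCut first-stage p threshold for refinement (default 0.1).
#' @return data.frame (module, feature, direction, a, b, indirect,
#'   ciLow, ciHigh, p, pAdj, unstable, label); features failing a model
#'   fit carry NA and are excluded from the BH family.
#' @export
causalScreen <- function(m, ms, diff, moduleLabel, ph, nBoot = 500,
                         seed = 1, pAdjCut = 0.05, looEigengene = FALSE,
                         refineBoot = NULL, refineCut = 0.1) {
  feats <- diff$unit[diff$significant]
  if (!length(feats)) {
    out <- data.frame(module = character(0), feature = character(0),
                      direction = character(0), a = numeric(0),
                      b = numeric(0), indirect = numeric(0),
                      ciLow = numeric(0), ciHigh = numeric(0),
                      p = numeric(0), pAdj = numeric(0),
                      unstable = logical(0), label = character(0))
    return(out)
  }
  al <- alignSamples(m, ph)
  vals <- assayValues(al$matrix)
  ph <- al$phenotypes
  eg <- eigengenes(ms)[moduleLabel, ]
  group <- responseValues(ph)
  conf <- confounderFrame(ph)
  if (!ncol(conf)) conf <- NULL
  asg <- moduleAssignment(ms)

  naRow <- data.frame(a = NA_real_, b = NA_real_, indirect = NA_real_,
                      ciLow = NA_real_, ciHigh = NA_real_, p = NA_real_,
                      unstable = NA)
  featEg <- function(f) {
    if (!looEigengene) return(eg)
    others <- setdiff(names(asg)[asg == moduleLabel], f)
    msLoo <- computeEigengenes(al$matrix,
                               setNames(rep(moduleLabel, length(others)),
                                        others))
    eigengenes(msLoo)[moduleLabel, ]
  }
  runOne <- function(f, dirn, nb, sd_) {
    egF <- featEg(f)
    med <- vals[f, ]
    fit <- tryCatch(
      if (dirn == "forward")
        testMediation(egF, med, group, conf, nBoot = nb, seed = sd_)
      else testMediation(group, med, egF, conf, nBoot = nb, seed = sd_),
      error = function(e) NULL)
    cbind(data.frame(module = moduleLabel, feature = f, direction = dirn),
          if (is.null(fit)) naRow else fit)
  }
  rows <- vector("list", 2L * length(feats))
  for (i in seq_along(feats)) {
    f <- feats[i]
    rows[[2L * i - 1L]] <- runOne(f, "forward", nBoot, seed + 2L * i)
    rows[[2L * i]] <- runOne(f, "reverse", nBoot, seed + 2L * i + 1L)
  }
  res <- do.call(rbind, rows)
  if (!is.null(refineBoot) && refineBoot > nBoot) {
    # refine only where the first-stage Monte Carlo resolution can
    # change the call: small raw p (possibly floor-censored) with an
    # adjusted p near the threshold on either side
    padj1 <- rep(NA_real_, nrow(res))
    for (dd in c("forward", "reverse")) {
      sel <- res$direction == dd & !is.na(res$p)
      padj1[sel] <- p.adjust(res$p[sel], "BH")
    }
    hot <- which(!is.na(res$p) & res$p <= refineCut &
                   padj1 >= pAdjCut / 2)
    for (j in hot) {
      i <- match(res$feature[j], feats)
      sd_ <- seed + 2L * i + (res$direction[j] == "reverse")
      res[j, ] <- runOne(res$feature[j], res$direction[j], refineBoot, sd_)
    }
  }
  res$pAdj <- NA_real_
  for (dd in c("forward", "reverse")) {
    sel <- res$direction == dd & !is.na(res$p)
    res$pAdj[sel] <- p.adjust(res$p[sel], "BH")
  }
  sigF <- with(res, direction == "forward" & !is.na(pAdj) & pAdj < pAdjCut)
  sigR <- with(res, direction == "reverse" & !is.na(pAdj) & pAdj < pAdjCut)
  fSig <- res$feature[sigF]
  rSig <- res$feature[sigR]
  lab <- function(f) {
    inF <- f %in% fSig; inR <- f %in% rSig
    if (inF && inR) "ambiguous" else if (inF) "driver"
    else if (inR) "passenger" else "none"
  }
  res$label <- vapply(res$feature, lab, "")
  rownames(res) <- NULL
  res
}
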