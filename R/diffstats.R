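## Confounder screening by per-feature type-III ANOVA and moderated
## differential testing of eigengenes / within-module features with an
## empirical-Bayes shrunken variance (scaled inverse-chi-square prior
## fitted by moment matching on log s^2).

.phenoModelFrame <- function(ph, variables) {
  d <- ph@data[, variables, drop = FALSE]
  if (any(!complete.cases(d))) stop("phenotype variables contain NA")
  d
}

#' Per-feature type-III ANOVA screen of phenotype variables
#'
#' Selects the \code{topN} most variable features, fits for each one a
#' linear model with every phenotype variable (response and confounders)
#' as predictor -- categorical variables sum-to-zero coded -- and
#' computes each variable's marginal (type-III) sum of squares by a
#' full-versus-reduced comparison. The per-variable mean sum of squares
#' (MSS), F statistic and P-value are averaged over features to rank the
#' variables' dataset-wide influence.
#'
#' @param m an \linkS4class{OmicsMatrix}.
#' @param ph a \linkS4class{PhenotypeTable}; all its variables are used.
#' @param topN number of most-variable features to screen (default 10000).
#' @return list with \code{summary} (per-variable meanMSS, meanF, meanP)
#'   and \code{perFeature} (long data.frame of feature, variable, MSS, F, p).
#' @export
type3AnovaScreen <- function(m, ph, topN = 10000) {
  al <- alignSamples(m, ph)
  vals <- assayValues(al$matrix)
  ph <- al$phenotypes
  variables <- c(ph@response, ph@confounders)
  d <- .phenoModelFrame(ph, variables)
  v <- apply(vals, 1, var)
  keep <- names(sort(v, decreasing = TRUE))[seq_len(min(topN, nrow(vals)))]
  vals <- vals[keep, , drop = FALSE]

  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  mm <- model.matrix(~ ., data = d)
  asn <- attr(mm, "assign")
  qrX <- qr(mm)
  if (qrX$rank < ncol(mm)) {
    bad <- colnames(mm)[qrX$pivot[(qrX$rank + 1):ncol(mm)]]
    stop("phenotype model is rank deficient (aliased): ",
         paste(bad, collapse = ", "))
  }
  n <- nrow(mm); p <- ncol(mm)
  dfRes <- n - p
  if (dfRes < 1) stop("more model parameters than samples")

  Y <- t(vals)                               # samples x features
  resFull <- qr.resid(qrX, Y)
  rssFull <- colSums(resFull^2)
  mse <- rssFull / dfRes

  out <- vector("list", length(variables))
  for (i in seq_along(variables)) {
    cols <- which(asn == i)
    qrRed <- qr(mm[, -cols, drop = FALSE])
    rssRed <- colSums(qr.resid(qrRed, Y)^2)
    ss <- rssRed - rssFull
    dfv <- length(cols)
    Fv <- (ss / dfv) / mse
    pv <- pf(Fv, dfv, dfRes, lower.tail = FALSE)
    out[[i]] <- data.frame(feature = keep, variable = variables[i],
                           MSS = ss / dfv, F = Fv, p = pv,
                           row.names = NULL)
  }
  perFeature <- do.call(rbind, out)
  summary <- do.call(rbind, lapply(out, function(x)
    data.frame(variable = x$variable[1L], meanMSS = mean(x$MSS),
               meanF = mean(x$F), meanP = mean(x$p))))
  rownames(summary) <- NULL
  list(summary = summary, perFeature = perFeature)
}

.trigammaInverse <- function(x) {
  # Newton iteration on y -> trigamma(1/y) as in empirical-Bayes
  # variance-prior estimation; x > 0
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

.fitVariancePrior <- function(s2, df) {
  # scaled inverse-chi-square prior (d0, s0^2) by matching moments of
  # log s^2: E[log s2] and Var[log s2] under s2 ~ s0^2 * F(df, d0)
  ok <- s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  evar <- var(e) * (sum(ok) - 1) / sum(ok) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0)
    return(list(d0 = Inf, s02 = exp(ebar)))
  d0 <- 2 * .trigammaInverse(evar)
  s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Moderated linear-model fit over many units
#'
#' Per-unit ordinary least squares of each row of \code{y} on
#' \code{design}, followed by empirical-Bayes moderation of the residual
#' variances: a scaled inverse-chi-square prior \eqn{(d_0, s_0^2)} is
#' fitted to the observed \eqn{s^2} by moment matching on
#' \eqn{\log s^2}, the posterior variance is
#' \eqn{\tilde{s}^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)} and the moderated t
#' for the coefficient of interest has \eqn{d_0 + d} degrees of freedom.
#' P-values are Benjamini-Hochberg adjusted across units.
#'
#' @param y numeric matrix, units x samples.
#' @param design model matrix (samples x parameters), full rank.
#' @param coef column (index or name) of the coefficient of interest.
#' @param priorDf optional forced prior degrees of freedom d0
#'   (0 disables shrinkage; Inf pools fully); default NULL = estimate.
#' @param pAdjCut adjusted-p threshold for the \code{significant} flag.
#' @return data.frame (unit, effect, t, p, pAdj, significant) plus
#'   attributes \code{d0} and \code{s02}.
#' @export
moderatedFit <- function(y, design, coef = 2L, priorDf = NULL,
                         pAdjCut = 0.05) {
  y <- as.matrix(y)
  X <- as.matrix(design)
  n <- ncol(y); p <- ncol(X)
  stopifnot(nrow(X) == n)
  qrX <- qr(X)
  if (qrX$rank < p) stop("design is rank deficient")
  d <- n - p
  if (d < 1) stop("no residual degrees of freedom")
  if (is.character(coef)) coef <- match(coef, colnames(X))
  XtXinv <- chol2inv(qr.R(qrX)[seq_len(p), seq_len(p), drop = FALSE])
  # account for pivoting
  piv <- qrX$pivot
  XtXinv <- XtXinv[order(piv), order(piv), drop = FALSE]
  B <- t(qr.coef(qrX, t(y)))
  R <- t(qr.resid(qrX, t(y)))
  s2 <- rowSums(R^2) / d
  if (is.null(priorDf)) {
    if (max(s2) - min(s2) < 1e-12 * max(s2, 1e-300)) {
      message("all residual variances equal; using the pooled-variance limit")
      prior <- list(d0 = Inf, s02 = mean(s2))
    } else prior <- .fitVariancePrior(s2, d)
  } else {
    prior <- list(d0 = priorDf,
                  s02 = if (priorDf > 0) mean(s2) else 0)
  }
  d0 <- prior$d0
  s2post <- if (is.infinite(d0)) rep(prior$s02, length(s2))
            else if (d0 == 0) s2
            else (d0 * prior$s02 + d * s2) / (d0 + d)
  seu <- sqrt(XtXinv[coef, coef])
  eff <- B[, coef]
  tmod <- eff / (sqrt(s2post) * seu)
  dfTot <- if (is.infinite(d0)) Inf else d0 + d
  pv <- 2 * pt(-abs(tmod), df = dfTot)
  padj <- p.adjust(pv, "BH")
  res <- data.frame(unit = rownames(y), effect = eff, t = tmod, p = pv,
                    pAdj = padj, significant = padj < pAdjCut,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "d0") <- d0
  attr(res, "s02") <- prior$s02
  res
}

.groupDesign <- function(ph) {
  r <- responseValues(ph)
  if (!is.factor(r)) stop("a binary (two-level factor) response is required")
  d <- data.frame(group = as.integer(r) - 1L)
  conf <- confounderFrame(ph)
  if (ncol(conf)) d <- cbind(d, conf)
  X <- model.matrix(~ ., data = d)
  X
}

#' Differential modules: moderated test of eigengenes between groups
#'
#' Fits each module eigengene against the design
#' \code{[intercept, group, confounders]} and reports the moderated t
#' for the group coefficient (second response level minus reference),
#' BH-adjusted across modules.
#'
#' @param ms a \linkS4class{ModuleSet}.
#' @param ph a \linkS4class{PhenotypeTable} with a binary response; its
#'   confounders enter the design as covariates.
#' @param pAdjCut significance threshold on adjusted p (default 0.05).
#' @return a DiffTable data.frame as from \code{\link{moderatedFit}}.
#' @export
diffModules <- function(ms, ph, pAdjCut = 0.05) {
  eg <- eigengenes(ms)
  stopifnot(identical(colnames(eg), sampleIds(ph)))
  X <- .groupDesign(ph)
  moderatedFit(eg, X, coef = "group", pAdjCut = pAdjCut)
}

#' Differential features within one module
#'
#' Moderated group test of every feature assigned to \code{moduleLabel},
#' same design as \code{\link{diffModules}}; BH adjustment within the
#' module. The effect column is on the data scale (e.g. delta beta for
#' methylation), positive when the second group level is higher.
#'
#' @param m the \linkS4class{OmicsMatrix} the modules came from.
#' @param ms a \linkS4class{ModuleSet}.
#' @param moduleLabel module to test (e.g. "ME1").
#' @param ph a \linkS4class{PhenotypeTable} with a binary response.
#' @param pAdjCut significance threshold on adjusted p.
#' @return a DiffTable data.frame.
#' @export
diffFeaturesWithinModule <- function(m, ms, moduleLabel, ph,
                                     pAdjCut = 0.05) {
  asg <- moduleAssignment(ms)
  feats <- names(asg)[asg == moduleLabel]
  if (length(feats) < 2L)
    stop("module '", moduleLabel, "' absent or has fewer than 2 features")
  al <- alignSamples(m, ph)
  vals <- assayValues(al$matrix)[feats, , drop = FALSE]
  X <- .groupDesign(al$phenotypes)
  moderatedFit(vals, X, coef = "group", pAdjCut = pAdjCut)
}
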