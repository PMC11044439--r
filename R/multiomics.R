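## Multi-omics machine learning: iterated pairwise CCA (or concatenated
## module eigengenes) to merge omics into one sample-by-component
## matrix, k-means clustering with internal validity indices to choose
## k, and an imbalance-aware ensemble classifier (bagging-SMOTE /
## bagging / single) with elastic-net feature selection and SVM or
## multinomial-logistic base learners.

#' Standardize features (rows) of an omics matrix
#'
#' Per-feature centering and scaling to mean 0, sd 1 across samples;
#' zero-variance features are dropped with a warning. Idempotent.
#'
#' @param m an \linkS4class{OmicsMatrix}.
#' @return a standardized \linkS4class{OmicsMatrix}.
#' @export
scaleFeatures <- function(m) {
  vals <- assayValues(m)
  s <- apply(vals, 1, sd)
  if (any(s == 0)) {
    warning("dropping ", sum(s == 0), " zero-variance feature(s)")
    vals <- vals[s > 0, , drop = FALSE]
  }
  OmicsMatrix(.standardizeRows(vals), omicLabel = omicLabel(m))
}

.scaleCols <- function(x) {
  s <- apply(x, 2, sd)
  keep <- s > 0
  x <- x[, keep, drop = FALSE]
  scale(x)[, , drop = FALSE]
}

.whiten <- function(x, rank = NULL, tol = 1e-8) {
  # centered block -> orthonormal score basis (left singular vectors)
  # truncated to the top `rank` components; without truncation a
  # p >= n block spans the whole sample space and every canonical
  # correlation degenerates to 1
  x <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(x)
  r <- sum(sv$d > tol * sv$d[1L])
  if (!is.null(rank)) r <- min(r, rank)
  list(u = sv$u[, seq_len(r), drop = FALSE], rank = r)
}

#' Canonical correlation analysis of two sample-aligned blocks
#'
#' Each block is first reduced to a whitened orthonormal basis of its
#' top \code{nCC} principal components (PCA-regularized CCA; without
#' the truncation a block with at least as many features as samples
#' spans the whole sample space and every canonical correlation is a
#' meaningless 1), then the canonical directions come from the SVD of
#' the whitened cross-covariance. Returns canonical variates per block
#' and the canonical correlations in decreasing order.
#'
#' @param a,b numeric matrices, samples x variables, same row order.
#' @param nCC number of canonical components (default 30; truncated to
#'   the attainable rank with a warning).
#' @return list (u, v, correlations).
#' @export
pairwiseCCA <- function(a, b, nCC = 30) {
  stopifnot(nrow(a) == nrow(b))
  wa <- .whiten(a, rank = nCC); wb <- .whiten(b, rank = nCC)
  r <- min(wa$rank, wb$rank)
  if (nCC > r) {
    warning("nCC = ", nCC, " exceeds the attainable rank ", r,
            "; truncating")
    nCC <- r
  }
  cc <- crossprod(wa$u, wb$u)
  sv <- svd(cc)
  idx <- seq_len(nCC)
  list(u = wa$u %*% sv$u[, idx, drop = FALSE],
       v = wb$u %*% sv$v[, idx, drop = FALSE],
       correlations = pmin(1, pmax(0, sv$d[idx])))
}

.sampleBlock <- function(m) {
  # OmicsMatrix -> samples x features block with standardized features
  t(assayValues(scaleFeatures(m)))
}

#' Merge omics into one representation by iterated pairwise CCA
#'
#' One omic degenerates to PCA (top \code{nCC} principal-component
#' scores); two omics give the column-concatenated canonical variates
#' of their CCA; for three or more the merged matrix is treated as a
#' single omic and folded with the next one in the given order.
#' Output columns are standardized.
#'
#' @param omics list of \linkS4class{OmicsMatrix} sharing sample ids.
#' @param nCC canonical/principal components per block (default 30).
#' @return A \linkS4class{MergedRepresentation}.
#' @export
multiccaMerge <- function(omics, nCC = 30) {
  stopifnot(length(omics) >= 1)
  sids <- sampleIds(omics[[1L]])
  for (om in omics)
    if (!identical(sort(sampleIds(om)), sort(sids)))
      stop("omics do not share the same sample set")
  blocks <- lapply(omics, function(om) {
    b <- .sampleBlock(om)
    b[sids, , drop = FALSE]
  })
  labels <- vapply(omics, omicLabel, "")
  if (length(blocks) == 1L) {
    x <- scale(blocks[[1L]], center = TRUE, scale = FALSE)
    sv <- svd(x)
    r <- min(nCC, sum(sv$d > 1e-8 * sv$d[1L]))
    merged <- sv$u[, seq_len(r), drop = FALSE] %*% diag(sv$d[seq_len(r)], r)
    prov <- data.frame(omicLabel = labels, nComponents = r, method = "pca")
  } else {
    merged <- blocks[[1L]]
    provLab <- labels[1L]
    for (i in 2L:length(blocks)) {
      cc <- suppressWarnings(pairwiseCCA(merged, blocks[[i]], nCC = nCC))
      merged <- cbind(cc$u, cc$v)
      provLab <- paste0(provLab, "+", labels[i])
    }
    prov <- data.frame(omicLabel = provLab, nComponents = ncol(merged),
                       method = "cca")
  }
  merged <- .scaleCols(merged)
  rownames(merged) <- sids
  colnames(merged) <- paste0("C", seq_len(ncol(merged)))
  new("MergedRepresentation", matrix = merged, provenance = prov)
}

#' Merge omics by concatenated module eigengenes
#'
#' Runs module detection per omic and concatenates the eigengenes
#' (samples x total modules), standardized. An omic yielding no module
#' contributes nothing, with a warning.
#'
#' @param omics list of \linkS4class{OmicsMatrix} sharing sample ids.
#' @param power soft power or "auto".
#' @param minSize minimum module size.
#' @param cutHeight static cut height (NULL = largest-gap midpoint).
#' @return A \linkS4class{MergedRepresentation}.
#' @export
wgcnaMerge <- function(omics, power = "auto", minSize = 30,
                       cutHeight = NULL) {
  sids <- sampleIds(omics[[1L]])
  parts <- list(); prov <- list()
  for (om in omics) {
    ms <- buildModules(om, power = power, minSize = minSize,
                       cutHeight = cutHeight)
    eg <- eigengenes(ms)
    if (!nrow(eg)) {
      warning("omic '", omicLabel(om), "' yielded no module; skipped")
      next
    }
    parts[[length(parts) + 1L]] <- t(eg[, sids, drop = FALSE])
    prov[[length(prov) + 1L]] <-
      data.frame(omicLabel = omicLabel(om), nComponents = nrow(eg),
                 method = "wgcna-eigengene")
  }
  if (!length(parts)) stop("no omic yielded any module")
  merged <- .scaleCols(do.call(cbind, parts))
  rownames(merged) <- sids
  colnames(merged) <- paste0("C", seq_len(ncol(merged)))
  new("MergedRepresentation", matrix = merged,
      provenance = do.call(rbind, prov))
}

.calinski <- function(x, labels) {
  n <- nrow(x); k <- length(unique(labels))
  gm <- colMeans(x)
  W <- 0; B <- 0
  for (cl in unique(labels)) {
    xi <- x[labels == cl, , drop = FALSE]
    ci <- colMeans(xi)
    W <- W + sum(sweep(xi, 2, ci)^2)
    B <- B + nrow(xi) * sum((ci - gm)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

.daviesBouldin <- function(x, labels) {
  cls <- sort(unique(labels))
  k <- length(cls)
  cent <- t(vapply(cls, function(cl)
    colMeans(x[labels == cl, , drop = FALSE]), numeric(ncol(x))))
  s <- vapply(seq_len(k), function(i) {
    xi <- x[labels == cls[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xi, 2, cent[i, ])^2)))
  }, 0)
  db <- 0
  for (i in seq_len(k)) {
    rij <- vapply(setdiff(seq_len(k), i), function(j)
      (s[i] + s[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2)), 0)
    db <- db + max(rij)
  }
  db / k
}

#' K-means clustering with internal-index selection of k
#'
#' Runs k-means (25 starts, seeded) for every candidate k, computes the
#' Silhouette, Calinski-Harabasz and Davies-Bouldin indices, and picks k
#' by majority vote of (argmax silhouette, argmax Calinski, argmin
#' Davies-Bouldin), the silhouette winner breaking three-way ties.
#'
#' @param rep a \linkS4class{MergedRepresentation} (or plain samples x
#'   components matrix).
#' @param kCandidates integer vector within 2..n-1.
#' @param seed RNG seed.
#' @param nStart k-means restarts (default 25).
#' @return list (labels, chosenK, indices) where indices is a data.frame
#'   (k, silhouette, calinski, davies, valid).
#' @export
clusterSelectK <- function(rep, kCandidates = 2:6, seed = 1, nStart = 25) {
  x <- if (is(rep, "MergedRepresentation")) rep@matrix else as.matrix(rep)
  n <- nrow(x)
  stopifnot(all(kCandidates >= 2), all(kCandidates <= n - 1))
  dmat <- dist(x)
  idx <- data.frame(k = kCandidates, silhouette = NA_real_,
                    calinski = NA_real_, davies = NA_real_, valid = FALSE)
  fits <- vector("list", length(kCandidates))
  for (i in seq_along(kCandidates)) {
    k <- kCandidates[i]
    fit <- NULL
    for (try in 0:4) {
      set.seed(seed + 1000L * try + k)
      fit <- tryCatch(kmeans(x, centers = k, nstart = nStart,
                             iter.max = 50),
                      error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(fit) && length(unique(fit$cluster)) == k) break
      fit <- NULL
    }
    if (is.null(fit)) next
    fits[[i]] <- fit
    lab <- fit$cluster
    idx$silhouette[i] <- mean(cluster::silhouette(lab, dmat)[, 3L])
    idx$calinski[i] <- .calinski(x, lab)
    idx$davies[i] <- .daviesBouldin(x, lab)
    idx$valid[i] <- TRUE
  }
  ok <- which(idx$valid)
  if (!length(ok)) stop("no candidate k produced a valid clustering")
  winners <- c(ok[which.max(idx$silhouette[ok])],
               ok[which.max(idx$calinski[ok])],
               ok[which.min(idx$davies[ok])])
  tab <- table(winners)
  best <- if (max(tab) >= 2) as.integer(names(tab)[which.max(tab)])
          else winners[1L]
  list(labels = fits[[best]]$cluster, chosenK = kCandidates[best],
       indices = idx)
}

#' One-way ANOVA screen of features against class labels
#'
#' Keeps features whose one-way ANOVA of value ~ class has p < alpha
#' (unadjusted). Zero-variance features are dropped.
#'
#' @param m an \linkS4class{OmicsMatrix} (or features x samples matrix).
#' @param labels factor of class labels, one per sample.
#' @param alpha retention threshold (default 0.05).
#' @return character vector of retained feature ids, with attribute
#'   \code{p} (named p-values of all tested features).
#' @export
anovaScreenFeatures <- function(m, labels, alpha = 0.05) {
  vals <- if (is(m, "OmicsMatrix")) assayValues(m) else as.matrix(m)
  labels <- droplevels(factor(labels))
  k <- nlevels(labels)
  stopifnot(k >= 2, ncol(vals) == length(labels))
  n <- ncol(vals)
  tot <- rowSums((vals - rowMeans(vals))^2)
  W <- 0
  B <- 0
  gm <- rowMeans(vals)
  for (cl in levels(labels)) {
    xi <- vals[, labels == cl, drop = FALSE]
    ci <- rowMeans(xi)
    W <- W + rowSums((xi - ci)^2)
    B <- B + ncol(xi) * (ci - gm)^2
  }
  keepVar <- tot > 0 & W > 0
  Fv <- (B / (k - 1)) / (W / (n - k))
  p <- pf(Fv, k - 1, n - k, lower.tail = FALSE)
  kept <- rownames(vals)[keepVar & p < alpha]
  structure(kept, p = p[keepVar])
}

#' Synthetic minority over-sampling (SMOTE)
#'
#' Generates synthetic points by interpolating uniformly on the segment
#' between a random minority sample and one of its k nearest minority
#' neighbors (Euclidean).
#'
#' @param x samples x features matrix of one class's samples (>= 2 rows).
#' @param nSynthetic number of synthetic samples to create.
#' @param k neighbors (default 5; capped at n - 1).
#' @return matrix of synthetic samples.
#' @export
smote <- function(x, nSynthetic, k = 5) {
  n <- nrow(x)
  if (n < 2L) stop("SMOTE needs at least 2 samples in the class")
  k <- min(k, n - 1L)
  d <- as.matrix(dist(x))
  diag(d) <- Inf
  # matrix() keeps n x k shape even when k = 1 (apply would drop it)
  nn <- t(matrix(apply(d, 1, function(r) order(r)[seq_len(k)]),
                 nrow = k))
  base <- sample.int(n, nSynthetic, replace = TRUE)
  pick <- nn[cbind(base, sample.int(k, nSynthetic, replace = TRUE))]
  u <- runif(nSynthetic)
  out <- x[base, , drop = FALSE] +
    u * (x[pick, , drop = FALSE] - x[base, , drop = FALSE])
  rownames(out) <- paste0("synth", seq_len(nSynthetic))
  out
}

#' Build base-learner training sets
#'
#' Mode 1 (bagging-SMOTE): 10 sets, each with every class brought to the
#' majority-class size -- the majority class by bootstrap, minority
#' classes by bootstrap of their own size topped up with SMOTE (k = 5)
#' to exact balance. Mode 2: 10 plain bootstraps of the whole training
#' set. Mode 3: the original data once.
#'
#' @param x samples x features matrix.
#' @param labels factor of class labels.
#' @param mode 1, 2 or 3.
#' @param seed RNG seed.
#' @return list of \code{list(x, y)} training sets (10 or 1).
#' @export
buildBaseDatasets <- function(x, labels, mode = 1, seed = 1) {
  stopifnot(mode %in% 1:3)
  labels <- droplevels(factor(labels))
  if (mode == 3) return(list(list(x = x, y = labels)))
  set.seed(seed)
  n <- nrow(x)
  out <- vector("list", 10L)
  if (mode == 2) {
    for (b in 1:10) {
      idx <- sample.int(n, n, replace = TRUE)
      out[[b]] <- list(x = x[idx, , drop = FALSE], y = labels[idx])
    }
    return(out)
  }
  sizes <- table(labels)
  if (any(sizes < 2L))
    stop("mode 1 needs at least 2 samples per class (SMOTE undefined)")
  nMaj <- max(sizes)
  for (b in 1:10) {
    xs <- list(); ys <- list()
    for (cl in levels(labels)) {
      xi <- x[labels == cl, , drop = FALSE]
      ni <- nrow(xi)
      boot <- xi[sample.int(ni, min(ni, nMaj), replace = TRUE), ,
                 drop = FALSE]
      if (ni < nMaj) boot <- rbind(boot, smote(boot, nMaj - ni, k = 5))
      xs[[cl]] <- boot
      ys[[cl]] <- rep(cl, nMaj)
    }
    xb <- do.call(rbind, xs)
    rownames(xb) <- paste0("b", b, "_", seq_len(nrow(xb)))
    out[[b]] <- list(x = xb, y = factor(unlist(ys), levels = levels(labels)))
  }
  out
}

.enetSelect <- function(x, y, alpha = 0.5, seed = 1) {
  fam <- if (nlevels(y) == 2L) "binomial" else "multinomial"
  set.seed(seed)
  cv <- glmnet::cv.glmnet(x, y, family = fam, alpha = alpha, nfolds = 5)
  cf <- glmnet::coef.glmnet(cv, s = "lambda.min")
  if (fam == "binomial") {
    nz <- rownames(cf)[which(as.numeric(cf) != 0)]
  } else {
    nz <- unique(unlist(lapply(cf, function(cc)
      rownames(cc)[which(as.numeric(cc) != 0)])))
  }
  setdiff(nz, "(Intercept)")
}

.fitBaseLearner <- function(x, y, learner) {
  if (learner == "svm") {
    e1071::svm(x, y, kernel = "linear", probability = TRUE, scale = FALSE)
  } else {
    df <- data.frame(.y = y, x, check.names = FALSE)
    nnet::multinom(.y ~ ., data = df, trace = FALSE,
                   MaxNWts = 100000, maxit = 200)
  }
}

.predictBase <- function(fit, x, classLevels, learner) {
  if (learner == "svm") {
    pr <- attr(predict(fit, x, probability = TRUE), "probabilities")
    pr <- pr[, classLevels, drop = FALSE]
  } else {
    df <- data.frame(x, check.names = FALSE)
    pr <- predict(fit, newdata = df, type = "probs")
    if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)  # two-class vector
    colnames(pr) <- classLevels
  }
  pr
}

#' Train the multi-omics ensemble classifier
#'
#' Per omic: features are standardized and screened by one-way ANOVA
#' (p < 0.05), base-learner datasets are built according to the
#' imbalance mode, elastic-net (mixing 0.5, internal 5-fold CV) selects
#' features per base dataset, the recurrent set (selected in at least
#' half of the base learners; falling back to the 50 smallest screen
#' p-values when empty) feeds 10 (mode 1-2) or 1 (mode 3) base learners
#' -- linear-kernel SVMs with probability outputs or multinomial
#' logistic regressions. Prediction averages class probabilities across
#' base learners within an omic and then across omics (soft vote).
#'
#' @param omics named list of \linkS4class{OmicsMatrix} sharing samples.
#' @param labels factor of class labels in the sample order of the
#'   first omic (or named by sample id).
#' @param mode 1 (bagging-SMOTE), 2 (bagging), 3 (single).
#' @param learner "svm" or "mlr".
#' @param seed RNG seed.
#' @param screenAlpha ANOVA screen threshold.
#' @param enetAlpha elastic-net mixing parameter.
#' @param recurrence fraction of base learners a feature must be
#'   selected in (default 0.5).
#' @return An \linkS4class{EnsembleModel}.
#' @export
trainEnsemble <- function(omics, labels, mode = 1,
                          learner = c("svm", "mlr"), seed = 1,
                          screenAlpha = 0.05, enetAlpha = 0.5,
                          recurrence = 0.5) {
  learner <- match.arg(learner)
  stopifnot(length(omics) >= 1)
  if (is.null(names(omics)))
    names(omics) <- vapply(omics, omicLabel, "")
  sids <- sampleIds(omics[[1L]])
  if (!is.null(names(labels))) labels <- labels[sids]
  labels <- droplevels(factor(labels))
  omicFits <- list()
  oi <- 0L
  for (oname in names(omics)) {
    oi <- oi + 1L
    om <- omics[[oname]]
    vals <- assayValues(om)[, sids, drop = FALSE]
    mu <- rowMeans(vals)
    sdv <- apply(vals, 1, sd)
    keep <- sdv > 0
    vals <- (vals[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
    screened <- anovaScreenFeatures(vals, labels, alpha = screenAlpha)
    pScreen <- attr(screened, "p")
    if (length(screened) < 2L)
      screened <- names(sort(pScreen))[seq_len(min(50L, length(pScreen)))]
    x <- t(vals[screened, , drop = FALSE])
    base <- buildBaseDatasets(x, labels, mode = mode,
                              seed = seed + 101L * oi)
    sel <- lapply(seq_along(base), function(b)
      .enetSelect(base[[b]]$x, base[[b]]$y, alpha = enetAlpha,
                  seed = seed + 101L * oi + b))
    cnt <- table(unlist(sel))
    recurrent <- names(cnt)[cnt >= recurrence * length(base)]
    if (!length(recurrent)) {
      warning("empty recurrent set for omic '", oname,
              "'; falling back to the 50 smallest screen p-values")
      recurrent <- names(sort(pScreen[screened]))[
        seq_len(min(50L, length(screened)))]
    }
    learners <- lapply(base, function(bd) {
      .fitBaseLearner(bd$x[, recurrent, drop = FALSE], bd$y, learner)
    })
    omicFits[[oname]] <- list(screened = screened, recurrent = recurrent,
                              learners = learners,
                              center = mu[keep], scale = sdv[keep])
  }
  new("EnsembleModel", mode = mode, learner = learner,
      classLevels = levels(labels), omics = omicFits, seed = seed)
}

#' Predict classes with a trained ensemble
#'
#' Features are aligned by name (row order is irrelevant) and scaled
#' with the training means and sds; missing recurrent features or a
#' missing omic raise an error. Class probabilities are averaged across
#' base learners within each omic and then across omics; the label is
#' the argmax. Deterministic given the model.
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param omics named list of \linkS4class{OmicsMatrix} covering every
#'   omic the model was trained on.
#' @return list (labels, probabilities) with probabilities a samples x
#'   classes matrix summing to 1 per row.
#' @export
predictEnsemble <- function(model, omics) {
  if (is.null(names(omics)))
    names(omics) <- vapply(omics, omicLabel, "")
  missingOmic <- setdiff(names(model@omics), names(omics))
  if (length(missingOmic))
    stop("omic(s) absent at prediction: ",
         paste(missingOmic, collapse = ", "))
  cl <- model@classLevels
  probs <- NULL
  for (oname in names(model@omics)) {
    fitO <- model@omics[[oname]]
    vals <- assayValues(omics[[oname]])
    missF <- setdiff(fitO$recurrent, rownames(vals))
    if (length(missF))
      stop("features missing from omic '", oname, "': ",
           paste(head(missF, 10), collapse = ", "),
           if (length(missF) > 10) " ...")
    x <- t((vals[fitO$recurrent, , drop = FALSE] -
              fitO$center[fitO$recurrent]) / fitO$scale[fitO$recurrent])
    pO <- Reduce(`+`, lapply(fitO$learners, function(fit)
      .predictBase(fit, x, cl, model@learner))) / length(fitO$learners)
    probs <- if (is.null(probs)) pO else probs + pO
  }
  probs <- probs / length(model@omics)
  probs <- probs / rowSums(probs)
  lab <- factor(cl[max.col(probs, ties.method = "first")], levels = cl)
  list(labels = setNames(lab, rownames(probs)), probabilities = probs)
}
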