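## Weighted co-expression network construction and module detection:
## soft-thresholded Pearson correlation adjacency, scale-free topology
## fit, topological overlap, average-linkage clustering with a static
## tree cut, and module eigengenes (first principal components).

.standardizeRows <- function(x) {
  mu <- rowMeans(x)
  s <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
  (x - mu) / s
}

#' Build a soft-thresholded adjacency network
#'
#' Computes the Pearson correlation between all feature pairs and raises
#' it to the soft power beta: \code{|cor|^beta} for an unsigned network,
#' \code{((1+cor)/2)^beta} for a signed one. Diagonal is 1.
#'
#' @param m an \linkS4class{OmicsMatrix} (features x samples).
#' @param beta positive soft-thresholding power.
#' @param signed logical; signed network.
#' @return A \linkS4class{CoexNetwork} (TOM not yet computed).
#' @export
buildNetwork <- function(m, beta = 6, signed = FALSE) {
  vals <- assayValues(m)
  s <- apply(vals, 1, sd)
  if (any(s == 0))
    stop("constant feature rows (correlation undefined): ",
         paste(head(rownames(vals)[s == 0], 5), collapse = ", "))
  cc <- cor(t(vals))
  a <- if (signed) ((1 + cc) / 2)^beta else abs(cc)^beta
  a <- (a + t(a)) / 2
  a[a > 1] <- 1
  diag(a) <- 1
  new("CoexNetwork", adjacency = a, tom = NULL, softPower = beta,
      signed = signed)
}

#' Scale-free topology fit of a soft power
#'
#' Builds the adjacency at power \code{beta}, computes each feature's
#' connectivity \eqn{k_i = \sum_{j \ne i} a_{ij}}, bins \code{log10(k)}
#' into 10 equal-width bins and regresses \code{log10(p(k))} on the
#' per-bin mean \code{log10(k)}. Returns the R-squared of that fit
#' (reported as 0 when the slope is positive, or when fewer than 3
#' non-empty bins remain) and the mean connectivity.
#'
#' @param m an \linkS4class{OmicsMatrix} with >= 20 features, >= 8 samples.
#' @param beta soft power.
#' @param signed logical; signed network.
#' @param nBins number of equal-width bins (default 10).
#' @return list with \code{rSquared} and \code{meanConnectivity}.
#' @export
scaleFreeFit <- function(m, beta = 6, signed = FALSE, nBins = 10) {
  if (dim(m)[1] < 20) stop("need at least 20 features")
  if (dim(m)[2] < 8) stop("need at least 8 samples")
  net <- buildNetwork(m, beta = beta, signed = signed)
  a <- adjacencyMatrix(net)
  k <- rowSums(a) - 1
  meanK <- mean(k)
  k <- k[k > 0]
  lk <- log10(k)
  if (length(unique(lk)) < 2L)
    return(list(rSquared = 0, meanConnectivity = meanK))
  breaks <- seq(min(lk), max(lk), length.out = nBins + 1L)
  bin <- findInterval(lk, breaks, rightmost.closed = TRUE)
  cnt <- tabulate(bin, nbins = nBins)
  keep <- cnt > 0
  if (sum(keep) < 3L)
    return(list(rSquared = 0, meanConnectivity = meanK))
  pk <- cnt[keep] / length(lk)
  xbar <- vapply(which(keep), function(b) mean(lk[bin == b]), 0)
  fit <- stats::lm.fit(cbind(1, xbar), log10(pk))
  slope <- fit$coefficients[2L]
  y <- log10(pk)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  if (!is.finite(r2) || slope > 0) r2 <- 0
  list(rSquared = max(0, min(1, r2)), meanConnectivity = meanK)
}

#' Pick the soft-thresholding power
#'
#' Returns the smallest candidate power whose scale-free fit R-squared
#' reaches \code{r2Cut}; when none does, warns and returns the candidate
#' with the largest R-squared.
#'
#' @param m an \linkS4class{OmicsMatrix}.
#' @param candidates ascending integer powers (default 1..20).
#' @param r2Cut fit threshold (default 0.8).
#' @param signed logical; signed network.
#' @return the chosen power, with attributes \code{rSquared} and
#'   \code{meanConnectivity} (per-candidate vectors).
#' @export
pickSoftPower <- function(m, candidates = 1:20, r2Cut = 0.8,
                          signed = FALSE) {
  stopifnot(length(candidates) > 0, !is.unsorted(candidates))
  r2 <- mk <- numeric(length(candidates))
  chosen <- NA_integer_
  for (i in seq_along(candidates)) {
    f <- scaleFreeFit(m, beta = candidates[i], signed = signed)
    r2[i] <- f$rSquared; mk[i] <- f$meanConnectivity
    if (is.na(chosen) && r2[i] >= r2Cut) {
      chosen <- candidates[i]
      break
    }
  }
  if (is.na(chosen)) {
    warning("no candidate power reached R^2 >= ", r2Cut,
            "; using the best-fitting power")
    chosen <- candidates[which.max(r2)]
  }
  structure(chosen, rSquared = r2, meanConnectivity = mk)
}

#' Compute the topological overlap matrix
#'
#' Unsigned TOM: \eqn{tom_{ij} = (l_{ij} + a_{ij}) /
#' (\min(k_i, k_j) + 1 - a_{ij})} with \eqn{l_{ij} = \sum_{u \ne i,j}
#' a_{iu} a_{uj}} and unit diagonal.
#'
#' @param net a \linkS4class{CoexNetwork}.
#' @return the network with its \code{tom} slot filled.
#' @export
computeTOM <- function(net) {
  a <- adjacencyMatrix(net)
  k <- rowSums(a) - 1
  aa <- a %*% a
  # (A^2)_ij includes the u = i and u = j terms a_ii a_ij + a_ij a_jj = 2 a_ij
  l <- aa - 2 * a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  tom[tom < 0] <- 0
  tom[tom > 1] <- 1
  new("CoexNetwork", adjacency = a, tom = tom, softPower = net@softPower,
      signed = net@signed)
}

.canonicalModuleLabels <- function(labels, featureIds) {
  # ME1..MEk by decreasing size; ties broken by lexicographically
  # smallest member, so the labelling is invariant to feature order
  names(labels) <- featureIds
  mods <- setdiff(unique(labels), "ME0")
  if (!length(mods)) return(labels)
  sz <- vapply(mods, function(mm) sum(labels == mm), 0L)
  firstMember <- vapply(mods, function(mm) min(featureIds[labels == mm]), "")
  ord <- order(-sz, firstMember)
  newLab <- setNames(paste0("ME", seq_along(mods)), mods[ord])
  out <- ifelse(labels == "ME0", "ME0", newLab[labels])
  setNames(out, featureIds)
}

#' Detect co-expression modules from the TOM
#'
#' Average-linkage hierarchical clustering on dissimilarity 1 - TOM with
#' a static tree cut. Clusters smaller than \code{minSize} are relabelled
#' ME0 (unassigned); surviving modules become ME1..MEk by decreasing
#' size. With \code{cutHeight = NULL} the cut is placed at the midpoint
#' of the largest gap between consecutive merge heights, a deterministic
#' choice that separates tight blocks from the background.
#'
#' @param net a \linkS4class{CoexNetwork} with TOM computed.
#' @param m the \linkS4class{OmicsMatrix} the network came from (used
#'   for eigengenes).
#' @param minSize minimum module size (default 30).
#' @param cutHeight static cut height on 1 - TOM, or NULL for the
#'   largest-gap midpoint.
#' @return A \linkS4class{ModuleSet}.
#' @export
detectModules <- function(net, m, minSize = 30, cutHeight = NULL) {
  tom <- tomMatrix(net)
  if (is.null(tom)) stop("compute the TOM first (computeTOM)")
  if (nrow(tom) < 2L) stop("need at least 2 features")
  d <- 1 - tom
  hc <- hclust(as.dist(d), method = "average")
  if (is.null(cutHeight)) {
    h <- sort(hc$height)
    if (length(h) == 1L) {
      cutHeight <- h / 2
    } else {
      gaps <- diff(h)
      i <- which.max(gaps)
      cutHeight <- (h[i] + h[i + 1L]) / 2
    }
  }
  cl <- cutree(hc, h = cutHeight)
  labels <- paste0("c", cl)
  tab <- table(labels)
  labels[labels %in% names(tab)[tab < minSize]] <- "ME0"
  ids <- rownames(tom)
  labels <- .canonicalModuleLabels(ifelse(labels == "ME0", "ME0",
                                          paste0("ME", labels)), ids)
  computeEigengenes(m, labels, network = net)
}

#' Compute module eigengenes
#'
#' Features are standardized across samples; each module's eigengene is
#' the first right singular vector of its standardized submatrix, scaled
#' to unit variance and sign-aligned so it correlates positively with
#' the module's mean standardized profile. Variance explained is
#' \eqn{\sigma_1^2 / \sum \sigma^2}. Zero-variance features are dropped
#' from the PC computation with a warning. ME0 gets no eigengene.
#'
#' @param m an \linkS4class{OmicsMatrix}.
#' @param assignment named character vector feature -> module label.
#' @param network optional \linkS4class{CoexNetwork} stored alongside.
#' @return A \linkS4class{ModuleSet}.
#' @export
computeEigengenes <- function(m, assignment, network = NULL) {
  vals <- assayValues(m)
  stopifnot(all(names(assignment) %in% rownames(vals)))
  mods <- setdiff(unique(assignment), "ME0")
  mods <- mods[order(as.integer(sub("^ME", "", mods)))]
  eg <- matrix(0, length(mods), ncol(vals),
               dimnames = list(mods, colnames(vals)))
  ve <- setNames(numeric(length(mods)), mods)
  for (mm in mods) {
    feats <- names(assignment)[assignment == mm]
    sub <- vals[feats, , drop = FALSE]
    s <- apply(sub, 1, sd)
    if (any(s == 0)) {
      warning("dropping ", sum(s == 0), " zero-variance feature(s) from ",
              mm, " eigengene")
      sub <- sub[s > 0, , drop = FALSE]
    }
    if (nrow(sub) < 2L) stop("module ", mm, " has fewer than 2 usable features")
    z <- .standardizeRows(sub)
    sv <- svd(z)
    e <- sv$v[, 1L]
    meanProfile <- colMeans(z)
    if (sum(e * meanProfile) < 0) e <- -e
    eg[mm, ] <- e / sd(e)
    ve[mm] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  new("ModuleSet", assignment = assignment, eigengenes = eg,
      varianceExplained = ve, network = network)
}

#' Run the full module-detection pipeline on one omic
#'
#' Soft-power selection (unless given), adjacency, TOM, static tree cut
#' and eigengenes.
#'
#' @param m an \linkS4class{OmicsMatrix}.
#' @param power soft power, or "auto" to pick by scale-free fit.
#' @param signed logical; signed network.
#' @param minSize minimum module size.
#' @param cutHeight static cut height (NULL = largest-gap midpoint).
#' @param candidates candidate powers for "auto".
#' @param r2Cut scale-free fit threshold for "auto".
#' @return A \linkS4class{ModuleSet}.
#' @export
buildModules <- function(m, power = "auto", signed = FALSE, minSize = 30,
                         cutHeight = NULL, candidates = 1:20, r2Cut = 0.8) {
  if (identical(power, "auto"))
    power <- as.integer(pickSoftPower(m, candidates, r2Cut, signed))
  net <- computeTOM(buildNetwork(m, beta = power, signed = signed))
  detectModules(net, m, minSize = minSize, cutHeight = cutHeight)
}

#' Serialize a ModuleSet to two TSV files
#'
#' Writes \code{assignment.tsv} (feature, module) and
#' \code{eigengenes.tsv} (module x sample) into \code{dir}.
#'
#' @param ms a \linkS4class{ModuleSet}.
#' @param dir output directory (created if needed).
#' @param seed optional seed recorded in the headers.
#' @return \code{dir}, invisibly.
#' @export
writeModuleSet <- function(ms, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeResultTable(data.frame(feature = names(moduleAssignment(ms)),
                              module = unname(moduleAssignment(ms))),
                   file.path(dir, "assignment.tsv"), seed = seed)
  writeMatrix(eigengenes(ms), file.path(dir, "eigengenes.tsv"),
              idColumn = "module", seed = seed)
  invisible(dir)
}
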