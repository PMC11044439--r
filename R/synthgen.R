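## Synthetic-data generators reproducing the statistical structures the
## rest of the package assumes: block-correlated feature modules,
## planted forward/reverse mediation chains with confounding, shared
## multi-omic cluster structure and imbalanced class labels. All are
## deterministic under a fixed seed.

#' Simulate block-correlated modular expression
#'
#' Each block is built from a common latent factor:
#' \eqn{x = \sqrt{\rho} f + \sqrt{1 - \rho}\, \epsilon}, giving exact
#' target pairwise within-block correlation \eqn{\rho}; background
#' features are i.i.d. noise.
#'
#' @param nSamples number of samples.
#' @param blocks data.frame with columns \code{size} and \code{rho}
#'   (one row per module), or a list of \code{c(size, rho)} pairs.
#' @param nBackground number of unstructured noise features.
#' @param seed RNG seed.
#' @param omicLabel omic label of the result.
#' @return list: \code{matrix} (\linkS4class{OmicsMatrix}) and
#'   \code{truth} (named character vector feature -> block label;
#'   background features are "ME0").
#' @export
simulateModularExpression <- function(nSamples, blocks, nBackground = 0,
                                      seed = 1, omicLabel = "RNA") {
  if (is.list(blocks) && !is.data.frame(blocks))
    blocks <- data.frame(size = vapply(blocks, `[`, 0, 1),
                         rho = vapply(blocks, `[`, 0, 2))
  stopifnot(all(blocks$size > 0), all(blocks$rho >= 0), all(blocks$rho < 1))
  set.seed(seed)
  rows <- list(); truth <- character(0)
  for (i in seq_len(nrow(blocks))) {
    sz <- blocks$size[i]; rho <- blocks$rho[i]
    f <- rnorm(nSamples)
    e <- matrix(rnorm(sz * nSamples), sz, nSamples)
    x <- sqrt(rho) * matrix(f, sz, nSamples, byrow = TRUE) +
      sqrt(1 - rho) * e
    rownames(x) <- paste0("blk", i, "_g", seq_len(sz))
    rows[[i]] <- x
    truth <- c(truth, setNames(rep(paste0("ME", i), sz), rownames(x)))
  }
  if (nBackground > 0) {
    bg <- matrix(rnorm(nBackground * nSamples), nBackground, nSamples)
    rownames(bg) <- paste0("bg_g", seq_len(nBackground))
    rows[[length(rows) + 1L]] <- bg
    truth <- c(truth, setNames(rep("ME0", nBackground), rownames(bg)))
  }
  vals <- do.call(rbind, rows)
  colnames(vals) <- paste0("s", seq_len(nSamples))
  list(matrix = OmicsMatrix(vals, omicLabel = omicLabel), truth = truth)
}

#' Simulate a module with planted forward and reverse mediation chains
#'
#' One co-expression module plus optional background noise features, a
#' binary phenotype and a binary confounder, built so the two mediation
#' directions leave distinguishable observational signatures:
#' \itemize{
#' \item a module factor \eqn{f_0} underlies every module feature and
#'   has a direct effect (\code{moduleEffect}) on the phenotype
#'   log-odds, so module-only ("null") features are close to
#'   conditionally independent of the group given the eigengene;
#' \item each \emph{driver} carries its own signal \eqn{d_0} that
#'   pushes the phenotype log-odds (slope \code{driverEffect}) plus a
#'   weak factor loading (\code{driverLoading}); its eigengene
#'   correlation is largely group-driven, so the reverse b-path
#'   (feature to eigengene given group) vanishes while both forward
#'   paths stay strong -- the forward product test fires alone;
#' \item \emph{passenger} features are shifted by the group
#'   (\code{passengerShift}) on top of a strong factor loading; because
#'   all passengers share the same shift direction, the eigengene
#'   absorbs it and the forward b-path (group on feature given
#'   eigengene) vanishes -- the reverse product test fires alone;
#' \item \emph{null} features load on \eqn{f_0} only and respond to
#'   neither product test;
#' \item the confounder shifts both the group log-odds and every
#'   feature.
#' }
#'
#' @param nSamples samples (default 300).
#' @param nDrivers,nPassengers,nNull feature counts (defaults 1/20/30).
#' @param driverEffect logistic slope of the group on the driver signal
#'   (default 2).
#' @param driverLoading driver loading on the module factor (default
#'   0.12, near the point where the loading offsets the collider
#'   association induced by conditioning on the group, leaving the
#'   driver's reverse b-path close to zero).
#' @param moduleEffect direct logistic slope of the module factor on
#'   the group (default 0.9).
#' @param passengerShift group shift of each passenger, in sd units
#'   (default 0.65).
#' @param passengerLoading,nullLoading factor loadings (defaults 0.9,
#'   0.25).
#' @param gamma confounder effect on the group log-odds (default 0.8).
#' @param delta confounder effect on the features (default 0.3).
#' @param prevalence target case fraction (default 0.4).
#' @param nBackground unstructured noise features (default 0).
#' @param seed RNG seed.
#' @return list: \code{matrix} (\linkS4class{OmicsMatrix}),
#'   \code{phenotypes} (\linkS4class{PhenotypeTable} with response
#'   \code{group}, confounder \code{conf}), \code{truth} (data.frame
#'   feature/role with roles driver/passenger/null/background) and
#'   \code{moduleLabels} (named vector usable with
#'   \code{\link{computeEigengenes}}).
#' @export
simulateMediationScenario <- function(nSamples = 300, nDrivers = 1,
                                      nPassengers = 20, nNull = 30,
                                      driverEffect = 2,
                                      driverLoading = 0.12,
                                      moduleEffect = 0.9,
                                      passengerShift = 0.65,
                                      passengerLoading = 0.9,
                                      nullLoading = 0.25, gamma = 0.8,
                                      delta = 0.3, prevalence = 0.4,
                                      nBackground = 0, seed = 1) {
  stopifnot(nDrivers >= 1)
  set.seed(seed)
  n <- nSamples
  f0 <- rnorm(n)
  C <- rbinom(n, 1, 0.5)
  Ct <- C - 0.5
  d0 <- matrix(rnorm(n * nDrivers), n, nDrivers)
  eta <- driverEffect * rowSums(d0) + moduleEffect * f0 + gamma * Ct
  c0 <- stats::uniroot(function(cc) mean(plogis(eta + cc)) - prevalence,
                       c(-20, 20))$root
  g <- rbinom(n, 1, plogis(eta + c0))
  gt <- g - mean(g)
  mkBlock <- function(k, load, fac, extra = 0) {
    if (k == 0) return(NULL)
    sdE <- sqrt(max(1 - load^2, 0.15))
    t(load * matrix(fac, n, k) + extra +
        matrix(rnorm(n * k, sd = sdE), n, k))
  }
  pas <- mkBlock(nPassengers, passengerLoading, f0,
                 passengerShift * gt + delta * Ct)
  nul <- mkBlock(nNull, nullLoading, f0, delta * Ct)
  drv <- t(driverLoading * f0 + d0 + delta * Ct)
  rownames(drv) <- paste0("driver_", seq_len(nDrivers))
  if (!is.null(pas)) rownames(pas) <- paste0("passenger_", seq_len(nPassengers))
  if (!is.null(nul)) rownames(nul) <- paste0("null_", seq_len(nNull))
  vals <- rbind(drv, pas, nul)
  roles <- c(rep("driver", nDrivers), rep("passenger", nPassengers),
             rep("null", nNull))
  if (nBackground > 0) {
    bg <- matrix(rnorm(nBackground * n), nBackground, n)
    rownames(bg) <- paste0("bg_g", seq_len(nBackground))
    vals <- rbind(vals, bg)
    roles <- c(roles, rep("background", nBackground))
  }
  colnames(vals) <- paste0("s", seq_len(n))
  phd <- data.frame(group = ifelse(g == 1, "case", "ctrl"),
                    conf = factor(ifelse(C == 1, "c1", "c0")),
                    row.names = colnames(vals))
  inModule <- roles != "background"
  list(matrix = OmicsMatrix(vals, omicLabel = "RNA"),
       phenotypes = PhenotypeTable(phd, response = "group",
                                   confounders = "conf"),
       truth = data.frame(feature = rownames(vals), role = roles,
                          stringsAsFactors = FALSE),
       moduleLabels = setNames(ifelse(inModule, "ME1", "ME0"),
                               rownames(vals)))
}

#' Simulate multi-omic data with shared sample clusters
#'
#' Every omic carries the same sample partition: each cluster shifts a
#' subset of informative features by a cluster-specific center drawn
#' with sd \code{separation}; all other variation is unit Gaussian
#' noise.
#'
#' @param clusterSizes integer vector of samples per cluster.
#' @param omics data.frame with columns \code{label}, \code{nFeatures},
#'   \code{nInformative}.
#' @param separation sd of cluster-center shifts, in noise-sd units.
#' @param seed RNG seed.
#' @return list: \code{omics} (named list of \linkS4class{OmicsMatrix})
#'   and \code{truth} (integer cluster label per sample).
#' @export
simulateMultiomicsClusters <- function(clusterSizes = c(50, 50, 50),
                                       omics = data.frame(
                                         label = c("RNA", "DNAm"),
                                         nFeatures = c(200, 200),
                                         nInformative = c(40, 40)),
                                       separation = 8, seed = 1) {
  set.seed(seed)
  n <- sum(clusterSizes)
  cl <- rep(seq_along(clusterSizes), clusterSizes)
  sids <- paste0("s", seq_len(n))
  out <- list()
  for (i in seq_len(nrow(omics))) {
    p <- omics$nFeatures[i]; pi <- omics$nInformative[i]
    centers <- matrix(rnorm(length(clusterSizes) * pi, sd = separation),
                      length(clusterSizes), pi)
    x <- matrix(rnorm(n * p), p, n)
    x[seq_len(pi), ] <- x[seq_len(pi), ] + t(centers[cl, , drop = FALSE])
    rownames(x) <- paste0(omics$label[i], "_g", seq_len(p))
    colnames(x) <- sids
    out[[omics$label[i]]] <- OmicsMatrix(x, omicLabel = omics$label[i])
  }
  list(omics = out, truth = setNames(cl, sids))
}

#' Simulate imbalanced two-or-more-class data
#'
#' Class means differ by \code{classSep} noise-sd units on the
#' informative features; smaller \code{classSep} means more class
#' overlap (higher Bayes error), monotonically.
#'
#' @param classSizes named or unnamed integer vector of class sizes
#'   (default c(400, 40)).
#' @param nFeatures total features (default 200).
#' @param nInformative features carrying the class signal (default 10).
#' @param classSep per-feature mean separation in sd units (default 0.5).
#' @param seed RNG seed.
#' @return list: \code{matrix} (\linkS4class{OmicsMatrix}) and
#'   \code{labels} (factor per sample).
#' @export
simulateImbalancedClasses <- function(classSizes = c(400, 40),
                                      nFeatures = 200, nInformative = 10,
                                      classSep = 0.5, seed = 1) {
  set.seed(seed)
  k <- length(classSizes)
  if (is.null(names(classSizes)))
    names(classSizes) <- paste0("class", seq_len(k))
  n <- sum(classSizes)
  lab <- factor(rep(names(classSizes), classSizes),
                levels = names(classSizes))
  x <- matrix(rnorm(nFeatures * n), nFeatures, n)
  for (i in seq_len(k))
    x[seq_len(nInformative), lab == names(classSizes)[i]] <-
      x[seq_len(nInformative), lab == names(classSizes)[i]] +
      (i - 1) * classSep
  rownames(x) <- paste0("g", seq_len(nFeatures))
  colnames(x) <- paste0("s", seq_len(n))
  names(lab) <- colnames(x)
  list(matrix = OmicsMatrix(x, omicLabel = "RNA"), labels = lab)
}
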