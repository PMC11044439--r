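## Network-topology-aware gene-set annotation. Each within-module edge
## (gene pair) carries the intersection of its two genes' function
## terms; a term's weight is the sum of its edges' weights. Significance
## by (i) shuffling the weight vector over all module edges (term
## assignments fixed) or (ii) a hypergeometric test of the term's edge
## count against a background edge set. A plain gene-level
## hypergeometric over-representation test is also provided.

.termIndex <- function(gs) {
  # gene -> integer term indices
  genes <- unlist(gs@members, use.names = FALSE)
  idx <- rep(seq_along(gs@members), lengths(gs@members))
  split(idx, genes)
}

#' Build the edge-to-term map for one module
#'
#' All within-module feature pairs with weight at least \code{minWeight}
#' become edges (canonical i < j order); an edge's terms are the
#' intersection of its two genes' term sets, so edges touching an
#' unannotated gene carry no term.
#'
#' @param ms a \linkS4class{ModuleSet} whose network holds the weights.
#' @param moduleLabel module to map.
#' @param gs a \linkS4class{GeneSets} in the features' namespace.
#' @param weightSource "tom" (default; the module-defining similarity)
#'   or "adjacency".
#' @param minWeight minimum edge weight (default 0 = complete graph).
#' @return An \linkS4class{EdgeTermMap}.
#' @export
buildEdgeTermMap <- function(ms, moduleLabel, gs,
                             weightSource = c("tom", "adjacency"),
                             minWeight = 0) {
  weightSource <- match.arg(weightSource)
  asg <- moduleAssignment(ms)
  feats <- sort(names(asg)[asg == moduleLabel])
  if (!length(feats)) stop("module '", moduleLabel, "' not found")
  net <- ms@network
  if (!is(net, "CoexNetwork")) stop("ModuleSet carries no network")
  W <- if (weightSource == "tom") tomMatrix(net) else adjacencyMatrix(net)
  if (is.null(W)) stop("requested weight source not computed")
  W <- W[feats, feats, drop = FALSE]
  pair <- which(upper.tri(W), arr.ind = TRUE)
  wt <- W[pair]
  keep <- wt >= minWeight
  pair <- pair[keep, , drop = FALSE]
  wt <- wt[keep]
  f1 <- feats[pair[, 1L]]; f2 <- feats[pair[, 2L]]
  edges <- data.frame(feature1 = pmin(f1, f2), feature2 = pmax(f1, f2),
                      weight = wt, stringsAsFactors = FALSE)
  ord <- order(edges$feature1, edges$feature2)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  ti <- .termIndex(gs)
  termEdges <- vector("list", length(gs@termIds))
  names(termEdges) <- gs@termIds
  acc <- rep(list(integer(0)), length(gs@termIds))
  for (e in seq_len(nrow(edges))) {
    t1 <- ti[[edges$feature1[e]]]
    t2 <- ti[[edges$feature2[e]]]
    if (is.null(t1) || is.null(t2)) next
    for (tt in intersect(t1, t2)) acc[[tt]] <- c(acc[[tt]], e)
  }
  names(acc) <- gs@termIds
  new("EdgeTermMap", edges = edges, termEdges = acc[lengths(acc) > 0],
      moduleLabel = moduleLabel)
}

#' Edge-weight shuffling test of term weights
#'
#' A term's observed weight is the sum of the weights of the edges
#' carrying it. Each shuffle permutes the weight vector uniformly over
#' all module edges while the term assignments stay fixed; the empirical
#' p is \eqn{(1 + \#\{null \ge observed\})/(n_{shuffle} + 1)} (so p is
#' never 0), BH-adjusted across terms. A term covering every edge has a
#' permutation-invariant weight and p = 1.
#'
#' @param etm an \linkS4class{EdgeTermMap} with >= 2 edges and >= 1 term.
#' @param nShuffle number of shuffles (default 1000).
#' @param seed RNG seed.
#' @param keepNull keep the per-term null weights in the result
#'   (attribute \code{nullWeights}).
#' @return data.frame (term, nEdges, observedWeight, p, pAdj).
#' @export
edgeShuffleTest <- function(etm, nShuffle = 1000, seed = 1,
                            keepNull = FALSE) {
  w <- etm@edges$weight
  if (length(w) < 2L) stop("need at least 2 edges")
  te <- etm@termEdges
  if (!length(te)) stop("no term maps to any edge")
  obs <- vapply(te, function(ix) sum(w[ix]), 0)
  M <- matrix(0, length(te), nShuffle)
  set.seed(seed)
  total <- sum(w)
  for (s in seq_len(nShuffle)) {
    wp <- w[sample.int(length(w))]
    stopifnot(abs(sum(wp) - total) < 1e-8 * max(1, abs(total)))
    M[, s] <- vapply(te, function(ix) sum(wp[ix]), 0)
  }
  exceed <- rowSums(M >= obs - 1e-12)
  p <- (1 + exceed) / (nShuffle + 1)
  res <- data.frame(term = names(te), nEdges = lengths(te),
                    observedWeight = obs, p = p,
                    pAdj = p.adjust(p, "BH"), row.names = NULL,
                    stringsAsFactors = FALSE)
  if (keepNull) attr(res, "nullWeights") <- M
  res
}

#' Hypergeometric test of term edge counts against a background
#'
#' Per term: upper-tail \eqn{P(X \ge k)} with k = module edges carrying
#' the term, K = background edges carrying it, n = module edge count,
#' N = background edge count; terms with K = 0 are skipped; BH across
#' the tested terms. The default background in a pipeline run is the
#' union of all modules' within-module edges.
#'
#' @param etm module \linkS4class{EdgeTermMap}.
#' @param background background \linkS4class{EdgeTermMap} (must contain
#'   the module's edges).
#' @return data.frame (term, k, K, n, N, p, pAdj).
#' @export
edgeHypergeomTest <- function(etm, background) {
  n <- nrow(etm@edges)
  N <- nrow(background@edges)
  if (N < n) stop("background has fewer edges than the module")
  terms <- names(background@termEdges)
  k <- vapply(terms, function(tt) {
    ix <- etm@termEdges[[tt]]
    if (is.null(ix)) 0L else length(ix)
  }, 0L)
  K <- lengths(background@termEdges)
  keep <- K > 0
  k <- k[keep]; K <- K[keep]; terms <- terms[keep]
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  data.frame(term = terms, k = k, K = K, n = n, N = N, p = p,
             pAdj = p.adjust(p, "BH"), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Gene-level hypergeometric over-representation test
#'
#' Standard one-sided over-representation of a gene list against a
#' universe, per term, BH-adjusted. Terms disjoint from the universe
#' are skipped.
#'
#' @param genes character vector of selected gene ids (subset of
#'   \code{universe}; non-empty).
#' @param universe character vector of background gene ids.
#' @param gs a \linkS4class{GeneSets}.
#' @return data.frame (term, k, K, n, N, p, pAdj).
#' @export
geneHypergeomEnrich <- function(genes, universe, gs) {
  genes <- unique(genes)
  universe <- unique(universe)
  if (!length(genes)) stop("empty gene list")
  if (!all(genes %in% universe)) stop("genes must be a subset of universe")
  N <- length(universe)
  n <- length(genes)
  K <- vapply(gs@members, function(mb) sum(mb %in% universe), 0L)
  keep <- K > 0
  terms <- gs@termIds[keep]
  K <- K[keep]
  k <- vapply(gs@members[keep], function(mb) sum(genes %in% mb), 0L)
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  data.frame(term = terms, k = k, K = K, n = n, N = N, p = p,
             pAdj = p.adjust(p, "BH"), row.names = NULL,
             stringsAsFactors = FALSE)
}
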