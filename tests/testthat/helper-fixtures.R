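# Shared small fixtures for the unit tests.

randomOmics <- function(nFeatures = 30, nSamples = 20, seed = 1,
                        omicLabel = "RNA") {
  set.seed(seed)
  x <- matrix(rnorm(nFeatures * nSamples), nFeatures, nSamples,
              dimnames = list(paste0("g", seq_len(nFeatures)),
                              paste0("s", seq_len(nSamples))))
  OmicsMatrix(x, omicLabel = omicLabel)
}

binaryPheno <- function(sampleIds, seed = 1, withConf = FALSE) {
  set.seed(seed)
  n <- length(sampleIds)
  d <- data.frame(group = sample(c("case", "ctrl"), n, replace = TRUE),
                  row.names = sampleIds)
  # guarantee both levels
  d$group[1:2] <- c("case", "ctrl")
  conf <- character(0)
  if (withConf) {
    d$batch <- sample(c("b1", "b2"), n, replace = TRUE)
    d$batch[1:2] <- c("b1", "b2")
    conf <- "batch"
  }
  PhenotypeTable(d, response = "group", confounders = conf)
}

# exact partition agreement up to label names: every true class maps to
# exactly one predicted label and vice versa
samePartition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

bruteTOM <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - 1
  tom <- matrix(0, n, n, dimnames = dimnames(a))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { tom[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}
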