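#' @import methods
#' @importFrom stats cor sd var quantile rnorm runif rbinom median
#'   coef fitted residuals pf pt phyper p.adjust hclust cutree as.dist
#'   dist kmeans glm binomial lm model.matrix plogis dnorm setNames
#'   complete.cases contr.sum pnorm
#' @importFrom utils read.delim write.table head
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' OmicsMatrix: one omic's feature-by-sample value matrix
#'
#' Container for a single omic layer (e.g. log2(TPM+1) expression, DNA
#' methylation beta values, miRNA counts): a numeric matrix with features
#' in rows and samples in columns, plus a label naming the omic.
#'
#' @slot assay numeric matrix, features x samples, with unique row and
#'   column names and no non-finite entries.
#' @slot omicLabel single character, e.g. \code{"RNA"}, \code{"DNAm"}.
#' @export
setClass("OmicsMatrix",
  representation(assay = "matrix", omicLabel = "character"))

setValidity("OmicsMatrix", function(object) {
  a <- object@assay
  if (!is.numeric(a)) return("assay must be numeric")
  if (is.null(rownames(a)) || is.null(colnames(a)))
    return("assay must carry feature (row) and sample (column) names")
  dupf <- unique(rownames(a)[duplicated(rownames(a))])
  if (length(dupf))
    return(paste0("duplicate feature ids: ", paste(dupf, collapse = ", ")))
  dups <- unique(colnames(a)[duplicated(colnames(a))])
  if (length(dups))
    return(paste0("duplicate sample ids: ", paste(dups, collapse = ", ")))
  if (any(!is.finite(a)))
    return("assay contains non-finite values; impute or drop them first")
  if (length(object@omicLabel) != 1L) return("omicLabel must be length 1")
  TRUE
})

#' Construct an OmicsMatrix
#'
#' @param values numeric matrix, features x samples.
#' @param featureIds optional row names (defaults to rownames of values).
#' @param sampleIds optional column names.
#' @param omicLabel omic label string.
#' @return An \linkS4class{OmicsMatrix}.
#' @examples
#' m <- OmicsMatrix(matrix(rnorm(6), 3, 2,
#'   dimnames = list(paste0("g", 1:3), paste0("s", 1:2))), omicLabel = "RNA")
#' dim(m)
#' @export
OmicsMatrix <- function(values, featureIds = rownames(values),
                        sampleIds = colnames(values), omicLabel = "omic") {
  values <- as.matrix(values)
  rownames(values) <- featureIds
  colnames(values) <- sampleIds
  new("OmicsMatrix", assay = values, omicLabel = omicLabel)
}

#' PhenotypeTable: per-sample response and confounders
#'
#' Holds one response variable (binary factor or continuous) and zero or
#' more confounder variables, indexed by sample id.
#'
#' @slot data data.frame with one row per sample; row names are sample ids.
#' @slot response name of the response column.
#' @slot confounders names of confounder columns (possibly empty).
#' @export
setClass("PhenotypeTable",
  representation(data = "data.frame", response = "character",
                 confounders = "character"))

setValidity("PhenotypeTable", function(object) {
  d <- object@data
  if (is.null(rownames(d))) return("data must carry sample ids as row names")
  if (anyDuplicated(rownames(d))) return("duplicate sample ids")
  if (!(object@response %in% colnames(d)))
    return(paste0("response column '", object@response, "' not found"))
  miss <- setdiff(object@confounders, colnames(d))
  if (length(miss))
    return(paste0("confounder columns missing: ", paste(miss, collapse = ", ")))
  r <- d[[object@response]]
  if (is.factor(r) && nlevels(r) != 2L)
    return("a factor response must have exactly two levels")
  TRUE
})

#' Construct a PhenotypeTable
#'
#' A two-level response is coerced to a factor whose reference level is
#' first in sort order (deterministic effect signs); responses with more
#' distinct non-numeric values are rejected, numeric responses with more
#' than two distinct values stay continuous. Confounders with at most 10
#' distinct non-numeric values become factors.
#'
#' @param data data.frame with sample ids as row names.
#' @param response response column name.
#' @param confounders character vector of confounder column names.
#' @param referenceLevel optional reference level for a binary response.
#' @return A \linkS4class{PhenotypeTable}.
#' @export
PhenotypeTable <- function(data, response, confounders = character(0),
                           referenceLevel = NULL) {
  stopifnot(is.data.frame(data))
  r <- data[[response]]
  if (is.null(r)) stop("response column '", response, "' not found")
  ur <- unique(r[!is.na(r)])
  if (length(ur) < 2L) stop("response has one level")
  if (is.numeric(r) && length(ur) > 2L) {
    # continuous response, leave as is
  } else {
    if (length(ur) > 2L)
      stop("response has ", length(ur), " levels; a binary response needs 2")
    lev <- sort(as.character(ur))
    if (!is.null(referenceLevel)) {
      if (!referenceLevel %in% lev) stop("referenceLevel not a response level")
      lev <- c(referenceLevel, setdiff(lev, referenceLevel))
    }
    data[[response]] <- factor(as.character(r), levels = lev)
  }
  for (cc in confounders) {
    v <- data[[cc]]
    if (!is.numeric(v)) {
      if (length(unique(v)) > 10L)
        stop("confounder '", cc, "' has >10 distinct non-numeric values")
      data[[cc]] <- factor(v)
    }
  }
  new("PhenotypeTable", data = data, response = response,
      confounders = confounders)
}

#' GeneSets: a collection of gene-set (function term) definitions
#'
#' @slot termIds character vector of term ids.
#' @slot termNames character vector of term descriptions.
#' @slot members list of character vectors of member gene ids.
#' @export
setClass("GeneSets",
  representation(termIds = "character", termNames = "character",
                 members = "list"))

setValidity("GeneSets", function(object) {
  n <- length(object@termIds)
  if (length(object@termNames) != n || length(object@members) != n)
    return("termIds, termNames and members must have equal length")
  if (anyDuplicated(object@termIds)) return("duplicate term ids")
  if (n && any(lengths(object@members) < 1L))
    return("every term needs at least one member gene")
  TRUE
})

#' Construct a GeneSets collection
#' @param termIds term ids.
#' @param members list of member-gene character vectors (deduplicated).
#' @param termNames optional descriptions (default the ids).
#' @return A \linkS4class{GeneSets}.
#' @export
GeneSets <- function(termIds, members, termNames = termIds) {
  new("GeneSets", termIds = as.character(termIds),
      termNames = as.character(termNames),
      members = lapply(members, function(x) unique(as.character(x))))
}

#' CoexNetwork: soft-thresholded co-expression network
#'
#' @slot adjacency symmetric matrix in [0,1] with unit diagonal,
#'   \code{|cor|^beta} (unsigned) or \code{((1+cor)/2)^beta} (signed).
#' @slot tom topological overlap matrix (or NULL before computation).
#' @slot softPower the soft-thresholding power beta.
#' @slot signed logical; signed network flag.
#' @export
setClass("CoexNetwork",
  representation(adjacency = "matrix", tom = "matrixOrNULL",
                 softPower = "numeric", signed = "logical"))

setValidity("CoexNetwork", function(object) {
  a <- object@adjacency
  if (nrow(a) != ncol(a)) return("adjacency must be square")
  if (max(abs(a - t(a))) > 1e-10) return("adjacency must be symmetric")
  if (min(a) < -1e-10 || max(a) > 1 + 1e-10)
    return("adjacency entries must lie in [0,1]")
  if (max(abs(diag(a) - 1)) > 1e-10) return("adjacency diagonal must be 1")
  if (!is.null(object@tom)) {
    tm <- object@tom
    if (max(abs(tm - t(tm))) > 1e-10) return("TOM must be symmetric")
    if (min(tm) < -1e-10 || max(tm) > 1 + 1e-10)
      return("TOM entries must lie in [0,1]")
  }
  TRUE
})

#' ModuleSet: module assignment, eigengenes and the underlying network
#'
#' Modules are labelled ME1..MEk by decreasing size; ME0 collects
#' unassigned (grey) features. Eigengenes are unit-variance first
#' principal components of each module's standardized feature submatrix,
#' sign-aligned with the module mean profile.
#'
#' @slot assignment named character vector: feature id -> module label.
#' @slot eigengenes matrix, modules x samples.
#' @slot varianceExplained named numeric in [0,1] per module.
#' @slot network the \linkS4class{CoexNetwork} the modules came from
#'   (may have empty slots when eigengenes were computed directly).
#' @export
setClass("ModuleSet",
  representation(assignment = "character", eigengenes = "matrix",
                 varianceExplained = "numeric", network = "ANY"))

setValidity("ModuleSet", function(object) {
  if (is.null(names(object@assignment)))
    return("assignment must be named by feature id")
  if (anyDuplicated(names(object@assignment)))
    return("a feature may appear in exactly one module")
  em <- rownames(object@eigengenes)
  if (length(em) && anyDuplicated(em)) return("duplicate eigengene labels")
  TRUE
})

#' EdgeTermMap: within-module edges annotated with function terms
#'
#' Each edge (feature pair, i < j canonical order) carries a weight and
#' the intersection of its two genes' term sets; terms index back into
#' the edge list.
#'
#' @slot edges data.frame with columns feature1, feature2, weight.
#' @slot termEdges named list: term id -> integer indices into edges.
#' @slot moduleLabel the module the map was built from.
#' @export
setClass("EdgeTermMap",
  representation(edges = "data.frame", termEdges = "list",
                 moduleLabel = "character"))

#' EnsembleModel: multi-omics ensemble classifier
#'
#' @slot mode 1 (bagging-SMOTE balanced), 2 (plain bagging) or 3 (single).
#' @slot learner "svm" (linear-kernel, probability outputs) or "mlr"
#'   (multinomial logistic regression).
#' @slot classLevels response class labels, in training order.
#' @slot omics named list, one entry per omic: screened features,
#'   recurrent feature set, fitted base learners, training feature means/sds.
#' @slot seed integer seed the model was trained under.
#' @export
setClass("EnsembleModel",
  representation(mode = "numeric", learner = "character",
                 classLevels = "character", omics = "list",
                 seed = "numeric"))

setValidity("EnsembleModel", function(object) {
  nb <- if (object@mode %in% c(1, 2)) 10L else 1L
  for (om in object@omics) {
    if (length(om$learners) != nb)
      return(sprintf("mode %d requires %d base learners", object@mode, nb))
    if (!all(om$recurrent %in% om$screened))
      return("recurrent feature set must lie inside the screened set")
  }
  TRUE
})

#' MergedRepresentation: samples-by-components matrix merged across omics
#'
#' @slot matrix samples x components, columns standardized.
#' @slot provenance data.frame (omicLabel, nComponents, method).
#' @export
setClass("MergedRepresentation",
  representation(matrix = "matrix", provenance = "data.frame"))

setValidity("MergedRepresentation", function(object) {
  m <- object@matrix
  if (ncol(m) > 0 && nrow(m) > 1) {
    mu <- colMeans(m); s <- apply(m, 2, sd)
    if (max(abs(mu)) > 1e-8 || max(abs(s - 1)) > 1e-6)
      return("columns must be standardized (mean 0, sd 1)")
  }
  TRUE
})
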