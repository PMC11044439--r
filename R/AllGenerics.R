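#' @rdname OmicsMatrix-class
#' @param object,x an object.
#' @export
setGeneric("assayValues", function(x) standardGeneric("assayValues"))
#' @rdname OmicsMatrix-class
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @rdname OmicsMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname OmicsMatrix-class
#' @export
setGeneric("omicLabel", function(x) standardGeneric("omicLabel"))

#' @rdname PhenotypeTable-class
#' @param x a PhenotypeTable.
#' @export
setGeneric("responseValues", function(x) standardGeneric("responseValues"))
#' @rdname PhenotypeTable-class
#' @export
setGeneric("confounderFrame", function(x) standardGeneric("confounderFrame"))

#' @rdname ModuleSet-class
#' @param x a ModuleSet or CoexNetwork.
#' @export
setGeneric("moduleAssignment", function(x) standardGeneric("moduleAssignment"))
#' @rdname ModuleSet-class
#' @export
setGeneric("eigengenes", function(x) standardGeneric("eigengenes"))
#' @rdname ModuleSet-class
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))
#' @rdname ModuleSet-class
#' @export
setGeneric("varianceExplained", function(x) standardGeneric("varianceExplained"))
#' @rdname CoexNetwork-class
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))
#' @rdname CoexNetwork-class
#' @export
setGeneric("tomMatrix", function(x) standardGeneric("tomMatrix"))

#' @rdname OmicsMatrix-class
#' @export
setMethod("assayValues", "OmicsMatrix", function(x) x@assay)
#' @rdname OmicsMatrix-class
#' @export
setMethod("featureIds", "OmicsMatrix", function(x) rownames(x@assay))
#' @rdname OmicsMatrix-class
#' @export
setMethod("sampleIds", "OmicsMatrix", function(x) colnames(x@assay))
#' @rdname OmicsMatrix-class
#' @export
setMethod("omicLabel", "OmicsMatrix", function(x) x@omicLabel)
#' @rdname OmicsMatrix-class
#' @export
setMethod("dim", "OmicsMatrix", function(x) dim(x@assay))

#' @rdname PhenotypeTable-class
#' @export
setMethod("sampleIds", "PhenotypeTable", function(x) rownames(x@data))
#' @rdname PhenotypeTable-class
#' @export
setMethod("responseValues", "PhenotypeTable", function(x) x@data[[x@response]])
#' @rdname PhenotypeTable-class
#' @export
setMethod("confounderFrame", "PhenotypeTable",
          function(x) x@data[, x@confounders, drop = FALSE])

#' @rdname ModuleSet-class
#' @export
setMethod("moduleAssignment", "ModuleSet", function(x) x@assignment)
#' @rdname ModuleSet-class
#' @export
setMethod("eigengenes", "ModuleSet", function(x) x@eigengenes)
#' @rdname ModuleSet-class
#' @export
setMethod("moduleLabels", "ModuleSet",
          function(x) rownames(x@eigengenes))
#' @rdname ModuleSet-class
#' @export
setMethod("varianceExplained", "ModuleSet", function(x) x@varianceExplained)

#' @rdname CoexNetwork-class
#' @export
setMethod("adjacencyMatrix", "CoexNetwork", function(x) x@adjacency)
#' @rdname CoexNetwork-class
#' @export
setMethod("tomMatrix", "CoexNetwork", function(x) x@tom)

setMethod("show", "OmicsMatrix", function(object) {
  cat("OmicsMatrix '", object@omicLabel, "': ", nrow(object@assay),
      " features x ", ncol(object@assay), " samples\n", sep = "")
})

setMethod("show", "PhenotypeTable", function(object) {
  r <- object@data[[object@response]]
  cat("PhenotypeTable: ", nrow(object@data), " samples; response '",
      object@response, "' (",
      if (is.factor(r)) paste0("binary: ", paste(levels(r), collapse = "/"))
      else "continuous",
      "); ", length(object@confounders), " confounder(s)\n", sep = "")
})

setMethod("show", "GeneSets", function(object) {
  cat("GeneSets: ", length(object@termIds), " terms; median set size ",
      if (length(object@termIds)) median(lengths(object@members)) else 0,
      "\n", sep = "")
})

setMethod("show", "CoexNetwork", function(object) {
  cat("CoexNetwork: ", nrow(object@adjacency), " features; ",
      if (object@signed) "signed" else "unsigned",
      ", beta = ", object@softPower,
      if (is.null(object@tom)) "; TOM not computed" else "; TOM computed",
      "\n", sep = "")
})

setMethod("show", "ModuleSet", function(object) {
  tb <- table(object@assignment)
  cat("ModuleSet: ", length(object@assignment), " features in ",
      sum(names(tb) != "ME0"), " modules",
      if ("ME0" %in% names(tb)) paste0(" (+", tb[["ME0"]], " unassigned)"),
      "\n", sep = "")
})

setMethod("show", "EnsembleModel", function(object) {
  cat("EnsembleModel: mode ", object@mode, ", learner '", object@learner,
      "', ", length(object@omics), " omic(s), classes ",
      paste(object@classLevels, collapse = "/"), "\n", sep = "")
})

setMethod("show", "MergedRepresentation", function(object) {
  cat("MergedRepresentation: ", nrow(object@matrix), " samples x ",
      ncol(object@matrix), " components\n", sep = "")
})
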