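## Readers and writers for the TSV/CSV dialects the package consumes:
## feature-by-sample matrices, phenotype tables, GMT gene sets and
## probe-to-gene maps. Output files carry a '#' header comment with the
## package version (and seed where randomness was involved); readers
## skip '#' lines.

.delim <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

.versionComment <- function(seed = NULL) {
  v <- as.character(utils::packageVersion("medwgcna"))
  s <- if (is.null(seed)) "" else paste0("; seed=", seed)
  paste0("# medwgcna ", v, s)
}

#' Read a feature-by-sample matrix
#'
#' Expects delimited text with a header row of sample ids and a leading
#' column of feature ids. Lines starting with '#' are skipped.
#'
#' @param path file path (.tsv/.txt tab-separated, .csv comma-separated).
#' @param samplesInRows set TRUE when the file stores samples in rows;
#'   the matrix is transposed so features end up in rows.
#' @param omicLabel omic label attached to the result.
#' @return An \linkS4class{OmicsMatrix}.
#' @export
readMatrix <- function(path, samplesInRows = FALSE, omicLabel = "omic") {
  d <- read.delim(path, sep = .delim(path), header = TRUE, row.names = NULL,
                  comment.char = "#", check.names = FALSE,
                  stringsAsFactors = FALSE)
  ids <- as.character(d[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate ", if (samplesInRows) "sample" else "feature",
         " ids in ", path, ": ", paste(dup, collapse = ", "))
  vals <- d[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "NA")
      if (length(bad))
        stop("non-numeric cell at row ", bad[1L], ", column '",
             colnames(vals)[j], "' in ", path, ": '", v[bad[1L]], "'")
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (samplesInRows) m <- t(m)
  OmicsMatrix(m, omicLabel = omicLabel)
}

#' Write an OmicsMatrix (or plain matrix) to delimited text
#'
#' @param m an \linkS4class{OmicsMatrix} or named numeric matrix.
#' @param path output path; extension decides the delimiter.
#' @param idColumn name for the leading id column.
#' @param seed optional seed recorded in the header comment.
#' @param digits significant digits used for formatting (default 10, so
#'   a write/read round trip preserves values to that precision).
#' @return \code{path}, invisibly.
#' @export
writeMatrix <- function(m, path, idColumn = "feature", seed = NULL,
                        digits = 10) {
  vals <- if (is(m, "OmicsMatrix")) assayValues(m) else m
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.versionComment(seed), con)
  sep <- .delim(path)
  writeLines(paste(c(idColumn, colnames(vals)), collapse = sep), con)
  body <- apply(signif(vals, digits), 1, paste, collapse = sep)
  writeLines(paste(rownames(vals), body, sep = sep), con)
  invisible(path)
}

#' Write a result data.frame to delimited text
#' @param d data.frame.
#' @param path output path.
#' @param seed optional seed recorded in the header comment.
#' @return \code{path}, invisibly.
#' @export
writeResultTable <- function(d, path, seed = NULL) {
  con <- file(path, "w")
  writeLines(.versionComment(seed), con)
  close(con)
  suppressWarnings(write.table(d, path, sep = .delim(path), quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Read a phenotype table
#'
#' First column (or \code{idColumn}) holds sample ids. The response is
#' coerced to a two-level factor (reference = first level in sort order)
#' when it has exactly two distinct values; otherwise it must be numeric
#' and is kept continuous. Non-numeric confounders with at most 10
#' distinct values become factors.
#'
#' @param path file path.
#' @param response response column name.
#' @param confounders confounder column names.
#' @param idColumn sample-id column name (default: first column).
#' @param referenceLevel optional reference level for a binary response.
#' @return A \linkS4class{PhenotypeTable}.
#' @export
readPhenotypes <- function(path, response, confounders = character(0),
                           idColumn = NULL, referenceLevel = NULL) {
  d <- read.delim(path, sep = .delim(path), header = TRUE,
                  comment.char = "#", check.names = FALSE,
                  stringsAsFactors = FALSE)
  if (is.null(idColumn)) idColumn <- colnames(d)[1L]
  ids <- as.character(d[[idColumn]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in ", path)
  d <- d[, setdiff(colnames(d), idColumn), drop = FALSE]
  rownames(d) <- ids
  PhenotypeTable(d, response = response, confounders = confounders,
                 referenceLevel = referenceLevel)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one term per line, tab-separated fields
#' \code{term_id<TAB>description<TAB>gene1<TAB>gene2...}. Duplicate
#' member genes within a term are removed; file order is preserved.
#'
#' @param path GMT file path.
#' @return A \linkS4class{GeneSets}.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(GeneSets(character(0), list(), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 tab-separated fields")
  GeneSets(termIds = vapply(parts, `[[`, "", 1L),
           termNames = vapply(parts, `[[`, "", 2L),
           members = lapply(parts, function(p) unique(p[-(1:2)])))
}

#' Read a probe-to-gene mapping table
#'
#' Two columns (probe id, gene id); extra columns ignored; duplicate
#' (probe, gene) pairs removed. A probe may map to several genes.
#'
#' @param path file path.
#' @return data.frame with columns \code{probe}, \code{gene}.
#' @export
readProbeGeneMap <- function(path) {
  d <- read.delim(path, sep = .delim(path), header = TRUE,
                  comment.char = "#", stringsAsFactors = FALSE)
  map <- data.frame(probe = as.character(d[[1L]]),
                    gene = as.character(d[[2L]]),
                    stringsAsFactors = FALSE)
  unique(map)
}

#' Compress probe-level values to gene level
#'
#' One output row per gene with at least one mapped probe present in the
#' matrix; the gene's value per sample is the arithmetic mean over its
#' mapped probes. A probe mapping to k genes contributes to all k rows;
#' unmapped probes are dropped.
#'
#' @param m an \linkS4class{OmicsMatrix} whose features are probe ids.
#' @param map data.frame (probe, gene) as from \code{readProbeGeneMap}.
#' @return An \linkS4class{OmicsMatrix} with gene-level rows.
#' @export
probesToGenes <- function(m, map) {
  vals <- assayValues(m)
  map <- unique(map[, c("probe", "gene")])
  map <- map[map$probe %in% rownames(vals), , drop = FALSE]
  if (!nrow(map))
    stop("no overlap between the map's probes and the matrix features")
  genes <- sort(unique(map$gene))
  out <- matrix(0, length(genes), ncol(vals),
                dimnames = list(genes, colnames(vals)))
  for (g in genes) {
    pr <- map$probe[map$gene == g]
    out[g, ] <- colMeans(vals[pr, , drop = FALSE])
  }
  OmicsMatrix(out, omicLabel = omicLabel(m))
}

#' Align an OmicsMatrix with a PhenotypeTable by sample id
#'
#' Every matrix sample must be covered by the phenotype table (silent
#' dropping hides bugs); the phenotype rows are reordered to the matrix
#' column order.
#'
#' @param m an \linkS4class{OmicsMatrix}.
#' @param ph a \linkS4class{PhenotypeTable}.
#' @return list with the matrix and the reordered PhenotypeTable.
#' @export
alignSamples <- function(m, ph) {
  ms <- sampleIds(m)
  missing <- setdiff(ms, sampleIds(ph))
  if (length(missing))
    stop("samples missing from the phenotype table: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...")
  d <- ph@data[ms, , drop = FALSE]
  list(matrix = m,
       phenotypes = new("PhenotypeTable", data = d, response = ph@response,
                        confounders = ph@confounders))
}
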