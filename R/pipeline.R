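## End-to-end orchestration: modules -> differential eigengenes ->
## within-module differential features -> (optional) mediation screen
## -> (optional) network-based annotation, writing one TSV table per
## stage plus a machine-readable manifest with checksums.

#' Assemble a run configuration
#'
#' @param matrixPath path to the feature-by-sample matrix (or an
#'   \linkS4class{OmicsMatrix} passed directly).
#' @param phenotypePath path to the phenotype table (or a
#'   \linkS4class{PhenotypeTable}).
#' @param response,confounders response / confounder column names (used
#'   when reading from file).
#' @param outDir output directory.
#' @param power soft power or "auto".
#' @param minSize minimum module size.
#' @param cutHeight static cut height or NULL.
#' @param mediation run the mediation screen on differential modules.
#' @param nBoot bootstrap resamples per mediation model.
#' @param gmtPath optional GMT path (or \linkS4class{GeneSets}) enabling
#'   annotation.
#' @param annotationMethod "shuffle" or "hypergeom".
#' @param nShuffle shuffles for the edge-weight test.
#' @param seed run seed, recorded in every output.
#' @return a \code{runConfig} list.
#' @export
runConfig <- function(matrixPath, phenotypePath, response,
                      confounders = character(0), outDir, power = "auto",
                      minSize = 30, cutHeight = NULL, mediation = TRUE,
                      nBoot = 500, gmtPath = NULL,
                      annotationMethod = c("shuffle", "hypergeom"),
                      nShuffle = 1000, seed = 1) {
  cfg <- list(matrixPath = matrixPath, phenotypePath = phenotypePath,
              response = response, confounders = confounders,
              outDir = outDir, power = power, minSize = minSize,
              cutHeight = cutHeight, mediation = mediation,
              nBoot = nBoot, gmtPath = gmtPath,
              annotationMethod = match.arg(annotationMethod),
              nShuffle = nShuffle, seed = seed)
  for (p in c("matrixPath", "phenotypePath", "gmtPath")) {
    v <- cfg[[p]]
    if (is.character(v) && !file.exists(v))
      stop("configured file does not exist: ", v)
  }
  class(cfg) <- "runConfig"
  cfg
}

#' Read a run configuration from a YAML file
#' @param path YAML file with the fields of \code{\link{runConfig}}.
#' @return a \code{runConfig} list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(runConfig, y)
}

.stageLog <- function(log, stage, msg) {
  line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", stage,
                 "] ", msg)
  message(line)
  cat(line, "\n", file = log, append = TRUE)
}

#' Run the causal co-expression pipeline
#'
#' Executes module detection, differential-eigengene testing,
#' within-module differential features for every significant module,
#' the driver/passenger mediation screen (when enabled) and
#' network-based annotation (when a gene-set collection is configured).
#' Any stage error aborts with the stage name; outputs of completed
#' stages are retained. Re-running with the same seed reproduces every
#' table byte for byte.
#'
#' @param cfg a \code{\link{runConfig}}.
#' @return the output directory, invisibly; a \code{manifest.json}
#'   there lists every artifact with its md5 checksum and the seed.
#' @export
runCausalWgcna <- function(cfg) {
  stopifnot(inherits(cfg, "runConfig"))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(cfg$outDir, "run.log")
  if (file.exists(log)) unlink(log)
  artifacts <- character(0)
  stage <- "input"
  result <- tryCatch({
    .stageLog(log, stage, paste0("seed=", cfg$seed))
    m <- if (is(cfg$matrixPath, "OmicsMatrix")) cfg$matrixPath
         else readMatrix(cfg$matrixPath)
    ph <- if (is(cfg$phenotypePath, "PhenotypeTable")) cfg$phenotypePath
          else readPhenotypes(cfg$phenotypePath, response = cfg$response,
                              confounders = cfg$confounders)
    al <- alignSamples(m, ph)
    m <- al$matrix; ph <- al$phenotypes

    stage <- "modules"
    .stageLog(log, stage, "building co-expression modules")
    ms <- buildModules(m, power = cfg$power, minSize = cfg$minSize,
                       cutHeight = cfg$cutHeight)
    mdir <- file.path(cfg$outDir, "modules")
    writeModuleSet(ms, mdir, seed = cfg$seed)
    artifacts <- c(artifacts, file.path(mdir, "assignment.tsv"),
                   file.path(mdir, "eigengenes.tsv"))
    if (!nrow(eigengenes(ms))) stop("no module detected")

    stage <- "diff"
    .stageLog(log, stage, "differential eigengenes and features")
    ddir <- file.path(cfg$outDir, "diff")
    dir.create(ddir, showWarnings = FALSE)
    dmod <- diffModules(ms, ph)
    f <- file.path(ddir, "modules.tsv")
    writeResultTable(dmod, f, seed = cfg$seed)
    artifacts <- c(artifacts, f)
    sigMods <- dmod$unit[dmod$significant]
    featTabs <- list()
    for (mod in sigMods) {
      dft <- diffFeaturesWithinModule(m, ms, mod, ph)
      featTabs[[mod]] <- dft
      f <- file.path(ddir, paste0("features_", mod, ".tsv"))
      writeResultTable(dft, f, seed = cfg$seed)
      artifacts <- c(artifacts, f)
    }

    if (isTRUE(cfg$mediation) && length(sigMods)) {
      stage <- "mediation"
      .stageLog(log, stage, paste0("screening ", length(sigMods),
                                   " differential module(s)"))
      meddir <- file.path(cfg$outDir, "mediation")
      dir.create(meddir, showWarnings = FALSE)
      for (i in seq_along(sigMods)) {
        mod <- sigMods[i]
        scr <- causalScreen(m, ms, featTabs[[mod]], mod, ph,
                            nBoot = cfg$nBoot,
                            seed = cfg$seed + 10000L * i)
        f <- file.path(meddir, paste0(mod, ".tsv"))
        writeResultTable(scr, f, seed = cfg$seed)
        artifacts <- c(artifacts, f)
      }
    }

    if (!is.null(cfg$gmtPath)) {
      stage <- "annotation"
      .stageLog(log, stage, "network-based gene set annotation")
      gs <- if (is(cfg$gmtPath, "GeneSets")) cfg$gmtPath
            else readGmt(cfg$gmtPath)
      adir <- file.path(cfg$outDir, "annotation")
      dir.create(adir, showWarnings = FALSE)
      mods <- moduleLabels(ms)
      maps <- lapply(mods, function(mod)
        buildEdgeTermMap(ms, mod, gs))
      names(maps) <- mods
      if (cfg$annotationMethod == "hypergeom") {
        allEdges <- do.call(rbind, lapply(maps, function(x) x@edges))
        te <- list()
        off <- 0L
        for (mod in mods) {
          for (tt in names(maps[[mod]]@termEdges))
            te[[tt]] <- c(te[[tt]], maps[[mod]]@termEdges[[tt]] + off)
          off <- off + nrow(maps[[mod]]@edges)
        }
        background <- new("EdgeTermMap", edges = allEdges,
                          termEdges = te, moduleLabel = "background")
      }
      for (mod in mods) {
        if (!length(maps[[mod]]@termEdges)) next
        res <- if (cfg$annotationMethod == "shuffle")
          edgeShuffleTest(maps[[mod]], nShuffle = cfg$nShuffle,
                          seed = cfg$seed)
        else edgeHypergeomTest(maps[[mod]], background)
        f <- file.path(adir, paste0(mod, ".tsv"))
        writeResultTable(res, f, seed = cfg$seed)
        artifacts <- c(artifacts, f)
      }
    }

    manifest <- list(seed = cfg$seed,
                     version = as.character(utils::packageVersion("medwgcna")),
                     artifacts = lapply(artifacts, function(a)
                       list(path = sub(paste0("^", cfg$outDir, "/?"), "", a),
                            md5 = unname(tools::md5sum(a)))))
    jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    .stageLog(log, "done", paste0(length(artifacts), " artifact(s)"))
    cfg$outDir
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
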