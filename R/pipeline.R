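#' Pipeline configuration
#'
#' Collects every tunable constant of the end-to-end analysis together with
#' the input/output paths and a single seed that is fanned out into
#' independent per-stage substreams (adding a stage never perturbs another
#' stage's randomness). Thresholds default to the analysis constants used
#' throughout the package: q < 0.10 with dominant frequencies 1/16 or 1/8
#' for PsP calling, 95% series completeness, k = 6 for k-NN, 8 CCSs,
#' minimum Spearman overlap 30, sigma multipliers 2.5/3/3 for match
#' filtering and 0.01 for enrichment significance.
#'
#' @param outputDir directory for all artifacts.
#' @param seed master seed.
#' @param sim a [SimConfig-class] used when no `abundancePath` is given.
#' @param abundancePath optional TSV of measured intensities (synthetic
#'   dialect) analyzed instead of a simulation.
#' @param fastaPath optional FASTA for motif enrichment; when `NULL` the
#'   enrichment stage is skipped with a logged notice.
#' @param qThresh,allowedFreqs,completeness,kNeighbors,nCcs,minOverlap,
#'   enrichAlpha stage thresholds.
#' @param clusterK number of Ward clusters; `NULL` picks the elbow (falling
#'   back to 5 when no strong elbow is found).
#' @return a validated configuration list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(outputDir, seed = 1L, sim = simConfig(seed = seed),
                           abundancePath = NULL, fastaPath = NULL,
                           qThresh = 0.10, allowedFreqs = c(1 / 16, 1 / 8),
                           completeness = 0.95, kNeighbors = 6L, nCcs = 8L,
                           minOverlap = 30L, enrichAlpha = 0.01,
                           clusterK = NULL) {
  stopifnot(qThresh > 0, qThresh < 1, completeness >= 0, completeness <= 1,
            kNeighbors >= 1, nCcs >= 2, minOverlap >= 3,
            enrichAlpha > 0, enrichAlpha < 1)
  cfg <- list(outputDir = outputDir, seed = as.integer(seed), sim = sim,
              abundancePath = abundancePath, fastaPath = fastaPath,
              qThresh = qThresh, allowedFreqs = allowedFreqs,
              completeness = completeness, kNeighbors = as.integer(kNeighbors),
              nCcs = as.integer(nCcs), minOverlap = as.integer(minOverlap),
              enrichAlpha = enrichAlpha, clusterK = clusterK)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipelineConfig()] arguments; an
#' optional `sim` block maps onto [simConfig()].
#'
#' @param path YAML file.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  simArgs <- y$sim
  y$sim <- NULL
  sim <- if (is.null(simArgs)) simConfig(seed = y$seed %||% 1L)
         else do.call(simConfig, simArgs)
  do.call(pipelineConfig, c(y, list(sim = sim)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

logMsg <- function(...) message("[CellCycleSig] ", ...)

#' Run the end-to-end cell-cycle signature pipeline
#'
#' Executes normalize -> pseudotimecourses -> periodicity -> PsP calling ->
#' clustering -> motif enrichment (when a FASTA is configured) -> signature
#' building with PCA and leave-one-biological-replicate-out k-NN. All stage
#' tables are written to the output directory as TSV along with a JSON run
#' manifest (configuration, seed, package version, per-stage counts and
#' file checksums). Any stage failure aborts with the stage name and cause.
#'
#' @param config a `PipelineConfig` from [pipelineConfig()].
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  outFile <- function(f) file.path(config$outputDir, f)
  counts <- list()
  stage <- function(name, expr) {
    logMsg("stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  se <- stage("input", {
    if (!is.null(config$abundancePath)) {
      readAbundanceTable(config$abundancePath)
    } else {
      se <- simulateCellCycleDataset(config$sim)
      writeAbundanceTable(se, outFile("abundance.tsv"))
      writeTsv(data.frame(protein_id = rownames(se),
                          as.data.frame(SummarizedExperiment::rowData(se))),
               outFile("ground_truth.tsv"))
      se
    }
  })
  counts$proteins <- nrow(se)
  counts$samples <- ncol(se)

  periodStage <- stage("periodicity", {
    seNorm <- ppmNormalize(se)
    pts <- assemblePseudotimecourses(seNorm, config$completeness)
    res <- testPeriodicity(pts)
    writeTsv(res, outFile("periodicity.tsv"))
    calls <- callPsps(res, qThresh = config$qThresh,
                      allowedFreqs = config$allowedFreqs)
    writeTsv(calls, outFile("psp_calls.tsv"))
    list(se = seNorm, calls = calls)
  })
  se <- periodStage$se
  psp <- periodStage$calls
  counts$testedBothRepeats <- sum(rowSums(
    !is.na(as.matrix(psp[grep("^q_", names(psp))]))) == 2)
  counts$psps <- sum(psp$is_psp)
  logMsg(counts$psps, " PsPs of ", counts$testedBothRepeats,
         " proteins tested in both repeats")
  pspIdsV <- psp$protein_id[psp$is_psp]
  if (length(pspIdsV) < max(config$nCcs, 5L))
    stop("pipeline stage 'periodicity' failed: only ", length(pspIdsV),
         " PsPs called; not enough to build a signature", call. = FALSE)

  clusters <- stage("clustering", {
    prof <- meanProfiles(se, pspIdsV)
    wssCurve <- elbowWss(prof$scaled)
    k <- config$clusterK %||% (if (is.na(wssCurve$elbow)) 5L
                               else wssCurve$elbow)
    cm <- wardCluster(prof$scaled, k)
    labels <- orderClustersByPeak(cm$labels, prof$scaled)
    writeTsv(data.frame(protein_id = rownames(prof$scaled), cluster = labels,
                        prof$mean, prof$scaled, check.names = FALSE),
             outFile("clusters.tsv"))
    writeTsv(data.frame(k = wssCurve$k, wss = wssCurve$wss),
             outFile("elbow_wss.tsv"))
    list(labels = labels, profiles = prof, k = k, elbow = wssCurve$elbow)
  })
  counts$clusters <- clusters$k

  enrichment <- NULL
  if (!is.null(config$fastaPath)) {
    enrichment <- stage("enrichment", {
      seqs <- Biostrings::readAAStringSet(config$fastaPath)
      names(seqs) <- sub("\\s.*$", "", names(seqs))
      scan <- scanMotifs(seqs)
      bg <- intersect(rownames(scan$hits), psp$protein_id)
      inBg <- names(clusters$labels) %in% bg
      er <- enrichmentTest(scan$hits, clusters$labels[inBg],
                           backgroundIds = bg, alpha = config$enrichAlpha)
      writeTsv(er, outFile("enrichment.tsv"))
      writeTsv(multiSlimSummary(scan$hits, clusters$labels[inBg])$perCluster,
               outFile("multi_slim.tsv"))
      er
    })
  } else logMsg("no FASTA configured; enrichment stage skipped")

  signature <- stage("signature", {
    model <- buildSignature(se, pspIdsV, nCcs = config$nCcs,
                            seed = stageSeed(config$seed, "signature"))
    writeSignatureModel(model, outFile("signature"))
    pca <- pcaWheel(model@sampleMatrix)
    writeTsv(data.frame(sample = rownames(pca$scores),
                        pca$scores[, 1:min(4, ncol(pca$scores))],
                        check.names = FALSE),
             outFile("pca_scores.tsv"))
    cd <- SummarizedExperiment::colData(se)
    testRep <- max(cd$biorep)
    isTest <- cd$biorep == testRep
    predicted <- knnClassify(model@sampleMatrix[!isTest, , drop = FALSE],
                             cd$population[!isTest],
                             model@sampleMatrix[isTest, , drop = FALSE],
                             k = config$kNeighbors)
    knnAcc <- mean(predicted == cd$population[isTest])
    writeTsv(data.frame(sample = rownames(model@sampleMatrix)[isTest],
                        truth = cd$population[isTest],
                        predicted = predicted),
             outFile("knn_predictions.tsv"))
    list(model = model, pca = pca, knnAccuracy = knnAcc)
  })
  counts$pc1VarExplained <- signature$pca$varExplained[1]
  counts$pc2VarExplained <- signature$pca$varExplained[2]
  counts$knnAccuracy <- signature$knnAccuracy

  manifest <- list(
    package = "CellCycleSig",
    version = as.character(utils::packageVersion("CellCycleSig")),
    seed = config$seed,
    config = configAsList(config),
    counts = counts)
  files <- list.files(config$outputDir, pattern = "\\.tsv$",
                      full.names = TRUE)
  manifest$checksums <- as.list(setNames(unname(tools::md5sum(files)),
                                         basename(files)))
  jsonlite::write_json(manifest, outFile("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logMsg("pipeline complete: ", config$outputDir)
  invisible(list(se = se, psp = psp, clusters = clusters,
                 enrichment = enrichment, signature = signature,
                 manifest = manifest))
}

configAsList <- function(config) {
  sim <- config$sim
  simList <- list(nProteins = sim@nProteins, fracPeriodic = sim@fracPeriodic,
                  nPopulations = sim@nPopulations, nBiorep = sim@nBiorep,
                  nTechrep = sim@nTechrep,
                  amplitudeRange = sim@amplitudeRange, noiseCV = sim@noiseCV,
                  depthCV = sim@depthCV,
                  missingMidpoint = sim@missingMidpoint,
                  missingSlope = sim@missingSlope, seed = sim@seed)
  out <- unclass(config)
  out$sim <- simList
  out
}
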