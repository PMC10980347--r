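#' Configure an end-to-end pipeline run
#'
#' Bundles every input and tuning knob of the full analysis: candidate
#' funnel thresholds, inference hyperparameters, consensus settings and
#' condition-specific retention thresholds. Inputs may be in-memory
#' objects or file paths (paths are loaded by [runPipeline()]).
#'
#' @param expression a `SummarizedExperiment` with `colData` column
#'   `condition` (values `"control"`/`"stress"`), or a path to an
#'   expression TSV (then `metadata` must be a metadata TSV path).
#' @param metadata optional sample-metadata path.
#' @param target target gene identifier.
#' @param y1hHits one-hybrid candidate regulators (vector or path).
#' @param knownRegulators known regulators (vector or path).
#' @param bindingSet binding-evidence genes (vector or path).
#' @param developmentGenes optional second gene set; when given, DEGs
#'   are intersected with it before the funnel (vector or path).
#' @param lfcMin,pMax,useAdjusted,direction DEG thresholds, see
#'   [callDegs()].
#' @param params an [InferenceParams-class] object.
#' @param nRuns,baseSeed consensus replication settings; the stress
#'   consensus uses `baseSeed`, the control consensus `baseSeed + nRuns`.
#' @param minFreqStress,minFreqControl retention thresholds (defaults
#'   0.80 and 0.40).
#' @param extraction,k per-run regulator extraction, see
#'   [extractTargetRegulators()]. The pipeline default is `"top_k"` with
#'   `k = NULL`, resolved at run time to 10 percent of the predictor
#'   panel (rounded up): per-run positive-importance sets saturate under
#'   a large stage budget, so consensus frequencies are only informative
#'   when each run keeps its strongest predictors.
#' @param outDir output directory for all artifacts.
#' @return A `PipelineConfig` list.
#' @export
pipelineConfig <- function(expression, metadata = NULL, target,
                           y1hHits = character(0),
                           knownRegulators = character(0),
                           bindingSet = character(0),
                           developmentGenes = NULL,
                           lfcMin = 1, pMax = 0.001, useAdjusted = TRUE,
                           direction = "both",
                           params = inferenceParams(),
                           nRuns = 100L, baseSeed = 0L,
                           minFreqStress = 0.80, minFreqControl = 0.40,
                           extraction = "top_k", k = NULL,
                           outDir) {
  cfg <- list(expression = expression, metadata = metadata,
              target = target, y1hHits = y1hHits,
              knownRegulators = knownRegulators, bindingSet = bindingSet,
              developmentGenes = developmentGenes,
              lfcMin = lfcMin, pMax = pMax, useAdjusted = useAdjusted,
              direction = direction, params = params,
              nRuns = as.integer(nRuns), baseSeed = as.integer(baseSeed),
              minFreqStress = minFreqStress,
              minFreqControl = minFreqControl,
              extraction = extraction,
              k = if (is.null(k)) NULL else as.integer(k),
              outDir = outDir)
  if (any(c(minFreqStress, minFreqControl) < 0 |
          c(minFreqStress, minFreqControl) > 1))
    stop("consensus thresholds must lie in [0, 1]")
  validObject(params)
  class(cfg) <- "PipelineConfig"
  cfg
}

loadGenes <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L && file.exists(x))
    readGeneList(x) else as.character(x)
}

#' Run the full regulator-discovery pipeline
#'
#' Executes the candidate funnel (differential expression stress versus
#' control, optional overlap with a second gene set, assembly with
#' one-hybrid hits and known regulators), the per-condition replicate
#' consensus inference, and the binding-evidence integration. Every
#' intermediate artifact is written to `config$outDir` together with a
#' `manifest.json` recording package version, seeds, thresholds and
#' stage sizes; rerunning an identical configuration reproduces
#' identical artifacts (the manifest timestamp aside). Stage failures
#' abort with a stage-labeled message and a manifest flagging the failed
#' stage.
#'
#' @param config a [pipelineConfig()] object.
#' @return The [RegulatorReport-class], invisibly.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "saltGRN",
                   version = as.character(packageVersion("saltGRN")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   status = "running", stages = list())
  artifact <- function(name) file.path(config$outDir, name)
  writeManifest <- function() {
    jsonlite::write_json(manifest, artifact("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$status <<- paste0("failed:", name)
      writeManifest()
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  se <- stage("load", {
    if (is.character(config$expression))
      readExperiment(config$expression, config$metadata)
    else config$expression
  })
  cond <- SummarizedExperiment::colData(se)$condition
  if (!all(c("control", "stress") %in% cond))
    stop("stage 'load': colData condition must contain both 'control' and 'stress'")
  mat <- asExpressionMatrix(se)
  stressSamples <- colnames(mat)[cond == "stress"]
  controlSamples <- colnames(mat)[cond == "control"]

  deg <- stage("deg", {
    tab <- moderatedTTest(mat, stressSamples, controlSamples)
    degs <- callDegs(tab, lfcMin = config$lfcMin, pMax = config$pMax,
                     useAdjusted = config$useAdjusted,
                     direction = config$direction)
    write.table(tab, artifact("deg_table.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeGeneList(degs, artifact("degs.txt"))
    list(tab = tab, degs = degs)
  })

  funnel <- stage("funnel", {
    devGenes <- loadGenes(config$developmentGenes)
    overlap <- if (is.null(devGenes)) deg$degs
               else overlapSets(deg$degs, devGenes)$intersection
    cand <- buildCandidateList(overlap,
                               loadGenes(config$y1hHits),
                               loadGenes(config$knownRegulators),
                               config$target)
    write.table(cand, artifact("candidates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(overlap = overlap, candidates = cand)
  })

  consensus <- stage("consensus", {
    kUse <- if (is.null(config$k))
      max(1L, as.integer(ceiling(0.1 * (nrow(funnel$candidates) - 1L))))
    else config$k
    run1 <- function(samples, seed) {
      runConsensus(mat[, samples, drop = FALSE], funnel$candidates,
                   config$target, nRuns = config$nRuns, baseSeed = seed,
                   params = config$params, extraction = config$extraction,
                   k = kUse)
    }
    stressCons <- run1(stressSamples, config$baseSeed)
    controlCons <- run1(controlSamples, config$baseSeed + config$nRuns)
    writeConsensusTable(stressCons, artifact("consensus_stress.tsv"))
    writeConsensusTable(controlCons, artifact("consensus_control.tsv"))
    list(stress = stressCons, control = controlCons)
  })

  report <- stage("report", {
    rep <- buildReport(consensus$stress, consensus$control,
                       thresholds = c(stress = config$minFreqStress,
                                      control = config$minFreqControl),
                       bindingSet = loadGenes(config$bindingSet))
    writeReport(rep, artifact("report.tsv"), artifact("report.json"))
    rep
  })

  manifest$status <- "complete"
  manifest$stages <- list(
    load = list(n_genes = nrow(mat), n_samples = ncol(mat),
                n_stress_samples = length(stressSamples),
                n_control_samples = length(controlSamples)),
    deg = list(lfc_min = config$lfcMin, p_max = config$pMax,
               use_adjusted = config$useAdjusted,
               direction = config$direction, n_degs = length(deg$degs)),
    funnel = list(n_overlap = length(funnel$overlap),
                  n_y1h = length(loadGenes(config$y1hHits)),
                  n_known = length(loadGenes(config$knownRegulators)),
                  n_candidates = nrow(funnel$candidates)),
    consensus = list(n_runs = config$nRuns,
                     base_seed_stress = config$baseSeed,
                     base_seed_control = config$baseSeed + config$nRuns,
                     extraction = config$extraction, k = kUse,
                     params = list(
                       learning_rate = config$params@learningRate,
                       n_stages = config$params@nStages,
                       subsample_fraction = config$params@subsampleFraction,
                       feature_fraction = config$params@featureFraction,
                       max_depth = config$params@maxDepth,
                       early_stop_window = config$params@earlyStopWindow)),
    report = list(min_freq_stress = config$minFreqStress,
                  min_freq_control = config$minFreqControl,
                  n_binding = length(loadGenes(config$bindingSet)),
                  n_regulators = nrow(as.data.frame(report))))
  writeManifest()
  invisible(report)
}
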