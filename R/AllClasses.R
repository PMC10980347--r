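#' @include AllGenerics.R
NULL

#' Simulation design for a ground-truth regulatory network experiment
#'
#' Describes a candidate panel of transcription factors, a target gene, the
#' true regulators of that target with their effect sizes and condition
#' activity, and the sampling design (time points per condition,
#' replicates, noise). Built with [grnSpec()].
#'
#' @slot nGenes integer; size of the candidate panel excluding the target.
#' @slot targetId character; identifier of the target gene.
#' @slot regulators data.frame with columns `gene`, `beta`, `condition`
#'   (`"stress"`, `"control"` or `"both"`) and `activationTime` (hours).
#' @slot controlTimepoints,stressTimepoints numeric; sampling times (hours).
#' @slot nReplicates integer; replicates per (condition, time) cell.
#' @slot noiseSd numeric; per-sample measurement noise SD (log2 units).
#' @slot baselineMean,baselineSd numeric; distribution of gene baselines.
#' @slot inductionAmplitude numeric; peak height of the stress induction
#'   bump on the log2 scale.
#' @slot inductionWidth numeric; Gaussian width (hours) of the bump.
#' @slot arCor numeric in \[0, 1); lag-one correlation of the latent
#'   time-course trajectory.
#' @slot seed integer; RNG seed making the simulation reproducible.
#' @export
setClass("GrnSpec",
  representation(
    nGenes = "integer",
    targetId = "character",
    regulators = "data.frame",
    controlTimepoints = "numeric",
    stressTimepoints = "numeric",
    nReplicates = "integer",
    noiseSd = "numeric",
    baselineMean = "numeric",
    baselineSd = "numeric",
    inductionAmplitude = "numeric",
    inductionWidth = "numeric",
    arCor = "numeric",
    seed = "integer"
  )
)

setValidity("GrnSpec", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
  if (length(object@targetId) != 1L || !nzchar(object@targetId))
    msg <- c(msg, "targetId must be a single non-empty identifier")
  reg <- object@regulators
  need <- c("gene", "beta", "condition", "activationTime")
  if (!all(need %in% names(reg)))
    msg <- c(msg, paste("regulators must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (object@targetId %in% reg$gene)
      msg <- c(msg, "the target cannot be one of its own regulators")
    if (anyDuplicated(reg$gene))
      msg <- c(msg, "duplicated regulator identifiers")
    if (any(!is.finite(reg$beta)))
      msg <- c(msg, "regulator effect sizes must be finite")
    if (!all(reg$condition %in% c("stress", "control", "both")))
      msg <- c(msg, "regulator condition must be stress, control or both")
  }
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be nonnegative")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be positive")
  if (length(object@controlTimepoints) < 1L ||
      length(object@stressTimepoints) < 1L)
    msg <- c(msg, "each condition needs at least one time point")
  if (object@arCor < 0 || object@arCor >= 1)
    msg <- c(msg, "arCor must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Simulated expression experiment with known ground truth
#'
#' A \linkS4class{SummarizedExperiment} (assay `"logexpr"`, genes in rows,
#' samples in columns, `colData` columns `condition`, `time_h`,
#' `replicate`) carrying the ground-truth edge list used to generate the
#' target gene's expression. Produced by [simulateExpression()].
#'
#' @slot groundTruth data.frame of true (regulator, target, beta,
#'   condition) edges.
#' @seealso [groundTruth()]
#' @export
setClass("GrnSimulation",
  contains = "SummarizedExperiment",
  representation(groundTruth = "data.frame")
)

setValidity("GrnSimulation", function(object) {
  gt <- object@groundTruth
  msg <- character()
  need <- c("regulator", "target", "beta", "condition")
  if (!all(need %in% names(gt)))
    return(paste("groundTruth must have columns:", paste(need, collapse = ", ")))
  if (any(gt$regulator == gt$target))
    msg <- c(msg, "groundTruth contains a self-edge")
  if (anyDuplicated(gt[, c("regulator", "target")]))
    msg <- c(msg, "duplicate (regulator, target) pair in groundTruth")
  if (!all(gt$regulator %in% rownames(object)))
    msg <- c(msg, "groundTruth regulator absent from the expression matrix")
  if (length(msg)) msg else TRUE
})

#' @describeIn GrnSimulation ground-truth edge list of the simulation.
#' @param x a `GrnSimulation`.
#' @export
setMethod("groundTruth", "GrnSimulation", function(x) x@groundTruth)

setMethod("show", "GrnSimulation", function(object) {
  callNextMethod()
  cat("groundTruth:", nrow(object@groundTruth), "edge(s) onto",
      paste(unique(object@groundTruth$target), collapse = ", "), "\n")
})

#' Hyperparameters of the boosted-tree inference engine
#'
#' Defaults follow the published stochastic gradient-boosting profile of
#' tree-ensemble network inference tools: a small learning rate with a
#' large stage budget, strong per-split feature subsampling, row
#' subsampling, shallow trees, and out-of-bag early stopping.
#' Built with [inferenceParams()].
#'
#' @slot learningRate numeric in (0, 1]; shrinkage applied to each tree.
#' @slot nStages integer; maximum number of boosting stages.
#' @slot subsampleFraction numeric in (0, 1]; without-replacement row
#'   subsample fraction per stage.
#' @slot featureFraction numeric in (0, 1]; fraction of predictors
#'   considered at each split.
#' @slot maxDepth integer; maximum tree depth.
#' @slot earlyStopWindow integer; trailing-window length for the
#'   out-of-bag improvement stopping rule.
#' @export
setClass("InferenceParams",
  representation(
    learningRate = "numeric",
    nStages = "integer",
    subsampleFraction = "numeric",
    featureFraction = "numeric",
    maxDepth = "integer",
    earlyStopWindow = "integer"
  )
)

setValidity("InferenceParams", function(object) {
  msg <- character()
  if (object@learningRate <= 0 || object@learningRate > 1)
    msg <- c(msg, "learningRate must lie in (0, 1]")
  if (object@nStages < 1L) msg <- c(msg, "nStages must be positive")
  if (object@subsampleFraction <= 0 || object@subsampleFraction > 1)
    msg <- c(msg, "subsampleFraction must lie in (0, 1]")
  if (object@featureFraction <= 0 || object@featureFraction > 1)
    msg <- c(msg, "featureFraction must lie in (0, 1]")
  if (object@maxDepth < 1L) msg <- c(msg, "maxDepth must be positive")
  if (object@earlyStopWindow < 1L ||
      object@earlyStopWindow > object@nStages)
    msg <- c(msg, "earlyStopWindow must lie in [1, nStages]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "InferenceParams", function(object) {
  cat("InferenceParams: learningRate=", object@learningRate,
      ", nStages=", object@nStages,
      ", subsample=", object@subsampleFraction,
      ", featureFraction=", object@featureFraction,
      ", maxDepth=", object@maxDepth,
      ", earlyStopWindow=", object@earlyStopWindow, "\n", sep = "")
})

#' Consensus-frequency table over replicate inference runs
#'
#' Per candidate regulator of a single target gene: in how many of the
#' replicate stochastic inference runs it was predicted as a direct
#' regulator, the corresponding frequency, its mean importance over the
#' runs where it was predicted, and its rank under the ordering
#' (frequency desc, mean importance desc, identifier asc). Produced by
#' [runConsensus()].
#'
#' @slot table data.frame with columns `regulator`, `count`, `frequency`,
#'   `mean_importance`, `rank`.
#' @slot nRuns integer; number of replicate runs.
#' @slot target character; the target gene.
#' @slot baseSeed integer; base seed (run i used seed `baseSeed + i`).
#' @export
setClass("ConsensusResult",
  representation(
    table = "data.frame",
    nRuns = "integer",
    target = "character",
    baseSeed = "integer"
  )
)

setValidity("ConsensusResult", function(object) {
  tb <- object@table
  msg <- character()
  need <- c("regulator", "count", "frequency", "mean_importance", "rank")
  if (!all(need %in% names(tb)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (any(tb$count < 0L) || any(tb$count > object@nRuns))
    msg <- c(msg, "counts must lie in [0, nRuns]")
  if (any(abs(tb$frequency - tb$count / object@nRuns) > 1e-12))
    msg <- c(msg, "frequency must equal count / nRuns")
  if (nrow(tb) && !identical(sort(tb$rank), seq_len(nrow(tb))))
    msg <- c(msg, "ranks must be a permutation of 1..n_regulators")
  if (object@target %in% tb$regulator)
    msg <- c(msg, "the target cannot appear as its own regulator")
  if (length(msg)) msg else TRUE
})

#' @describeIn ConsensusResult number of replicate inference runs.
#' @param x a `ConsensusResult`.
#' @export
setMethod("nRuns", "ConsensusResult", function(x) x@nRuns)

#' @describeIn ConsensusResult target gene identifier.
#' @export
setMethod("targetGene", "ConsensusResult", function(x) x@target)

#' @describeIn ConsensusResult the consensus table as a `data.frame`, in
#'   rank order.
#' @param row.names,optional,... passed on conventionally; unused.
#' @export
setMethod("as.data.frame", "ConsensusResult",
          function(x, row.names = NULL, optional = FALSE, ...) x@table)

setMethod("show", "ConsensusResult", function(object) {
  cat("ConsensusResult for target '", object@target, "': ",
      nrow(object@table), " regulator(s) over ", object@nRuns,
      " run(s)\n", sep = "")
  top <- utils::head(object@table, 5L)
  if (nrow(top)) print(top, row.names = FALSE)
})

#' Final prioritized regulator report
#'
#' Combines the stress- and control-condition consensus sets with binding
#' evidence. Each retained regulator is classified as stress-specific,
#' control-specific or shared, flagged for binding evidence, and assigned
#' a final priority: binding-evidenced regulators first, then
#' stress-specific before shared before control-specific, then by stress
#' frequency, then alphabetically. Produced by [buildReport()].
#'
#' @slot table data.frame with columns `regulator`, `class`,
#'   `frequency_stress`, `frequency_control`, `binding_evidence`,
#'   `final_priority`.
#' @slot thresholds named numeric of length 2 (`stress`, `control`).
#' @export
setClass("RegulatorReport",
  representation(
    table = "data.frame",
    thresholds = "numeric"
  )
)

setValidity("RegulatorReport", function(object) {
  tb <- object@table
  msg <- character()
  need <- c("regulator", "class", "frequency_stress", "frequency_control",
            "binding_evidence", "final_priority")
  if (!all(need %in% names(tb)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (!all(tb$class %in% c("stress-specific", "control-specific", "shared")))
    msg <- c(msg, "unknown regulator class")
  if (anyDuplicated(tb$regulator))
    msg <- c(msg, "a regulator appears in more than one class")
  if (nrow(tb) && !identical(sort(tb$final_priority), seq_len(nrow(tb))))
    msg <- c(msg, "final_priority must be a permutation of 1..n")
  if (!all(c("stress", "control") %in% names(object@thresholds)))
    msg <- c(msg, "thresholds must be named 'stress' and 'control'")
  if (length(msg)) msg else TRUE
})

#' @describeIn RegulatorReport the report as a `data.frame`, in priority
#'   order.
#' @param x a `RegulatorReport`.
#' @param row.names,optional,... passed on conventionally; unused.
#' @export
setMethod("as.data.frame", "RegulatorReport",
          function(x, row.names = NULL, optional = FALSE, ...) x@table)

setMethod("show", "RegulatorReport", function(object) {
  cat("RegulatorReport: ", nrow(object@table), " regulator(s) ",
      "(thresholds stress>=", object@thresholds[["stress"]],
      ", control>=", object@thresholds[["control"]], ")\n", sep = "")
  top <- utils::head(object@table, 8L)
  if (nrow(top)) print(top, row.names = FALSE)
})
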