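#' Replicate inference and rank regulators by consensus frequency
#'
#' Runs the stochastic network inference `nRuns` times (replicate `i`
#' uses seed `baseSeed + i`), restricted to the single target, extracts
#' the predicted direct regulators of the target from each run, and
#' counts how often each candidate was predicted. The consensus
#' frequency of a regulator is its count divided by `nRuns`; ranking is
#' by frequency descending, then mean importance descending, then
#' identifier ascending. The procedure replicates the algorithm's
#' stochasticity only — the expression data are never resampled.
#'
#' @param x genes x samples numeric matrix or `SummarizedExperiment`.
#' @param candidates candidate panel (character vector or
#'   [buildCandidateList()] data.frame) containing `target`.
#' @param target the target gene.
#' @param nRuns number of replicate runs (default 100).
#' @param baseSeed base RNG seed.
#' @param params an [InferenceParams-class] object.
#' @param extraction `"positive"` (all positive-importance regulators
#'   per run) or `"top_k"`.
#' @param k regulators kept per run under `extraction = "top_k"`.
#' @return A [ConsensusResult-class] covering every candidate regulator
#'   (the target excluded), including never-predicted ones at count 0.
#' @examples
#' sim <- simulateExpression(grnSpec(nGenes = 12, seed = 4))
#' cons <- runConsensus(sim, rownames(sim), "TARGET", nRuns = 5,
#'                      baseSeed = 10)
#' cons
#' @export
runConsensus <- function(x, candidates, target, nRuns = 100L,
                         baseSeed = 0L, params = inferenceParams(),
                         extraction = c("positive", "top_k"), k = 5L) {
  extraction <- match.arg(extraction)
  x <- asExpressionMatrix(x)
  candidates <- asCandidateIds(candidates)
  if (!target %in% candidates) stop("target must be one of the candidates")
  if (nRuns < 1L) stop("nRuns must be >= 1")

  regulators <- setdiff(candidates, target)
  count <- setNames(integer(length(regulators)), regulators)
  impSum <- setNames(numeric(length(regulators)), regulators)
  for (i in seq_len(nRuns)) {
    edges <- inferEdges(x, candidates, params, targets = target,
                        seed = baseSeed + i)
    regs <- extractTargetRegulators(edges, target, mode = extraction, k = k)
    count[regs] <- count[regs] + 1L
    sub <- edges[edges$regulator %in% regs, , drop = FALSE]
    impSum[sub$regulator] <- impSum[sub$regulator] + sub$importance
  }

  tb <- data.frame(regulator = regulators,
                   count = as.integer(count),
                   frequency = as.numeric(count) / nRuns,
                   mean_importance = ifelse(count > 0, impSum / pmax(count, 1L), 0),
                   stringsAsFactors = FALSE)
  ord <- order(-tb$frequency, -tb$mean_importance, tb$regulator)
  tb <- tb[ord, , drop = FALSE]
  tb$rank <- seq_len(nrow(tb))
  rownames(tb) <- NULL
  new("ConsensusResult", table = tb, nRuns = as.integer(nRuns),
      target = as.character(target), baseSeed = as.integer(baseSeed))
}

#' @rdname thresholdConsensus
#' @export
setMethod("thresholdConsensus", "ConsensusResult",
  function(x, minFrequency) {
    if (!is.finite(minFrequency) || minFrequency < 0 || minFrequency > 1)
      stop("minFrequency must lie in [0, 1]")
    tb <- x@table
    tb$regulator[tb$count >= 1L & tb$frequency >= minFrequency]
  })
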