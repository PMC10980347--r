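#' Ground-truth edges of a simulated experiment
#'
#' @param x a [GrnSimulation-class] object.
#' @return A `data.frame` with columns `regulator`, `target`, `beta`,
#'   `condition` (one of `"stress"`, `"control"`, `"both"`).
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' Number of inference replicates behind a consensus table
#'
#' @param x a [ConsensusResult-class] object.
#' @return Integer scalar.
#' @export
setGeneric("nRuns", function(x) standardGeneric("nRuns"))

#' Target gene of a consensus or report object
#'
#' @param x a [ConsensusResult-class] object.
#' @return Character scalar gene identifier.
#' @export
setGeneric("targetGene", function(x) standardGeneric("targetGene"))

#' Retain regulators at or above a consensus frequency
#'
#' Regulators never predicted in any run (count 0) are excluded at every
#' threshold: a consensus frequency is only defined for interactions that
#' were actually predicted.
#'
#' @param x a [ConsensusResult-class] object.
#' @param minFrequency numeric in \[0, 1\]; retention is inclusive
#'   (frequency exactly equal to the threshold is retained).
#' @return Character vector of regulator identifiers in rank order.
#' @export
setGeneric("thresholdConsensus",
           function(x, minFrequency) standardGeneric("thresholdConsensus"))
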