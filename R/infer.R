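#' Infer a regulator-target edge list from expression data
#'
#' For each target gene, fits one boosted-tree model
#' ([fitTargetModel()]) with all other candidates as predictors and
#' emits one edge per predictor with positive importance. The returned
#' edge list is sorted by importance descending with ties broken
#' lexicographically on (regulator, target), so the output is totally
#' ordered and byte-reproducible under a fixed seed.
#'
#' @param x genes x samples numeric matrix or `SummarizedExperiment`.
#' @param candidates candidate gene identifiers (character vector or a
#'   [buildCandidateList()] data.frame); all must be rows of `x`.
#' @param params an [InferenceParams-class] object.
#' @param targets genes to fit models for (default: all candidates);
#'   must be a subset of `candidates`.
#' @param seed RNG seed for the whole call.
#' @return `data.frame` with columns `regulator`, `target`, `importance`.
#' @examples
#' sim <- simulateExpression(grnSpec(nGenes = 10, seed = 5))
#' edges <- inferEdges(sim, rownames(sim), targets = "TARGET", seed = 2)
#' head(edges)
#' @export
inferEdges <- function(x, candidates, params = inferenceParams(),
                       targets = NULL, seed = 1L) {
  x <- asExpressionMatrix(x)
  candidates <- asCandidateIds(candidates)
  missing <- setdiff(candidates, rownames(x))
  if (length(missing))
    stop("candidate(s) absent from the expression matrix: ",
         paste(missing, collapse = ", "))
  if (is.null(targets)) targets <- candidates
  targets <- asCandidateIds(targets)
  if (length(setdiff(targets, candidates)))
    stop("targets must be a subset of candidates")

  rows <- withSeed(seed, {
    out <- vector("list", length(targets))
    for (i in seq_along(targets)) {
      tg <- targets[i]
      predictors <- setdiff(candidates, tg)
      if (!length(predictors)) next
      X <- t(x[predictors, , drop = FALSE])
      # fresh seed per target: each model's randomness depends only on
      # the call seed and the target's position, not on how much RNG
      # the previous fits consumed
      imp <- fitTargetModel(x[tg, ], X, params,
                            seed = sample.int(.Machine$integer.max, 1L))
      keep <- imp > 0
      if (any(keep))
        out[[i]] <- data.frame(regulator = predictors[keep], target = tg,
                               importance = unname(imp[keep]),
                               stringsAsFactors = FALSE)
    }
    out
  })
  edges <- do.call(rbind, rows)
  if (is.null(edges))
    edges <- data.frame(regulator = character(0), target = character(0),
                        importance = numeric(0), stringsAsFactors = FALSE)
  edges <- edges[order(-edges$importance, edges$regulator, edges$target), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Extract the predicted direct regulators of one target
#'
#' @param edges an edge list from [inferEdges()].
#' @param target target gene identifier.
#' @param mode `"positive"` returns every regulator with a positive
#'   importance into the target; `"top_k"` truncates to the `k`
#'   strongest.
#' @param k number of regulators kept under `mode = "top_k"`.
#' @return Character vector of regulators ordered by importance
#'   descending (ties lexicographic); empty when the target has no
#'   incoming edges.
#' @export
extractTargetRegulators <- function(edges, target,
                                    mode = c("positive", "top_k"),
                                    k = 5L) {
  mode <- match.arg(mode)
  if (mode == "top_k" && (!is.finite(k) || k < 1))
    stop("k must be >= 1 for mode 'top_k'")
  rows <- edges[edges$target == target, , drop = FALSE]
  rows <- rows[order(-rows$importance, rows$regulator), , drop = FALSE]
  regs <- rows$regulator
  if (mode == "top_k") regs <- utils::head(regs, k)
  regs
}
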