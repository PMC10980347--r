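#' Construct inference-engine hyperparameters
#'
#' Defaults (`learningRate = 0.01`, `nStages = 5000`,
#' `subsampleFraction = 0.9`, `featureFraction = 0.1`, `maxDepth = 3`,
#' `earlyStopWindow = 25`) follow the published stochastic
#' gradient-boosting profile of tree-ensemble network inference.
#'
#' @param learningRate shrinkage in (0, 1].
#' @param nStages maximum boosting stages.
#' @param subsampleFraction without-replacement row subsample per stage,
#'   in (0, 1].
#' @param featureFraction fraction of predictors considered per split,
#'   in (0, 1].
#' @param maxDepth maximum tree depth.
#' @param earlyStopWindow trailing window for the out-of-bag stopping
#'   rule; must not exceed `nStages`.
#' @return A validated [InferenceParams-class] object.
#' @export
inferenceParams <- function(learningRate = 0.01, nStages = 5000L,
                            subsampleFraction = 0.9,
                            featureFraction = 0.1, maxDepth = 3L,
                            earlyStopWindow = 25L) {
  new("InferenceParams",
      learningRate = as.numeric(learningRate),
      nStages = as.integer(nStages),
      subsampleFraction = as.numeric(subsampleFraction),
      featureFraction = as.numeric(featureFraction),
      maxDepth = as.integer(maxDepth),
      earlyStopWindow = as.integer(earlyStopWindow))
}

#' Fit one boosted-tree model for a single target gene
#'
#' Stochastic gradient boosting on squared-error loss: each stage fits a
#' depth-limited regression tree to the current residuals on a
#' without-replacement row subsample, considering a random fraction of
#' predictors at every split, and the model is updated by
#' `learningRate` times the tree prediction. Boosting stops before the
#' stage budget when the trailing-window mean of the out-of-bag loss
#' improvement (measured on each stage's held-out rows) drops to zero or
#' below. The importance of a predictor is its total squared-error
#' impurity reduction over all splits across the retained stages,
#' normalized to sum to one; the vector is all zero when no split ever
#' occurred (e.g. a constant response).
#'
#' With fewer than 4 samples, row subsampling is disabled (with a
#' warning), which also disables early stopping.
#'
#' @param y numeric response (the target gene's expression per sample).
#' @param X samples x predictors numeric matrix with column names.
#' @param params an [InferenceParams-class] object.
#' @param seed RNG seed; fixed seed gives identical importances.
#' @return Named numeric importance vector (one entry per predictor,
#'   nonnegative, summing to 1 when any split occurred), with attribute
#'   `"stages"` giving the number of boosting stages retained.
#' @export
fitTargetModel <- function(y, X, params = inferenceParams(), seed = 1L) {
  validObject(params)
  if (!is.matrix(X) || !is.numeric(X)) stop("X must be a numeric matrix")
  if (is.null(colnames(X))) stop("X must carry predictor column names")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (length(y) < 2L) stop("at least 2 samples are required")
  if (any(!is.finite(y)) || any(!is.finite(X)))
    stop("expression values must be finite and non-missing")

  subsample <- params@subsampleFraction
  if (nrow(X) < 4L && subsample < 1) {
    warning("fewer than 4 samples: row subsampling disabled")
    subsample <- 1
  }

  fit <- withSeed(seed,
    .sgbm_fit(X, as.numeric(y), params@learningRate, params@nStages,
              subsample, params@featureFraction, params@maxDepth,
              params@earlyStopWindow))
  imp <- fit$importance
  tot <- sum(imp)
  if (fit$any_split && tot > 0) imp <- imp / tot else imp <- rep(0, ncol(X))
  names(imp) <- colnames(X)
  attr(imp, "stages") <- fit$stages
  imp
}
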