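#' Construct a simulation design
#'
#' The defaults describe the benchmark condition the package is built
#' around: a candidate panel of 94 genes (93 transcription factors plus
#' the target), expression sampled at 2 control and 6 stress time points
#' with 3 replicates each, and a single true regulator that is
#' transcriptionally activated early under stress (induction peaking at
#' 3 h) and drives the target with a strong effect.
#'
#' @param nGenes total panel size including the target (default 94).
#' @param targetId identifier of the target gene.
#' @param regulators data.frame with columns `gene`, `beta`, `condition`
#'   (`"stress"`, `"control"` or `"both"`) and `activationTime` (hours).
#'   `condition` states in which condition the regulator drives the
#'   target; regulators with `condition = "stress"` additionally receive
#'   the stress induction bump.
#' @param controlTimepoints,stressTimepoints sampling times in hours.
#' @param nReplicates replicates per (condition, time point) cell.
#' @param noiseSd per-sample noise SD on the log2 scale.
#' @param baselineMean,baselineSd mean and SD of per-gene baselines.
#' @param inductionAmplitude peak height (log2 units) of the stress bump.
#' @param inductionWidth Gaussian width (hours) of the stress bump.
#' @param arCor lag-one correlation of the latent time trajectories.
#' @param seed RNG seed.
#' @return A validated [GrnSpec-class] object.
#' @examples
#' spec <- grnSpec()
#' spec
#' @export
grnSpec <- function(nGenes = 94L,
                    targetId = "TARGET",
                    regulators = data.frame(
                      gene = "TF001", beta = 2,
                      condition = "stress", activationTime = 3,
                      stringsAsFactors = FALSE),
                    controlTimepoints = c(1, 24),
                    stressTimepoints = c(0.5, 1, 3, 6, 12, 24),
                    nReplicates = 3L,
                    noiseSd = 0.25,
                    baselineMean = 6,
                    baselineSd = 1,
                    inductionAmplitude = 4,
                    inductionWidth = 2,
                    arCor = 0.8,
                    seed = 1L) {
  new("GrnSpec",
      nGenes = as.integer(nGenes),
      targetId = as.character(targetId),
      regulators = regulators,
      controlTimepoints = as.numeric(controlTimepoints),
      stressTimepoints = as.numeric(stressTimepoints),
      nReplicates = as.integer(nReplicates),
      noiseSd = as.numeric(noiseSd),
      baselineMean = as.numeric(baselineMean),
      baselineSd = as.numeric(baselineSd),
      inductionAmplitude = as.numeric(inductionAmplitude),
      inductionWidth = as.numeric(inductionWidth),
      arCor = as.numeric(arCor),
      seed = as.integer(seed))
}

#' An empty regulator table: a pure-noise panel
#'
#' Convenience for null experiments in which no gene drives the target;
#' the target row is then pure Normal(0, noiseSd^2) noise.
#'
#' @return Zero-row `data.frame` with the regulator columns expected by
#'   [grnSpec()].
#' @export
noRegulators <- function() {
  data.frame(gene = character(0), beta = numeric(0),
             condition = character(0), activationTime = numeric(0),
             stringsAsFactors = FALSE)
}

#' Simulate condition-dependent time-course expression with known truth
#'
#' Generates a genes x samples log2-scale expression matrix from the
#' ground-truth network of `spec`. Every gene follows a smooth latent
#' time trajectory (a stationary AR(1) around its baseline, so
#' neighbouring time points are correlated as in real time courses) plus
#' independent per-sample noise. Stress-activated regulators additionally
#' receive a unimodal induction bump, additive on the log2 scale
#' (multiplicative on the linear scale), peaking at their activation time
#' under the stress condition only. The target gene's value in a sample
#' is the sum of `beta * regulator expression` over regulators active in
#' that sample's condition, plus Normal(0, noiseSd^2) noise; the target
#' has no baseline of its own, so at `noiseSd = 0` the target is an
#' exact linear function of its realized regulator rows.
#'
#' Identical `spec` (including its `seed`) yields identical output.
#'
#' @param spec a [GrnSpec-class] from [grnSpec()].
#' @return A [GrnSimulation-class]: a `SummarizedExperiment` with assay
#'   `"logexpr"`, `colData` columns `condition` (`"control"`/`"stress"`),
#'   `time_h` and `replicate`, and the ground-truth edge list available
#'   via [groundTruth()].
#' @examples
#' sim <- simulateExpression(grnSpec(seed = 7))
#' dim(sim)          # 94 genes x 24 samples
#' groundTruth(sim)
#' @export
simulateExpression <- function(spec) {
  validObject(spec)
  reg <- spec@regulators
  nFill <- spec@nGenes - nrow(reg) - 1L
  if (nFill < 0L)
    stop("nGenes is smaller than the number of regulators plus the target")

  fillerIds <- character(0)
  if (nFill > 0L) {
    pool <- sprintf("TF%03d", seq_len(spec@nGenes + nrow(reg) + 1L))
    pool <- setdiff(pool, c(reg$gene, spec@targetId))
    fillerIds <- pool[seq_len(nFill)]
  }
  genes <- c(reg$gene, fillerIds, spec@targetId)
  if (anyDuplicated(genes)) stop("duplicated gene identifiers in panel")

  design <- rbind(
    expand.grid(replicate = seq_len(spec@nReplicates),
                time_h = spec@controlTimepoints,
                condition = "control", stringsAsFactors = FALSE),
    expand.grid(replicate = seq_len(spec@nReplicates),
                time_h = spec@stressTimepoints,
                condition = "stress", stringsAsFactors = FALSE)
  )
  design <- design[, c("condition", "time_h", "replicate")]
  design$sample <- sprintf("%s_t%g_r%d", design$condition, design$time_h,
                           design$replicate)
  nSamples <- nrow(design)

  allTimes <- sort(unique(c(spec@controlTimepoints, spec@stressTimepoints)))
  nT <- length(allTimes)
  nonTarget <- setdiff(genes, spec@targetId)

  mat <- withSeed(spec@seed, {
    m <- matrix(0, nrow = length(genes), ncol = nSamples,
                dimnames = list(genes, design$sample))
    # per-gene baselines and stationary AR(1) latent trajectories
    base <- rnorm(length(nonTarget), spec@baselineMean, spec@baselineSd)
    names(base) <- nonTarget
    latent <- matrix(0, nrow = length(nonTarget), ncol = nT,
                     dimnames = list(nonTarget, as.character(allTimes)))
    innov <- matrix(rnorm(length(nonTarget) * nT), nrow = length(nonTarget))
    latent[, 1L] <- base + spec@baselineSd * innov[, 1L]
    if (nT > 1L) {
      sdInn <- spec@baselineSd * sqrt(1 - spec@arCor^2)
      for (k in 2L:nT)
        latent[, k] <- base + spec@arCor * (latent[, k - 1L] - base) +
          sdInn * innov[, k]
    }
    # realized expression of every non-target gene
    stressReg <- reg$gene[reg$condition == "stress"]
    repNoise <- matrix(rnorm(length(nonTarget) * nSamples, 0, spec@noiseSd),
                       nrow = length(nonTarget))
    for (j in seq_len(nSamples)) {
      tj <- design$time_h[j]
      x <- latent[, as.character(tj)]
      if (design$condition[j] == "stress" && length(stressReg)) {
        t0 <- reg$activationTime[match(stressReg, reg$gene)]
        bump <- spec@inductionAmplitude *
          exp(-(tj - t0)^2 / (2 * spec@inductionWidth^2))
        x[stressReg] <- x[stressReg] + bump
      }
      m[nonTarget, j] <- x + repNoise[, j]
    }
    # target = condition-dependent linear combination of realized regulators
    eps <- rnorm(nSamples, 0, spec@noiseSd)
    for (j in seq_len(nSamples)) {
      active <- reg$condition == "both" | reg$condition == design$condition[j]
      m[spec@targetId, j] <-
        sum(reg$beta[active] * m[reg$gene[active], j]) + eps[j]
    }
    m
  })

  gt <- data.frame(regulator = reg$gene,
                   target = rep(spec@targetId, nrow(reg)),
                   beta = reg$beta,
                   condition = reg$condition,
                   stringsAsFactors = FALSE)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(logexpr = mat),
    colData = S4Vectors::DataFrame(design[, c("condition", "time_h",
                                              "replicate")],
                                   row.names = design$sample))
  new("GrnSimulation", se, groundTruth = gt)
}

#' Corrupt a ground-truth regulator set into a noisy evidence list
#'
#' Emulates experimental evidence lists (a one-hybrid hit list, a
#' promoter binding-evidence list) that contain the functional regulator
#' alongside false positives: each true regulator is included with
#' probability `sensitivity`, each other gene of the universe with
#' probability `fpRate`.
#'
#' @param truth a [GrnSimulation-class], a ground-truth edge `data.frame`
#'   (column `regulator`), or a character vector of true regulators.
#' @param universe character vector of all genes an assay could return;
#'   must contain the true regulators.
#' @param sensitivity,fpRate inclusion probabilities in \[0, 1\].
#' @param seed RNG seed; a fixed seed gives a fixed list.
#' @return Character vector: the corrupted evidence list (true positives
#'   first, then false positives, each in `universe` order).
#' @examples
#' sim <- simulateExpression(grnSpec(seed = 3))
#' corruptEvidence(sim, rownames(sim), sensitivity = 1, fpRate = 0.05,
#'                 seed = 11)
#' @export
corruptEvidence <- function(truth, universe, sensitivity, fpRate, seed) {
  if (is(truth, "GrnSimulation")) truth <- groundTruth(truth)
  if (is.data.frame(truth)) truth <- truth$regulator
  regs <- unique(as.character(truth))
  if (sensitivity < 0 || sensitivity > 1 || fpRate < 0 || fpRate > 1)
    stop("sensitivity and fpRate must lie in [0, 1]")
  if (!all(regs %in% universe))
    stop("universe must contain every true regulator")
  regs <- universe[universe %in% regs]
  others <- setdiff(universe, regs)
  withSeed(seed, {
    keepTrue <- regs[runif(length(regs)) <= sensitivity]
    keepFalse <- others[runif(length(others)) <= fpRate]
    c(keepTrue, keepFalse)
  })
}
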