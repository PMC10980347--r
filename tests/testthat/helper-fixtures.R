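# Shared fixture builders. All data are generated in code; nothing is
# read from disk.

# a small noiseless single-regulator simulation (exact linear target)
noiselessSim <- function(nGenes = 6, beta = 2, seed = 2) {
  simulateExpression(grnSpec(
    nGenes = nGenes, noiseSd = 0, seed = seed,
    regulators = data.frame(gene = "TF001", beta = beta,
                            condition = "stress", activationTime = 3,
                            stringsAsFactors = FALSE)))
}

assayOf <- function(sim) SummarizedExperiment::assay(sim)

conditionCols <- function(sim, cond) {
  m <- assayOf(sim)
  m[, SummarizedExperiment::colData(sim)$condition == cond, drop = FALSE]
}

# independently coded pooled two-sample t oracle (textbook formula)
pooledTOracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), df = na + nb - 2))
}

# brute-force BH step-up oracle: p_(i) * m / i with cumulative min from
# the largest p downward, capped at 1, mapped back to input order
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  if (m == 1) adj <- pmin(p, 1)
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# iid-noise expression panel (no structure, no true edges)
pureNoiseMatrix <- function(nGenes, seed) {
  sim <- simulateExpression(grnSpec(
    nGenes = nGenes, regulators = noRegulators(), baselineSd = 0,
    seed = seed))
  conditionCols(sim, "stress")
}

# consensus table with a regulator sitting exactly on the 0.80 boundary
mkConsensus80 <- function() {
  tb <- data.frame(regulator = c("high", "edge80", "low"),
                   count = c(95L, 80L, 10L),
                   frequency = c(95, 80, 10) / 100,
                   mean_importance = c(0.3, 0.2, 0.1),
                   rank = 1:3,
                   stringsAsFactors = FALSE)
  methods::new("ConsensusResult", table = tb, nRuns = 100L, target = "T",
               baseSeed = 0L)
}
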