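test_that("paper-shaped preset yields a 94 x 24 experiment with metadata", {
  sim <- simulateExpression(grnSpec(seed = 1))
  expect_identical(dim(sim), c(94L, 24L))
  cd <- SummarizedExperiment::colData(sim)
  expect_identical(sum(cd$condition == "control"), 6L)   # 2 tp x 3 reps
  expect_identical(sum(cd$condition == "stress"), 18L)   # 6 tp x 3 reps
  expect_true(all(c("condition", "time_h", "replicate") %in% colnames(cd)))
  expect_false(anyDuplicated(rownames(sim)) > 0)
})

test_that("identical spec and seed reproduce the matrix exactly", {
  a <- simulateExpression(grnSpec(seed = 11))
  b <- simulateExpression(grnSpec(seed = 11))
  expect_identical(assayOf(a), assayOf(b))
  expect_false(identical(assayOf(a), assayOf(simulateExpression(grnSpec(seed = 12)))))
})

test_that("noiseless target is an exact linear function of its regulator", {
  sim <- noiselessSim(beta = 2)
  m <- assayOf(sim)
  stress <- SummarizedExperiment::colData(sim)$condition == "stress"
  expect_identical(m["TARGET", stress], 2 * m["TF001", stress])
})

test_that("stress-specific regulators have zero effect in control samples", {
  sim <- noiselessSim(beta = 2)
  m <- assayOf(sim)
  ctrl <- SummarizedExperiment::colData(sim)$condition == "control"
  expect_true(all(m["TARGET", ctrl] == 0))
  # and the within-condition regression slope is exactly zero
  fit <- lm(m["TARGET", ctrl] ~ m["TF001", ctrl])
  expect_equal(unname(coef(fit)[2]), 0)
})

test_that("ground truth carries no self-edges and lives in the panel", {
  sim <- simulateExpression(grnSpec(seed = 3))
  gt <- groundTruth(sim)
  expect_true(all(gt$regulator != gt$target))
  expect_true(all(gt$regulator %in% rownames(sim)))
})

test_that("invalid designs are rejected", {
  expect_error(grnSpec(targetId = "TF001"), "own regulators")
  expect_error(grnSpec(noiseSd = -1), "nonnegative")
  expect_error(grnSpec(nGenes = 0), "positive")
  expect_error(
    simulateExpression(grnSpec(nGenes = 2,
      regulators = data.frame(gene = c("A", "B"), beta = 1,
                              condition = "stress", activationTime = 3))),
    "smaller")
})

test_that("a pure-noise panel has no edges and a noise-only target", {
  sim <- simulateExpression(grnSpec(nGenes = 10, regulators = noRegulators(),
                                    noiseSd = 0, seed = 5))
  expect_identical(nrow(groundTruth(sim)), 0L)
  expect_true(all(assayOf(sim)["TARGET", ] == 0))
})

test_that("corruptEvidence honors boundary rates exactly", {
  sim <- noiselessSim()
  universe <- rownames(sim)
  expect_identical(corruptEvidence(sim, universe, 1, 0, seed = 1), "TF001")
  expect_identical(corruptEvidence(sim, universe, 0, 0, seed = 1),
                   character(0))
  full <- corruptEvidence(sim, universe, 1, 1, seed = 1)
  expect_setequal(full, universe)
  expect_error(corruptEvidence(sim, universe, 1.2, 0, seed = 1), "0, 1")
  expect_error(corruptEvidence("TF999", universe, 1, 0, seed = 1),
               "universe")
})

test_that("corruptEvidence is seed-deterministic and binomially sized", {
  sim <- noiselessSim(nGenes = 21)  # 20 non-target genes, 1 true regulator
  universe <- setdiff(rownames(sim), "TARGET")
  a <- corruptEvidence(sim, universe, 0.7, 0.5, seed = 9)
  b <- corruptEvidence(sim, universe, 0.7, 0.5, seed = 9)
  expect_identical(a, b)
  # E|set| = 1 + 0.5 * 19 = 10.5 over many seeds (binomial mean)
  sizes <- vapply(1:1000, function(s)
    length(corruptEvidence(sim, universe, 1, 0.5, seed = s)), numeric(1))
  expect_equal(mean(sizes), 1 + 19 * 0.5,
               tolerance = 3 * sqrt(19 * 0.25 / 1000) / (1 + 19 * 0.5))
  expect_true(all(vapply(1:50, function(s)
    "TF001" %in% corruptEvidence(sim, universe, 1, 0.5, seed = s),
    logical(1))))
})
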