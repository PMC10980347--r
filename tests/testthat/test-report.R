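# build a ConsensusResult directly from named frequencies
mkConsensus <- function(freqs, nRuns = 100L, target = "T") {
  counts <- as.integer(round(freqs * nRuns))
  tb <- data.frame(regulator = names(freqs), count = counts,
                   frequency = counts / nRuns,
                   mean_importance = rev(seq_along(freqs)) / 100,
                   stringsAsFactors = FALSE)
  ord <- order(-tb$frequency, -tb$mean_importance, tb$regulator)
  tb <- tb[ord, , drop = FALSE]
  tb$rank <- seq_len(nrow(tb))
  rownames(tb) <- NULL
  new("ConsensusResult", table = tb, nRuns = nRuns, target = target,
      baseSeed = 0L)
}

test_that("condition-specificity is an exact three-way partition", {
  cls <- classifyConditionSpecific(c("z", "a", "b"), c("a"))
  expect_identical(cls$stress_only, c("z", "b"))
  expect_identical(cls$shared, "a")
  expect_identical(cls$control_only, character(0))
  expect_identical(classifyConditionSpecific(c("x"), c("y"))$shared,
                   character(0))
  eq <- classifyConditionSpecific(c("p", "q"), c("q", "p"))
  expect_identical(eq$stress_only, character(0))
  expect_identical(eq$control_only, character(0))
  union <- unlist(cls)
  expect_false(anyDuplicated(union) > 0)
})

test_that("binding filtering is an order-preserving intersection", {
  regs <- sprintf("R%02d", 1:13)
  binding <- c("R11", "R02", "R07", "R05", "other")
  kept <- filterByBinding(regs, binding)
  expect_identical(kept, c("R02", "R05", "R07", "R11"))
  expect_identical(length(kept), 4L)
  expect_identical(filterByBinding(regs, character(0)), character(0))
  expect_identical(filterByBinding(regs, regs), regs)
})

test_that("a maximal-frequency binding-evidenced stress regulator is priority 1", {
  stress <- mkConsensus(c(star = 1.0, other = 0.9, weak = 0.3))
  control <- mkConsensus(c(ctrlA = 0.5, other = 0.45, star = 0.1))
  rep <- buildReport(stress, control, bindingSet = c("star", "ctrlA"))
  tb <- as.data.frame(rep)
  expect_identical(tb$regulator[tb$final_priority == 1], "star")
  expect_identical(tb$class[tb$regulator == "star"], "stress-specific")
  expect_identical(tb$class[tb$regulator == "other"], "shared")
  expect_identical(tb$class[tb$regulator == "ctrlA"], "control-specific")
  expect_false("weak" %in% tb$regulator)
  expect_true(tb$binding_evidence[tb$regulator == "star"])
})

test_that("report classes partition the thresholded union exactly", {
  stress <- mkConsensus(c(a = 0.95, b = 0.85, c = 0.5))
  control <- mkConsensus(c(b = 0.6, d = 0.41, e = 0.2))
  rep <- buildReport(stress, control)
  tb <- as.data.frame(rep)
  expect_setequal(tb$regulator, c("a", "b", "d"))
  expect_false(anyDuplicated(tb$regulator) > 0)
  expect_identical(sort(tb$final_priority), seq_len(nrow(tb)))
  # stress-specific <=> retained under stress and not under control
  expect_identical(tb$class[tb$regulator == "a"], "stress-specific")
  expect_identical(tb$class[tb$regulator == "b"], "shared")
  expect_identical(tb$class[tb$regulator == "d"], "control-specific")
})

test_that("an empty report arises when nothing passes thresholds", {
  stress <- mkConsensus(c(a = 0.2))
  control <- mkConsensus(c(b = 0.1))
  rep <- buildReport(stress, control)
  expect_identical(nrow(as.data.frame(rep)), 0L)
})

test_that("ties fall back to lexicographic regulator order", {
  stress <- mkConsensus(c(zed = 0.9, ant = 0.9))
  control <- mkConsensus(c(none = 0.05))
  rep <- buildReport(stress, control)
  tb <- as.data.frame(rep)
  expect_identical(tb$regulator, c("ant", "zed"))
})

test_that("threshold validation is enforced", {
  stress <- mkConsensus(c(a = 0.9))
  expect_error(buildReport(stress, stress, thresholds = c(stress = 2,
                                                          control = 0.4)),
               "0, 1")
  expect_error(buildReport(stress, stress, thresholds = c(0.8, 0.4)),
               "named")
})
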