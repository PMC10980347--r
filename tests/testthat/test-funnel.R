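degFixture <- function() {
  data.frame(gene = c("up", "weak", "downer", "flat"),
             log2_fc = c(1.0, 0.9, -1.4, 0.0),
             s2_g = 0.1, d_g = 4L,
             t_mod = c(5, 4, -6, 0),
             p = c(0.001, 1e-6, 1e-4, 0.9),
             p_adj = c(0.001, 4e-6, 2e-4, 0.9),
             stringsAsFactors = FALSE)
}

test_that("DEG thresholds are inclusive at the boundary", {
  tab <- degFixture()
  # exactly 2-fold and exactly at the p ceiling is retained
  expect_true("up" %in% callDegs(tab, lfcMin = 1, pMax = 0.001))
  # below the fold-change bound is excluded however small the p-value
  expect_false("weak" %in% callDegs(tab, lfcMin = 1, pMax = 0.001))
})

test_that("direction filtering and the full-universe identity hold", {
  tab <- degFixture()
  expect_setequal(callDegs(tab, 1, 0.001, direction = "both"),
                  c("up", "downer"))
  expect_identical(callDegs(tab, 1, 0.001, direction = "up"), "up")
  expect_identical(callDegs(tab, 1, 0.001, direction = "down"), "downer")
  expect_setequal(callDegs(tab, lfcMin = 0, pMax = 1), tab$gene)
  expect_identical(callDegs(tab[0, ], 1, 0.001), character(0))
  expect_error(callDegs(tab, -1, 0.5), "lfcMin")
})

test_that("overlapSets partitions exactly", {
  ov <- overlapSets(c("g1", "g2", "g3"), c("g2", "g3", "g4"))
  expect_identical(ov$intersection, c("g2", "g3"))
  expect_identical(ov$a_only, "g1")
  expect_identical(ov$b_only, "g4")
  expect_identical(overlapSets(c("a", "b"), c("c"))$intersection,
                   character(0))
  sub <- overlapSets(c("x", "y"), c("x", "y", "z"))
  expect_identical(sub$a_only, character(0))
  expect_identical(length(sub$intersection), 2L)
  # |intersection| + |a_only| = |set_a|
  expect_identical(length(ov$intersection) + length(ov$a_only), 3L)
})

test_that("candidate panel reproduces the 91 + 2 + 1 funnel arithmetic", {
  y1h <- sprintf("Y%03d", 1:300)           # screen-scale hit list
  overlap <- c(sprintf("Y%03d", 1:91), sprintf("D%03d", 1:500))
  known <- c("ARF_A", "ARF_B")
  msgs <- capture_messages(
    cand <- buildCandidateList(overlap, y1h, known, "the_target"))
  expect_identical(nrow(cand), 94L)
  expect_identical(sum(cand$provenance == "one-hybrid"), 91L)
  expect_identical(sum(cand$provenance == "known-regulator"), 2L)
  expect_identical(sum(cand$provenance == "target"), 1L)
  expect_match(msgs, "91 one-hybrid", all = FALSE)
  expect_match(msgs, "94 candidates", all = FALSE)
})

test_that("provenance precedence deduplicates overlapping classes", {
  suppressMessages({
    cand <- buildCandidateList(c("k1", "h1"), y1hHits = c("k1", "h1"),
                               knownRegulators = "k1", target = "t")
  })
  expect_identical(sum(cand$gene == "k1"), 1L)
  expect_identical(cand$provenance[cand$gene == "k1"], "known-regulator")
  # target trumps everything
  suppressMessages({
    cand2 <- buildCandidateList("t", y1hHits = "t", knownRegulators = "t",
                                target = "t")
  })
  expect_identical(cand2$gene, "t")
  expect_identical(cand2$provenance, "target")
})

test_that("candidate list size follows the union formula", {
  suppressMessages({
    cand <- buildCandidateList(character(0), character(0), c("a", "b"), "t")
  })
  expect_identical(nrow(cand), 3L)
  set.seed(4)
  for (i in 1:20) {
    ov <- sample(letters, 10)
    y1 <- sample(letters, 8)
    kn <- sample(letters, 3)
    y1Kept <- setdiff(intersect(sort(unique(y1)), ov), c(kn, "zz"))
    expected <- length(y1Kept) + length(setdiff(unique(kn), "zz")) + 1L
    suppressMessages(cand <- buildCandidateList(ov, y1, kn, "zz"))
    expect_identical(nrow(cand), expected)
    expect_false(anyDuplicated(cand$gene) > 0)
  }
})
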