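mkMatrix <- function(nGenes, nA, nB, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(nGenes * (nA + nB)), nrow = nGenes,
              dimnames = list(sprintf("g%04d", seq_len(nGenes)),
                              sprintf("s%02d", seq_len(nA + nB))))
  list(m = m, a = sprintf("s%02d", seq_len(nA)),
       b = sprintf("s%02d", nA + seq_len(nB)))
}

test_that("d0 = 0 reproduces the ordinary pooled two-sample t-test", {
  # hand-checkable example: groups (1,2,3) vs (2,3,4)
  m <- matrix(c(1, 2, 3, 2, 3, 4), nrow = 1,
              dimnames = list("g1", paste0("s", 1:6)))
  res <- moderatedTTest(m, paste0("s", 1:3), paste0("s", 4:6),
                        prior = shrinkagePrior(0, 1))
  oracle <- pooledTOracle(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$t_mod, oracle$t, tolerance = 1e-12)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
  expect_equal(res$log2_fc, -1)
  expect_identical(res$d_g, 4L)

  # and on random matrices within 1e-8
  fix <- mkMatrix(200, 4, 5, seed = 42)
  res <- moderatedTTest(fix$m, fix$a, fix$b, prior = shrinkagePrior(0, 1))
  orc <- t(apply(fix$m, 1, function(x)
    unlist(pooledTOracle(x[1:4], x[5:9]))))
  expect_equal(res$t_mod, unname(orc[, "t"]), tolerance = 1e-8)
  expect_equal(res$p, unname(orc[, "p"]), tolerance = 1e-8)
})

test_that("identical group means give t = 0 and p = 1", {
  m <- matrix(c(1, 5, 3, 3, 1, 5), nrow = 1,
              dimnames = list("g1", paste0("s", 1:6)))
  res <- moderatedTTest(m, paste0("s", 1:3), paste0("s", 4:6),
                        prior = shrinkagePrior(2, 1))
  expect_equal(res$t_mod, 0)
  expect_equal(res$p, 1)
})

test_that("a huge prior df forces the posterior variance to s0sq", {
  fix <- mkMatrix(50, 3, 3)
  res <- moderatedTTest(fix$m, fix$a, fix$b,
                        prior = shrinkagePrior(1e9, 0.7))
  sTilde2 <- (res$log2_fc / res$t_mod)^2 / (1 / 3 + 1 / 3)
  expect_equal(sTilde2, rep(0.7, 50), tolerance = 1e-5)
  # d0 = Inf is exact
  resInf <- moderatedTTest(fix$m, fix$a, fix$b,
                           prior = shrinkagePrior(Inf, 0.7))
  sT2 <- (resInf$log2_fc / resInf$t_mod)^2 / (2 / 3)
  expect_equal(sT2, rep(0.7, 50), tolerance = 1e-12)
})

test_that("posterior variance lies between the sample and prior variance", {
  fix <- mkMatrix(300, 4, 4, seed = 7)
  for (d0 in c(0.5, 2, 20)) {
    res <- moderatedTTest(fix$m, fix$a, fix$b,
                          prior = shrinkagePrior(d0, 0.5))
    sTilde2 <- (d0 * 0.5 + res$d_g * res$s2_g) / (d0 + res$d_g)
    expect_true(all(sTilde2 >= pmin(res$s2_g, 0.5) - 1e-12))
    expect_true(all(sTilde2 <= pmax(res$s2_g, 0.5) + 1e-12))
  }
})

test_that("estimated prior matches limma's empirical-Bayes machinery", {
  fix <- mkMatrix(400, 4, 4, seed = 99)
  res <- moderatedTTest(fix$m, fix$a, fix$b, prior = "estimate")
  prior <- attr(res, "prior")
  expect_true(prior$d0 > 0)
  expect_true(prior$s0sq > 0)
  # independent route: limma lmFit/eBayes moderated t on the same design
  design <- cbind(1, rep(c(1, 0), each = 4))
  fit <- limma::eBayes(limma::lmFit(fix$m, design))
  expect_equal(unname(res$t_mod), unname(fit$t[, 2]), tolerance = 1e-6)
  # limma caps its total df at the summed residual df, so p-values can
  # differ in the 4th decimal when the estimated d0 is very large
  expect_equal(unname(res$p), unname(fit$p.value[, 2]), tolerance = 1e-3)
})

test_that("zero-variance genes behave as documented", {
  m <- rbind(g1 = c(1, 1, 1, 2, 2, 2), g2 = c(3, 3, 3, 3, 3, 3))
  colnames(m) <- paste0("s", 1:6)
  # d0 = 0: means differ -> p = 0; means equal -> p = 1
  res0 <- moderatedTTest(m, paste0("s", 1:3), paste0("s", 4:6),
                         prior = shrinkagePrior(0, 1))
  expect_equal(res0$p, c(0, 1))
  # d0 > 0: shrinkage rescues a finite statistic
  res1 <- moderatedTTest(m, paste0("s", 1:3), paste0("s", 4:6),
                         prior = shrinkagePrior(4, 0.5))
  expect_true(all(is.finite(res1$t_mod)))
})

test_that("group preconditions are enforced", {
  fix <- mkMatrix(5, 3, 3)
  expect_error(moderatedTTest(fix$m, fix$a, fix$a), "disjoint")
  expect_error(moderatedTTest(fix$m, fix$a[1], fix$b), "at least 2")
  expect_error(moderatedTTest(fix$m, c(fix$a, "nope"), fix$b), "present")
  cm <- matrix(1, 3, 4, dimnames = list(letters[1:3], LETTERS[1:4]))
  expect_error(moderatedTTest(cm, LETTERS[1:2], LETTERS[3:4],
                              prior = "estimate"), "all-constant")
})

test_that("bhAdjust matches hand and brute-force step-up computations", {
  expect_equal(bhAdjust(0.03), 0.03)                       # m = 1 identity
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
  set.seed(8)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bhAdjust(p), bhOracle(p), tolerance = 1e-14)
  }
  # adjusted values never fall below raw and are monotone in p order
  set.seed(9)
  p <- runif(100)
  adj <- bhAdjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})
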