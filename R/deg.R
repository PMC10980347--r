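#' Empirical-Bayes variance shrinkage prior
#'
#' @param d0 prior degrees of freedom (> 0, may be `Inf`).
#' @param s0sq prior variance (> 0).
#' @return A named list with components `d0` and `s0sq`.
#' @export
shrinkagePrior <- function(d0, s0sq) {
  if (!(d0 >= 0)) stop("d0 must be nonnegative")
  if (!(s0sq > 0) && d0 > 0) stop("s0sq must be positive")
  list(d0 = d0, s0sq = s0sq)
}

#' Moderated two-group t-test with empirical-Bayes variance shrinkage
#'
#' For each gene, computes the mean difference on the log2 scale
#' (`group_a` minus `group_b`), the pooled two-group residual variance
#' `s2_g` on `d_g = n_a + n_b - 2` degrees of freedom, the posterior
#' variance
#' \deqn{\tilde s^2 = (d_0 s_0^2 + d_g s^2_g) / (d_0 + d_g),}
#' the moderated statistic
#' \eqn{t = \mathrm{lfc} / (\tilde s \sqrt{1/n_a + 1/n_b})}, and a
#' two-sided p-value on a t distribution with \eqn{d_0 + d_g} degrees of
#' freedom. With `d0 = 0` this is the ordinary pooled two-sample t-test;
#' as `d0` grows the posterior variance approaches `s0sq` for every gene.
#'
#' With `prior = "estimate"` the prior `(d0, s0sq)` is fitted to the
#' observed sample variances by moment matching on the log scale
#' (the scaled-F fit of `limma::fitFDist`); `d0` comes back infinite when
#' the variance of the log sample variances falls at or below its
#' theoretical sampling floor.
#'
#' Genes with zero residual variance are a documented edge case: under
#' `d0 > 0` shrinkage gives them a finite statistic; under `d0 = 0` they
#' yield `p = 0` when the group means differ and `p = 1` otherwise.
#'
#' @param x genes x samples numeric matrix or `SummarizedExperiment`.
#' @param groupA,groupB disjoint sets of sample identifiers (or column
#'   indices), each of size >= 2.
#' @param prior `"estimate"` or a [shrinkagePrior()] list.
#' @return A `data.frame` (one row per gene) with columns `gene`,
#'   `log2_fc`, `s2_g`, `d_g`, `t_mod`, `p`, `p_adj`
#'   (Benjamini-Hochberg), carrying the fitted prior in attribute
#'   `"prior"`.
#' @examples
#' m <- matrix(rnorm(60), 10, 6,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
#' moderatedTTest(m, paste0("s", 1:3), paste0("s", 4:6), prior = "estimate")
#' @export
moderatedTTest <- function(x, groupA, groupB, prior = "estimate") {
  x <- asExpressionMatrix(x)
  idxA <- if (is.numeric(groupA)) groupA else match(groupA, colnames(x))
  idxB <- if (is.numeric(groupB)) groupB else match(groupB, colnames(x))
  if (anyNA(idxA) || anyNA(idxB))
    stop("all samples must be present in the matrix")
  if (length(intersect(idxA, idxB))) stop("groups must be disjoint")
  nA <- length(idxA); nB <- length(idxB)
  if (nA < 2L || nB < 2L) stop("each group needs at least 2 samples")

  mA <- rowMeans(x[, idxA, drop = FALSE])
  mB <- rowMeans(x[, idxB, drop = FALSE])
  lfc <- mA - mB
  ssA <- rowSums((x[, idxA, drop = FALSE] - mA)^2)
  ssB <- rowSums((x[, idxB, drop = FALSE] - mB)^2)
  dg <- nA + nB - 2L
  s2 <- (ssA + ssB) / dg

  if (identical(prior, "estimate")) {
    if (all(s2 <= 1e-300))
      stop("cannot estimate a variance prior from an all-constant matrix")
    fit <- limma::fitFDist(s2, df1 = dg)
    prior <- shrinkagePrior(d0 = fit$df2, s0sq = fit$scale)
  }
  d0 <- prior$d0; s0sq <- prior$s0sq

  sTilde2 <- if (is.infinite(d0)) rep(s0sq, length(s2)) else
    (d0 * s0sq + dg * s2) / (d0 + dg)
  se <- sqrt(sTilde2 * (1 / nA + 1 / nB))
  tmod <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  dfTotal <- d0 + dg
  p <- 2 * pt(-abs(tmod), df = dfTotal)
  p[is.infinite(tmod)] <- 0

  out <- data.frame(gene = rownames(x), log2_fc = lfc, s2_g = s2,
                    d_g = dg, t_mod = tmod, p = p,
                    p_adj = bhAdjust(p), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "prior") <- prior
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated interface over `p.adjust(method = "BH")`: step-up
#' adjusted p-values, capped at 1, monotone in the order statistics of
#' the input.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' Retains genes whose fold change and p-value pass the thresholds, both
#' comparisons inclusive: `|log2_fc| >= lfcMin` (restricted by
#' `direction`) and chosen p-column `<= pMax`.
#'
#' @param table a `DegTable` data.frame from [moderatedTTest()].
#' @param lfcMin minimum absolute log2 fold change (default 1, i.e. at
#'   least 2-fold).
#' @param pMax p-value ceiling.
#' @param useAdjusted compare `p_adj` (default) rather than raw `p`.
#' @param direction `"both"` (default), `"up"` (log2_fc >= lfcMin) or
#'   `"down"` (log2_fc <= -lfcMin).
#' @return Character vector of retained gene identifiers.
#' @export
callDegs <- function(table, lfcMin = 1, pMax = 0.001, useAdjusted = TRUE,
                     direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  if (!is.finite(lfcMin) || lfcMin < 0) stop("lfcMin must be finite and >= 0")
  if (!is.finite(pMax)) stop("pMax must be finite")
  if (!nrow(table)) return(character(0))
  pcol <- if (useAdjusted) table$p_adj else table$p
  passFc <- switch(direction,
                   both = abs(table$log2_fc) >= lfcMin,
                   up = table$log2_fc >= lfcMin,
                   down = table$log2_fc <= -lfcMin)
  table$gene[passFc & pcol <= pMax]
}
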