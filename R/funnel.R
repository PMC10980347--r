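#' Partition two gene sets
#'
#' @param setA,setB character vectors (treated as sets).
#' @return List with elements `intersection`, `a_only`, `b_only`;
#'   `intersection` and `a_only` follow the order of `setA`, `b_only`
#'   the order of `setB`.
#' @export
overlapSets <- function(setA, setB) {
  setA <- unique(as.character(setA))
  setB <- unique(as.character(setB))
  list(intersection = setA[setA %in% setB],
       a_only = setA[!setA %in% setB],
       b_only = setB[!setB %in% setA])
}

#' Assemble the candidate panel entering network inference
#'
#' The panel is the deduplicated union of the one-hybrid hits that
#' survive the differential-expression overlap, the known regulators,
#' and the target itself. When a gene qualifies under several classes,
#' provenance precedence is target > known-regulator > one-hybrid. The
#' order is deterministic: target first, then known regulators, then
#' one-hybrid hits, alphabetically within each class.
#'
#' @param overlapDegs genes passing the differential-expression overlap.
#' @param y1hHits one-hybrid candidate regulators (filtered against
#'   `overlapDegs` before inclusion).
#' @param knownRegulators regulators included unconditionally.
#' @param target the target gene identifier (single string).
#' @return A `data.frame` with columns `gene` and `provenance`
#'   (`"target"`, `"known-regulator"`, `"one-hybrid"`).
#' @examples
#' buildCandidateList(overlapDegs = c("a", "b", "c"),
#'                    y1hHits = c("b", "z"),
#'                    knownRegulators = c("k1", "k2"),
#'                    target = "t")
#' @export
buildCandidateList <- function(overlapDegs, y1hHits, knownRegulators,
                               target) {
  if (length(target) != 1L || !nzchar(target))
    stop("target must be a single identifier")
  y1h <- sort(unique(as.character(y1hHits)))
  y1h <- y1h[y1h %in% overlapDegs]
  known <- sort(unique(as.character(knownRegulators)))
  y1h <- setdiff(y1h, c(known, target))
  known <- setdiff(known, target)
  out <- data.frame(
    gene = c(target, known, y1h),
    provenance = c("target",
                   rep("known-regulator", length(known)),
                   rep("one-hybrid", length(y1h))),
    stringsAsFactors = FALSE)
  if (!nrow(out)) stop("candidate list is empty")
  message(sprintf(
    "candidate funnel: %d one-hybrid (of %d, after overlap with %d DEGs) + %d known + 1 target = %d candidates",
    length(y1h), length(unique(y1hHits)), length(unique(overlapDegs)),
    length(known), nrow(out)))
  out
}
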