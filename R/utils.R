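# Evaluate code under a fixed seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Extract the genes x samples numeric matrix from a matrix-like input.
asExpressionMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) x <- SummarizedExperiment::assay(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression input must be a numeric matrix or SummarizedExperiment")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicated gene identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (any(!is.finite(x)))
    stop("expression matrix contains non-finite values")
  x
}

# Candidate identifiers from a CandidateList data.frame or character vector.
asCandidateIds <- function(candidates) {
  if (is.data.frame(candidates)) {
    if (!"gene" %in% names(candidates))
      stop("candidate data.frame must have a 'gene' column")
    candidates <- candidates$gene
  }
  candidates <- as.character(candidates)
  if (anyDuplicated(candidates)) stop("duplicated candidate identifiers")
  candidates
}
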