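# Readers and writers for the pipeline's plain-text interchange formats.
# Gene identifiers are opaque case-sensitive strings throughout and are
# never parsed or case-folded. Numeric columns are written with 17
# significant digits so that write-then-read round-trips are exact.

fmtNum <- function(x) formatC(x, digits = 17, format = "g", width = -1)

detectSep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Write / read a genes x samples expression matrix as TSV
#'
#' First column holds gene identifiers, the header row sample
#' identifiers. The reader auto-detects tab versus comma dialect from
#' the header line.
#'
#' @param x numeric matrix or `SummarizedExperiment`.
#' @param path output (or input) file path.
#' @return `writeExpressionMatrix` returns `path` invisibly;
#'   `readExpressionMatrix` returns a numeric matrix with gene rownames
#'   and sample colnames.
#' @export
writeExpressionMatrix <- function(x, path) {
  m <- asExpressionMatrix(x)
  out <- data.frame(gene = rownames(m), apply(m, 2, fmtNum),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("gene", colnames(m))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeExpressionMatrix
#' @export
readExpressionMatrix <- function(path) {
  sep <- detectSep(path)
  df <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    stop("duplicated gene identifier(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression value in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicated sample identifiers")
  rownames(m) <- genes
  m
}

#' Write / read a sample-metadata table
#'
#' Columns `sample`, `condition`, `time_h`, `replicate`.
#'
#' @param x a `SummarizedExperiment` (its `colData` is written) or a
#'   data.frame with the four columns.
#' @param path file path.
#' @return The metadata `data.frame` (reader); `path` invisibly
#'   (writer).
#' @export
writeSampleMetadata <- function(x, path) {
  if (is(x, "SummarizedExperiment")) {
    df <- as.data.frame(SummarizedExperiment::colData(x))
    df <- data.frame(sample = rownames(df), df, row.names = NULL,
                     stringsAsFactors = FALSE)
  } else df <- x
  need <- c("sample", "condition", "time_h", "replicate")
  if (!all(need %in% names(df)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  write.table(df[, need], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeSampleMetadata
#' @export
readSampleMetadata <- function(path) {
  read.table(path, sep = detectSep(path), header = TRUE,
             stringsAsFactors = FALSE)
}

#' Assemble a `SummarizedExperiment` from expression and metadata files
#'
#' @param exprPath expression matrix TSV/CSV.
#' @param metadataPath sample metadata TSV/CSV; every metadata sample
#'   must be a column of the matrix.
#' @return A `SummarizedExperiment` with assay `"logexpr"`, restricted
#'   to the metadata samples in metadata order.
#' @export
readExperiment <- function(exprPath, metadataPath) {
  m <- readExpressionMatrix(exprPath)
  meta <- readSampleMetadata(metadataPath)
  missing <- setdiff(meta$sample, colnames(m))
  if (length(missing))
    stop("metadata sample(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  m <- m[, meta$sample, drop = FALSE]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(logexpr = m),
    colData = S4Vectors::DataFrame(
      meta[, setdiff(names(meta), "sample"), drop = FALSE],
      row.names = meta$sample))
}

#' Write / read a gene list (one identifier per line)
#'
#' @param genes character vector.
#' @param path file path.
#' @return Character vector (reader); `path` invisibly (writer).
#' @export
writeGeneList <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' @rdname writeGeneList
#' @export
readGeneList <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

#' Write / read a regulator-target edge list as 3-column TSV
#'
#' Columns `regulator`, `target`, `importance`, with header.
#'
#' @param edges edge `data.frame` from [inferEdges()].
#' @param path file path.
#' @return Edge `data.frame` (reader); `path` invisibly (writer).
#' @export
writeEdgeList <- function(edges, path) {
  out <- edges
  out$importance <- fmtNum(out$importance)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEdgeList
#' @export
readEdgeList <- function(path) {
  df <- read.table(path, sep = detectSep(path), header = TRUE,
                   stringsAsFactors = FALSE)
  df$importance <- as.numeric(df$importance)
  df
}

#' Write / read a consensus table as TSV
#'
#' The table body has columns `regulator`, `count`, `frequency`,
#' `mean_importance`, `rank`; `#`-prefixed header lines carry the
#' target, the number of runs and the base seed so the file round-trips
#' to a full [ConsensusResult-class].
#'
#' @param x a [ConsensusResult-class].
#' @param path file path.
#' @return A `ConsensusResult` (reader); `path` invisibly (writer).
#' @export
writeConsensusTable <- function(x, path) {
  stopifnot(is(x, "ConsensusResult"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# target=%s", x@target),
               sprintf("# n_runs=%d", x@nRuns),
               sprintf("# base_seed=%d", x@baseSeed)), con)
  tb <- x@table
  tb$frequency <- fmtNum(tb$frequency)
  tb$mean_importance <- fmtNum(tb$mean_importance)
  write.table(tb, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeConsensusTable
#' @export
readConsensusTable <- function(path) {
  hdr <- readLines(path, n = 3L)
  meta <- sub("^# *", "", hdr)
  kv <- strsplit(meta, "=", fixed = TRUE)
  vals <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  tb <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  tb$frequency <- as.numeric(tb$frequency)
  tb$mean_importance <- as.numeric(tb$mean_importance)
  new("ConsensusResult", table = tb,
      nRuns = as.integer(vals[["n_runs"]]),
      target = vals[["target"]],
      baseSeed = as.integer(vals[["base_seed"]]))
}

#' Write / read the final regulator report
#'
#' `writeReport` writes the prioritized table as TSV and, when
#' `jsonPath` is given, a structured JSON document carrying the
#' thresholds and the per-regulator records. `readReport` restores a
#' [RegulatorReport-class] from the JSON form.
#'
#' @param x a [RegulatorReport-class].
#' @param path TSV output path.
#' @param jsonPath optional JSON output path.
#' @return A `RegulatorReport` (reader); `path` invisibly (writer).
#' @export
writeReport <- function(x, path, jsonPath = NULL) {
  stopifnot(is(x, "RegulatorReport"))
  tb <- x@table
  out <- tb
  out$frequency_stress <- fmtNum(out$frequency_stress)
  out$frequency_control <- fmtNum(out$frequency_control)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(jsonPath)) {
    doc <- list(thresholds = as.list(x@thresholds), regulators = tb)
    jsonlite::write_json(doc, jsonPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(jsonPath) {
  doc <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  tb <- as.data.frame(doc$regulators, stringsAsFactors = FALSE)
  if (!nrow(tb))
    tb <- data.frame(regulator = character(0), class = character(0),
                     frequency_stress = numeric(0),
                     frequency_control = numeric(0),
                     binding_evidence = logical(0),
                     final_priority = integer(0))
  tb$final_priority <- as.integer(tb$final_priority)
  new("RegulatorReport", table = tb,
      thresholds = c(stress = doc$thresholds$stress,
                     control = doc$thresholds$control))
}
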