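#' @importFrom utils write.csv read.csv
NULL

#' Write / read a counts matrix as TSV
#'
#' Genes in rows (first column `gene`), samples in the header row.
#'
#' @param counts a count `SummarizedExperiment` (see [countExperiment()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCountsTSV <- function(counts, path) {
  m <- SummarizedExperiment::assay(counts, "counts")
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCountsTSV
#' @param metaPath sample-metadata TSV as written by [writeSampleTableTSV()].
#' @export
readCountsTSV <- function(path, metaPath) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  meta <- read.table(metaPath, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  rownames(meta) <- meta$sample
  countExperiment(m, meta[colnames(m), c("trait", "batch", "sex"),
                          drop = FALSE])
}

#' Write the sample table (sample, trait, batch, sex) as TSV
#'
#' @param counts a count `SummarizedExperiment`.
#' @param path output file.
#' @export
writeSampleTableTSV <- function(counts, path) {
  cd <- as.data.frame(SummarizedExperiment::colData(counts))
  df <- data.frame(sample = colnames(counts), cd, row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an interaction graph as a STRING-dialect edge list TSV
#'
#' @param graph an [igraph::igraph] with per-channel edge attributes and
#'   `combined_score`.
#' @param path output file.
#' @export
writeEdgeListTSV <- function(graph, path) {
  el <- igraph::as_data_frame(graph, what = "edges")
  colnames(el)[1:2] <- c("protein1", "protein2")
  write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write GMT gene-set collections
#'
#' GMT lines are `set_id <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#'
#' @param path file path.
#' @return `readGMT` returns a named list of character vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  if (anyDuplicated(names(sets))) stop("duplicate set ids in GMT")
  sets
}

#' @rdname readGMT
#' @param sets named list of character vectors.
#' @export
writeGMT <- function(sets, path) {
  lines <- vapply(names(sets), function(id)
    paste(c(id, "na", sets[[id]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read startle trials as CSV (trial_type, amplitude)
#'
#' @param trials data.frame with `trial_type` and `amplitude`.
#' @param path file path.
#' @export
writeTrialsCSV <- function(trials, path) {
  write.csv(trials[, c("trial_type", "amplitude")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname writeTrialsCSV
#' @export
readTrialsCSV <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a ground-truth record as JSON
#'
#' @param truth a truth list as returned by the simulators.
#' @param path file path.
#' @export
writeTruthJSON <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
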