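# Plain-text interchange: expression TSV, gene lists, GMT term sets,
# edge lists, presence matrices and feature summaries.

#' Read a genes x samples expression matrix from TSV
#'
#' Rows are genes (first column = gene ID), remaining header columns are
#' sample IDs.
#' @param path TSV path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a genes x samples expression matrix as TSV
#' @param matrix numeric matrix with dimnames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_expression_tsv <- function(matrix, path) {
  df <- data.frame(gene = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a one-ID-per-line gene list
#' @param path file path.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Read term sets from a GMT file
#'
#' Tab-separated lines: term, description, member genes.
#' @param path GMT path.
#' @return named list of member vectors; attribute \code{"description"}
#'   maps term -> description.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "description") <-
    stats::setNames(vapply(parts, `[`, character(1), 2), names(sets))
  sets
}

#' Write term sets as a GMT file
#' @param sets named list of member vectors.
#' @param path output path.
#' @param descriptions optional named descriptions (defaults to the term
#'   names).
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(tm)
    paste(c(tm, descriptions[[tm]], sets[[tm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a network edge list as TSV
#'
#' Columns: regulator, target, weight, plus occurrence and confidence for
#' consensus networks.  A JSON sidecar (\code{<path>.json}) records the
#' engine (and consensus) configuration.
#'
#' @param network a \code{grn_network} or \code{consensus_grn}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- list(engine = unclass(network$config))
  if (!is.null(network$consensus)) cfg$consensus <- unclass(network$consensus)
  jsonlite::write_json(cfg, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read an edge list TSV back into a plain edge data.frame
#' @param path TSV path written by \code{\link{write_edge_list}}.
#' @return data.frame of edges.
#' @export
read_edge_list <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a presence/absence matrix as 0/1 TSV
#' @param matrix logical samples x genes matrix.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_presence_tsv <- function(matrix, path) {
  df <- data.frame(sample = rownames(matrix), matrix * 1L,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarise several genomes into one feature table
#'
#' Convenience wrapper: detects the inverted repeats, partitions each
#' genome and stacks the per-sample \code{\link{summarize_features}} rows
#' in the conventional column order.
#'
#' @param records list of \code{\link{genome_record}} objects.
#' @param min_ir_len minimal IR length passed to
#'   \code{\link{detect_inverted_repeats}}.
#' @return data.frame, one row per sample.
#' @export
feature_table <- function(records, min_ir_len = 100) {
  do.call(rbind, lapply(records, function(rec) {
    irs <- detect_inverted_repeats(rec$sequence, min_len = min_ir_len)
    part <- if (is.null(irs)) NULL else partition_regions(rec, irs)
    out <- summarize_features(rec, part)
    out$lsc_length <- if (is.null(part)) NA else interval_len(part$lsc)
    out$ssc_length <- if (is.null(part)) NA else interval_len(part$ssc)
    out$ir_length <- if (is.null(part)) NA else interval_len(part$ira)
    out
  }))
}
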