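#' Read and write pipeline matrices and tables
#'
#' Plain-text interchange: beta and intensity matrices as TSV with a
#' `probe_id` first column, sample sheets and annotation as CSV, planted
#' truth as JSON.
#'
#' @param x Matrix (probes x samples) with dimnames, or data.frame.
#' @param path File path.
#' @name methdev-io
NULL

#' @rdname methdev-io
#' @export
write_beta_tsv <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(probe_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname methdev-io
#' @export
read_beta_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname methdev-io
#' @export
write_sample_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname methdev-io
#' @export
read_sample_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname methdev-io
#' @export
write_truth_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname methdev-io
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
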