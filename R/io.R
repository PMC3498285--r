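#' Write a data frame as a diff-stable TSV
#'
#' All tables the pipeline writes share one format: tab-separated, header
#' row, no quoting, and floating-point columns rendered with a fixed number
#' of decimals so reruns of the same seed diff cleanly.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param digits Decimal places for numeric (double) columns.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, digits = 6L) {
  out <- as.data.frame(df)
  for (col in names(out)) {
    if (is.double(out[[col]]))
      out[[col]] <- formatC(out[[col]], format = "f", digits = digits)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path File path.
#' @return A data frame.
#' @export
read_tsv <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' Write / read an expression matrix as TSV
#'
#' Features as rows (first column `feature`), samples or conditions as the
#' remaining columns.
#'
#' @param mat Numeric matrix with rownames.
#' @param path File path.
#' @return `path` invisibly ([write_matrix_tsv()]); a numeric matrix
#'   ([read_matrix_tsv()]).
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(feature = rownames(mat), as.data.frame(mat),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}
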