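#' Construct a genotype call matrix
#'
#' The central container of the package: a markers x samples character
#' matrix of IUPAC genotype codes with `"N"` as the missing sentinel.
#' Homozygous calls are the four bases, heterozygous calls the six
#' two-base ambiguity letters. Row names are marker (probe) identifiers,
#' column names sample identifiers.
#'
#' @param calls character matrix (markers x samples) with row and column
#'   names set.
#' @return the validated matrix, invisibly classed as `call_matrix`.
#' @export
call_matrix <- function(calls) {
  if (!is.matrix(calls) || !is.character(calls)) {
    stop("calls must be a character matrix")
  }
  if ((nrow(calls) > 0L && is.null(rownames(calls))) ||
      (ncol(calls) > 0L && is.null(colnames(calls)))) {
    stop("calls must have marker row names and sample column names")
  }
  if (anyDuplicated(rownames(calls))) stop("marker ids must be unique")
  if (anyDuplicated(colnames(calls))) stop("sample ids must be unique")
  bad <- !(calls %in% CALL_ALPHABET)
  if (any(bad)) {
    stop("calls contain codes outside the IUPAC genotype alphabet: ",
         paste(unique(calls[bad]), collapse = ", "))
  }
  class(calls) <- c("call_matrix", class(calls))
  calls
}

as_call_matrix <- function(calls) {
  if (inherits(calls, "call_matrix")) calls else call_matrix(calls)
}

#' Write genotype calls to TSV
#'
#' Rows are markers, columns samples; the first column `probe_id` holds
#' the marker identifier. Missing calls are written as `N`.
#'
#' @param calls call matrix (see [call_matrix()]).
#' @param path output file.
#' @export
write_calls <- function(calls, path) {
  df <- data.frame(probe_id = rownames(calls), unclass(calls),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotype calls from TSV
#'
#' @param path file written by [write_calls()] (or any TSV with a
#'   `probe_id` first column and one column per sample).
#' @return a `call_matrix`.
#' @export
read_calls <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  call_matrix(m)
}
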