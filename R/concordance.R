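#' Concordance between two call sets for one accession
#'
#' Compares two genotype call vectors (e.g. in-silico calls from an
#' assembly versus array calls from DNA of the same accession) over the
#' markers they share. A marker counts as matching only when the IUPAC
#' codes are identical; by default, markers where either call is missing
#' are excluded from the denominator.
#'
#' @param calls1,calls2 named character vectors of IUPAC calls (names
#'   are marker ids), or single-column call matrices.
#' @param id1,id2 sample labels for the report.
#' @param partial_credit if TRUE, a pair sharing exactly one of two
#'   alleles (e.g. homozygous `A` vs heterozygous `M`) counts as half a
#'   match instead of a mismatch.
#' @param missing_in_denominator if TRUE, pairs with a missing call stay
#'   in the denominator (and never match).
#' @return list of class `concordance_report` with `sample_pair`,
#'   `n_shared_markers`, `n_compared`, `n_matching`, `percent`.
#' @export
concordance <- function(calls1, calls2, id1 = "calls1", id2 = "calls2",
                        partial_credit = FALSE,
                        missing_in_denominator = FALSE) {
  v1 <- if (is.matrix(calls1)) setNames(calls1[, 1L], rownames(calls1)) else calls1
  v2 <- if (is.matrix(calls2)) setNames(calls2[, 1L], rownames(calls2)) else calls2
  if (is.null(names(v1)) || is.null(names(v2))) {
    stop("call vectors must be named by marker id")
  }
  shared <- intersect(names(v1), names(v2))
  if (length(shared) == 0L) stop("no shared markers between call sets")
  x <- v1[shared]; y <- v2[shared]
  miss <- x == "N" | y == "N"
  if (missing_in_denominator) {
    n_compared <- length(shared)
  } else {
    n_compared <- sum(!miss)
  }
  xv <- x[!miss]; yv <- y[!miss]
  if (partial_credit) {
    px <- iupac_to_pairs(matrix(xv, ncol = 1L))
    py <- iupac_to_pairs(matrix(yv, ncol = 1L))
    n_matching <- sum(shared_allele_count(px$a1, px$a2, py$a1, py$a2)) / 2
  } else {
    n_matching <- sum(xv == yv)
  }
  percent <- if (n_compared > 0L) 100 * n_matching / n_compared else NA_real_
  structure(list(sample_pair = c(id1, id2),
                 n_shared_markers = length(shared),
                 n_compared = n_compared, n_matching = n_matching,
                 percent = percent),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance %s vs %s: %.1f%% (%g/%g matching; %d shared markers)\n",
              x$sample_pair[1], x$sample_pair[2], x$percent, x$n_matching,
              x$n_compared, x$n_shared_markers))
  invisible(x)
}
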