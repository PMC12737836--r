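#' Construct a probe table
#'
#' An Axiom-style probe set is a biallelic SNP written `[X/Y]` between
#' two fixed-length flanking arms (by default 35 bp each, i.e. a 71 bp
#' probe). Probes are held as a data frame with columns `probe_id`,
#' `left_flank`, `allele1`, `allele2`, `right_flank`.
#'
#' @param probe_id character vector of unique identifiers.
#' @param left_flank,right_flank flanking sequences over `ACGT`.
#' @param allele1,allele2 the two SNP alleles (single distinct bases).
#' @return data frame of class `probe_table`.
#' @export
probe_table <- function(probe_id, left_flank, allele1, allele2, right_flank) {
  df <- data.frame(probe_id = as.character(probe_id),
                   left_flank = toupper(left_flank),
                   allele1 = toupper(allele1), allele2 = toupper(allele2),
                   right_flank = toupper(right_flank),
                   stringsAsFactors = FALSE)
  if (any(df$allele1 == df$allele2)) stop("probe alleles must differ")
  if (!all(c(df$allele1, df$allele2) %in% DNA_BASES)) {
    stop("alleles must be single ACGT bases")
  }
  if (any(grepl("[^ACGT]", c(df$left_flank, df$right_flank)))) {
    stop("flanks must be over ACGT")
  }
  class(df) <- c("probe_table", class(df))
  df
}

#' Parse bracket-notation probe sequences
#'
#' Reads a two-column TSV (`probe_id<TAB>sequence`) where each sequence
#' is written `LEFT[X/Y]RIGHT`. Duplicated probe identifiers are removed
#' entirely (all copies), and probes whose flanks are shorter than
#' `flank_length` are dropped as non-full-length; the number removed by
#' each rule is recorded in the `"removed"` attribute.
#'
#' @param path TSV file path.
#' @param flank_length required length of each flanking arm (default 35).
#' @return a `probe_table`; attribute `removed` holds counts
#'   `c(duplicate = , non_full_length = )`.
#' @export
parse_probes <- function(path, flank_length = 35) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2) stop("probe TSV must have probe_id and sequence columns")
  ids <- df[[1]]
  seqs <- toupper(df[[2]])
  m <- regmatches(seqs, regexec("^([ACGT]*)\\[([ACGT])/([ACGT])\\]([ACGT]*)$", seqs))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop("malformed probe sequence(s), expected LEFT[X/Y]RIGHT over ACGT: ",
         paste(utils::head(ids[bad], 3), collapse = ", "))
  }
  left <- vapply(m, `[`, character(1), 2L)
  a1 <- vapply(m, `[`, character(1), 3L)
  a2 <- vapply(m, `[`, character(1), 4L)
  right <- vapply(m, `[`, character(1), 5L)

  dup <- ids %in% ids[duplicated(ids)]
  n_dup <- sum(dup)
  full <- nchar(left) == flank_length & nchar(right) == flank_length
  n_nfl <- sum(!full & !dup)
  keep <- !dup & full
  out <- probe_table(ids[keep], left[keep], a1[keep], a2[keep], right[keep])
  attr(out, "removed") <- c(duplicate = n_dup, non_full_length = n_nfl)
  out
}

#' Write probes in bracket notation
#'
#' @param probes a `probe_table`.
#' @param path output TSV.
#' @export
write_probes <- function(probes, path) {
  seqs <- paste0(probes$left_flank, "[", probes$allele1, "/", probes$allele2,
                 "]", probes$right_flank)
  write.table(data.frame(probe_id = probes$probe_id, sequence = seqs),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Expand a probe into its two allele sequences
#'
#' @param probe one row of a `probe_table` (or a list with the same fields).
#' @return character vector of the two full-length allele sequences,
#'   `left_flank + allele + right_flank`.
#' @export
expand_alleles <- function(probe) {
  c(paste0(probe$left_flank, probe$allele1, probe$right_flank),
    paste0(probe$left_flank, probe$allele2, probe$right_flank))
}
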