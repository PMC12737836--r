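#' @importFrom stats cmdscale cophenetic dist rbinom runif setNames
#' @importFrom utils read.table write.table modifyList
NULL

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC genotype code -> unordered allele pair (heterozygous codes only for
# the six two-base ambiguity letters; "N" is the missing sentinel)
IUPAC_PAIRS <- list(
  A = c("A", "A"), C = c("C", "C"), G = c("G", "G"), T = c("T", "T"),
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C")
)

CALL_ALPHABET <- c(names(IUPAC_PAIRS), "N")

#' Reverse-complement a DNA string
#'
#' Plain-character convenience wrapper used throughout; IUPAC ambiguity
#' codes are complemented too.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(x) chartr("ACGTRYSWKMN", "TGCAYRSWMKN", x)

# split IUPAC calls into two allele-character matrices (NA where missing);
# alleles are returned sorted within the pair
iupac_to_pairs <- function(calls) {
  codes <- names(IUPAC_PAIRS)
  a1 <- vapply(IUPAC_PAIRS, `[`, character(1), 1L)
  a2 <- vapply(IUPAC_PAIRS, `[`, character(1), 2L)
  i <- match(calls, codes)
  bad <- is.na(i) & !(calls %in% "N") & !is.na(calls)
  if (any(bad)) {
    stop("invalid genotype code(s): ", paste(unique(calls[bad]), collapse = ", "))
  }
  list(a1 = structure(a1[i], dim = dim(calls), dimnames = dimnames(calls)),
       a2 = structure(a2[i], dim = dim(calls), dimnames = dimnames(calls)))
}

# shared-allele count between two sorted allele pairs: maximum matching on
# two-element multisets
shared_allele_count <- function(x1, x2, y1, y2) {
  pmax((x1 == y1) + (x2 == y2), (x1 == y2) + (x2 == y1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  as.integer(seed)
}
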