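#' Marker filtering configuration
#'
#' Defaults follow common array-panel curation practice: markers with
#' minor allele frequency strictly below 0.05 are removed, and markers
#' (or samples) with more than 3% missing data are removed.
#'
#' @param maf_threshold minor allele frequency below which (strict `<`)
#'   a marker is dropped.
#' @param max_missing_fraction maximum tolerated missing fraction;
#'   entries above it are dropped.
#' @param missing_axis apply the missingness filter to `"marker"` rows
#'   (default) or `"sample"` columns.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(maf_threshold = 0.05, max_missing_fraction = 0.03,
                          missing_axis = c("marker", "sample")) {
  missing_axis <- match.arg(missing_axis)
  stopifnot(maf_threshold >= 0, maf_threshold <= 1,
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  structure(list(maf_threshold = maf_threshold,
                 max_missing_fraction = max_missing_fraction,
                 missing_axis = missing_axis),
            class = "filter_config")
}

#' Build a sample's SNP pseudosequence
#'
#' Concatenates one sample's calls over the marker list in matrix order;
#' missing calls appear as `N`. Because all samples share one ordered
#' marker list, pseudosequences are positionally comparable without any
#' realignment.
#'
#' @param matrix a `call_matrix`.
#' @param sample sample id (column) to extract.
#' @return a single string of length `nrow(matrix)`.
#' @export
build_pseudosequence <- function(matrix, sample) {
  if (!sample %in% colnames(matrix)) stop("unknown sample: ", sample)
  paste(matrix[, sample], collapse = "")
}

#' Pseudosequences for all samples
#'
#' @param matrix a `call_matrix`.
#' @return named character vector, one pseudosequence per sample.
#' @export
pseudosequences <- function(matrix) {
  setNames(vapply(colnames(matrix), function(s)
    build_pseudosequence(matrix, s), character(1)), colnames(matrix))
}

#' Write pseudosequences as FASTA
#'
#' @param pseudo named character vector from [pseudosequences()].
#' @param path output FASTA file.
#' @export
write_pseudo_fasta <- function(pseudo, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(pseudo), path)
  invisible(path)
}

#' Merge a reference panel with additional call sets
#'
#' Restricts to the markers present in both matrices (order taken from
#' the panel) and appends the additional samples (e.g. dissected
#' subgenome columns of a tetraploid) to the panel samples.
#'
#' @param panel,additions call matrices with disjoint sample ids.
#' @return merged `call_matrix`.
#' @export
merge_panels <- function(panel, additions) {
  dup <- intersect(colnames(panel), colnames(additions))
  if (length(dup)) stop("duplicate sample id(s): ", paste(dup, collapse = ", "))
  shared <- intersect(rownames(panel), rownames(additions))
  if (length(shared) == 0L) stop("no shared markers between panels")
  shared <- rownames(panel)[rownames(panel) %in% shared]
  call_matrix(cbind(unclass(panel)[shared, , drop = FALSE],
                    unclass(additions)[shared, , drop = FALSE]))
}

# distinct non-missing calls per marker
.n_distinct_calls <- function(m) {
  apply(unclass(m), 1L, function(r) length(unique(r[r != "N"])))
}

# per-marker allele counts from IUPAC calls: a homozygote contributes two
# copies of one base, a heterozygote one copy of each, missing none.
# Returns a list with per-marker named count tables.
.allele_counts <- function(m) {
  p <- iupac_to_pairs(unclass(m))
  lapply(seq_len(nrow(m)), function(i) {
    a <- c(p$a1[i, ], p$a2[i, ])
    table(a[!is.na(a)])
  })
}

#' Drop monomorphic markers
#'
#' Removes markers with fewer than two distinct non-missing calls.
#' Distinctness is at the IUPAC-code level, so a heterozygous call
#' against a homozygous one counts as polymorphism.
#'
#' @param matrix a `call_matrix`.
#' @return list with the filtered `matrix` and a `report` entry
#'   (`n_input`, `n_kept`, `dropped` ids).
#' @export
filter_polymorphic <- function(matrix) {
  keep <- .n_distinct_calls(matrix) >= 2L
  list(matrix = call_matrix(unclass(matrix)[keep, , drop = FALSE]),
       report = list(step = "polymorphic", n_input = nrow(matrix),
                     n_kept = sum(keep), dropped = rownames(matrix)[!keep]))
}

#' Drop markers by minor allele frequency
#'
#' Allele copies are counted from the IUPAC codes (homozygote = 2,
#' heterozygote = 1 + 1, missing skipped). Markers whose minor allele
#' frequency is strictly below the threshold are dropped; markers at
#' which more than two alleles are observed are dropped with a distinct
#' reason code.
#'
#' @param matrix a `call_matrix`.
#' @param cfg a [filter_config()].
#' @return list with filtered `matrix` and `report` (also records
#'   `dropped_multiallelic`).
#' @export
filter_maf <- function(matrix, cfg = filter_config()) {
  counts <- .allele_counts(matrix)
  n_alleles <- vapply(counts, length, integer(1))
  maf <- vapply(counts, function(tb) {
    tot <- sum(tb)
    if (tot == 0L || length(tb) < 2L) 0 else min(tb) / tot
  }, numeric(1))
  multi <- n_alleles > 2L
  low <- !multi & maf < cfg$maf_threshold
  keep <- !multi & !low
  list(matrix = call_matrix(unclass(matrix)[keep, , drop = FALSE]),
       report = list(step = "maf", n_input = nrow(matrix), n_kept = sum(keep),
                     dropped = rownames(matrix)[low],
                     dropped_multiallelic = rownames(matrix)[multi]))
}

#' Drop markers (or samples) by missing-data fraction
#'
#' With `missing_axis = "marker"` (default) markers whose fraction of
#' missing calls across samples exceeds the threshold are dropped; with
#' `"sample"` the same rule is applied to sample columns.
#'
#' @param matrix a `call_matrix`.
#' @param cfg a [filter_config()].
#' @return list with filtered `matrix` and `report`.
#' @export
filter_missing <- function(matrix, cfg = filter_config()) {
  m <- unclass(matrix)
  if (cfg$missing_axis == "marker") {
    frac <- rowMeans(m == "N")
    keep <- frac <= cfg$max_missing_fraction
    out <- call_matrix(m[keep, , drop = FALSE])
    dropped <- rownames(m)[!keep]
  } else {
    frac <- colMeans(m == "N")
    keep <- frac <= cfg$max_missing_fraction
    out <- call_matrix(m[, keep, drop = FALSE])
    dropped <- colnames(m)[!keep]
  }
  list(matrix = out,
       report = list(step = "missing", axis = cfg$missing_axis,
                     n_input = if (cfg$missing_axis == "marker") nrow(m) else ncol(m),
                     n_kept = sum(keep), dropped = dropped))
}

#' Three-step marker filtering pipeline
#'
#' Applies, in order: removal of monomorphic markers, removal of markers
#' with minor allele frequency below threshold, removal of markers (or
#' samples) exceeding the missing-data bound. The report records the
#' marker count after each step.
#'
#' @param matrix a `call_matrix`.
#' @param cfg a [filter_config()].
#' @return list with the final `matrix` and a `report` of class
#'   `filter_report` (`n_input`, `n_after_polymorphic`, `n_after_maf`,
#'   `n_after_missing`, per-step dropped ids).
#' @export
run_filter_pipeline <- function(matrix, cfg = filter_config()) {
  s1 <- filter_polymorphic(matrix)
  s2 <- filter_maf(s1$matrix, cfg)
  s3 <- filter_missing(s2$matrix, cfg)
  report <- structure(list(
    n_input = nrow(matrix),
    n_after_polymorphic = s1$report$n_kept,
    n_after_maf = s2$report$n_kept,
    n_after_missing = nrow(s3$matrix),
    dropped = list(polymorphic = s1$report$dropped,
                   maf = s2$report$dropped,
                   maf_multiallelic = s2$report$dropped_multiallelic,
                   missing = s3$report$dropped)),
    class = "filter_report")
  list(matrix = s3$matrix, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("markers: %d -> %d (polymorphic) -> %d (MAF) -> %d (missing)\n",
              x$n_input, x$n_after_polymorphic, x$n_after_maf,
              x$n_after_missing))
  invisible(x)
}
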