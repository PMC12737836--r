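#' Write a simulation truth bundle to disk
#'
#' Produces `true_tree.nwk` (Newick), `true_variants.vcf` (VCF v4.2,
#' 1-based, haploid genotype columns for the two chosen lineages),
#' `genic.bed` (BED3, 0-based half-open), `parents.tsv` and
#' `probe_truth.tsv`.
#'
#' @param truth the `truth` element of [simulate_panel()] output.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_truth <- function(truth, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  writeLines(truth$true_tree, file.path(outdir, "true_tree.nwk"))
  write_vcf(truth$true_variants, file.path(outdir, "true_variants.vcf"),
            chrom_lengths = truth$chrom_lengths)
  write_bed(truth$genic_bed, file.path(outdir, "genic.bed"))
  write.table(
    data.frame(key = c("parent_A_id", "parent_B_id", "lineage_close",
                       "lineage_far"),
               value = c(truth$parent_A_id, truth$parent_B_id,
                         truth$lineage_close, truth$lineage_far)),
    file.path(outdir, "parents.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write.table(truth$probe_truth, file.path(outdir, "probe_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(chrom = names(truth$chrom_lengths),
                         length = as.integer(truth$chrom_lengths)),
              file.path(outdir, "chrom_lengths.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' Read a truth bundle written by [write_truth()]
#'
#' @param outdir directory containing the truth files.
#' @return list with the same fields as the `truth` element of
#'   [simulate_panel()].
#' @export
read_truth <- function(outdir) {
  parents <- read.table(file.path(outdir, "parents.tsv"), sep = "\t",
                        header = TRUE, colClasses = "character")
  kv <- setNames(parents$value, parents$key)
  lens <- read.table(file.path(outdir, "chrom_lengths.tsv"), sep = "\t",
                     header = TRUE,
                     colClasses = c("character", "integer"))
  list(parent_A_id = unname(kv[["parent_A_id"]]),
       parent_B_id = unname(kv[["parent_B_id"]]),
       lineage_close = unname(kv[["lineage_close"]]),
       lineage_far = unname(kv[["lineage_far"]]),
       true_tree = readLines(file.path(outdir, "true_tree.nwk")),
       true_variants = read_vcf(file.path(outdir, "true_variants.vcf")),
       genic_bed = read.table(file.path(outdir, "genic.bed"), sep = "\t",
                              col.names = c("chrom", "start", "end"),
                              colClasses = c("character", "integer",
                                             "integer")),
       chrom_lengths = setNames(lens$length, lens$chrom),
       probe_truth = read.table(file.path(outdir, "probe_truth.tsv"),
                                sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE))
}
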