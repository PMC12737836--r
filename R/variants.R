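#' Construct a variant table
#'
#' Reference-coordinate variants with per-lineage genotypes: a data
#' frame with columns `chrom`, `pos` (1-based), `ref`, `alt`
#' (comma-joined alternate alleles) and one integer genotype column per
#' lineage (0 = reference, k >= 1 = k-th alternate, NA = missing /
#' not called).
#'
#' @param df data frame with the columns above.
#' @param lineages character vector naming the genotype columns.
#' @return data frame of class `variant_table` with attribute
#'   `lineages`.
#' @export
variant_table <- function(df, lineages) {
  need <- c("chrom", "pos", "ref", "alt", lineages)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("variant table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$pos < 1L)) stop("positions must be >= 1")
  if (any(!nzchar(df$ref))) stop("ref alleles must be non-empty")
  n_alt <- vapply(strsplit(df$alt, ",", fixed = TRUE), length, integer(1))
  for (l in lineages) {
    gt <- df[[l]]
    if (any(gt[!is.na(gt)] > n_alt[!is.na(gt)])) {
      stop("genotype index exceeds alternate allele count for lineage ", l)
    }
  }
  attr(df, "lineages") <- lineages
  class(df) <- unique(c("variant_table", class(df)))
  df
}

#' Lineages of a variant table
#' @param variants a `variant_table`.
#' @return character vector of lineage (genotype column) names.
#' @export
variant_lineages <- function(variants) attr(variants, "lineages")

#' Read a multi-lineage VCF
#'
#' Parses a VCF (v4.x) whose genotype columns are haploid or
#' homozygous-diploid calls, as produced by graph-based multi-genome
#' alignment, into a [variant_table()]. Multiallelic records are kept as
#' is; `.` genotypes become missing.
#'
#' @param path VCF file.
#' @return a `variant_table` with one genotype column per VCF sample.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  lineages <- colnames(v@gt)[-1L]
  if (nrow(fix) == 0L) {
    df <- data.frame(chrom = character(), pos = integer(), ref = character(),
                     alt = character(), stringsAsFactors = FALSE)
    for (l in lineages) df[[l]] <- integer()
    return(variant_table(df, lineages))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  df <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                   ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  df$alt[is.na(df$alt)] <- ""
  for (l in lineages) {
    g <- gt[, l]
    # haploid "1", diploid "1/1" or "1|1"; heterozygous calls are not
    # expected from assemblies and are rejected
    first <- sub("[/|].*$", "", g)
    rest <- ifelse(grepl("[/|]", g), sub("^[^/|]*[/|]", "", g), first)
    if (any(!is.na(g) & first != rest)) {
      stop("heterozygous genotype in lineage ", l)
    }
    df[[l]] <- suppressWarnings(as.integer(ifelse(first == ".", NA, first)))
  }
  variant_table(df, lineages)
}

#' Write a variant table as VCF v4.2
#'
#' Genotypes are written haploid (`0`, `1`, ... or `.`).
#'
#' @param variants a `variant_table`.
#' @param path output file.
#' @param chrom_lengths optional named vector used to emit `##contig`
#'   header lines.
#' @export
write_vcf <- function(variants, path, chrom_lengths = NULL) {
  lineages <- variant_lineages(variants)
  header <- c("##fileformat=VCFv4.2",
              if (!is.null(chrom_lengths)) {
                sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
                        as.integer(chrom_lengths))
              },
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", lineages), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(variants) > 0L) {
    gts <- sapply(lineages, function(l) {
      g <- variants[[l]]
      ifelse(is.na(g), ".", as.character(g))
    })
    if (is.null(dim(gts))) gts <- matrix(gts, nrow = nrow(variants))
    body <- cbind(variants$chrom, variants$pos, ".", variants$ref,
                  variants$alt, ".", "PASS", ".", "GT", gts)
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Classify lineage-specific variants
#'
#' A variant is specific to the focal lineage when the focal genotype is
#' explicitly called as any alternate allele and the other lineage is
#' explicitly called as the reference allele; a missing call in either
#' lineage excludes the variant.
#'
#' @param variants a `variant_table`.
#' @param focal,other lineage names.
#' @return the focal-specific subset, still a `variant_table`.
#' @export
classify_lineage_specific <- function(variants, focal, other) {
  lineages <- variant_lineages(variants)
  miss <- setdiff(c(focal, other), lineages)
  if (length(miss)) stop("unknown lineage(s): ", paste(miss, collapse = ", "))
  gf <- variants[[focal]]
  go <- variants[[other]]
  keep <- !is.na(gf) & !is.na(go) & gf >= 1L & go == 0L
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  variant_table(out, lineages)
}

.as_bed_df <- function(bed) {
  if (is.character(bed) && length(bed) == 1L) {
    bed <- read.table(bed, sep = "\t", header = FALSE,
                      col.names = c("chrom", "start", "end"),
                      colClasses = c("character", "integer", "integer"))
  }
  if (inherits(bed, "GRanges")) {
    bed <- data.frame(chrom = as.character(GenomicRanges::seqnames(bed)),
                      start = GenomicRanges::start(bed) - 1L,
                      end = GenomicRanges::end(bed), stringsAsFactors = FALSE)
  }
  if (!all(c("chrom", "start", "end") %in% names(bed))) {
    stop("bed must have chrom, start, end columns")
  }
  if (any(bed$start >= bed$end)) stop("bed interval with start >= end")
  bed
}

#' Restrict variants to BED regions
#'
#' A variant belongs to a region when its start position (`pos - 1` in
#' 0-based coordinates) falls inside a half-open `[start, end)`
#' interval on the same chromosome; multi-bp variants are assigned by
#' their start position.
#'
#' @param variants a `variant_table`.
#' @param bed BED3 file path, data frame with `chrom`/`start`/`end`
#'   (0-based half-open), or a `GRanges`.
#' @return the restricted subset.
#' @export
restrict_to_regions <- function(variants, bed) {
  bed <- .as_bed_df(bed)
  if (nrow(bed) == 0L || nrow(variants) == 0L) {
    out <- variants[integer(), , drop = FALSE]
    return(variant_table(out, variant_lineages(variants)))
  }
  gr_bed <- GenomicRanges::GRanges(bed$chrom,
                                   IRanges::IRanges(bed$start + 1L, bed$end))
  gr_var <- GenomicRanges::GRanges(variants$chrom,
                                   IRanges::IRanges(variants$pos, width = 1L))
  keep <- IRanges::overlapsAny(gr_var, gr_bed)
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  variant_table(out, variant_lineages(variants))
}

#' Count variants in fixed genomic windows
#'
#' Windows tile each chromosome from coordinate 0 in half-open steps of
#' `window_size` (the last window is truncated at the chromosome
#' length); a variant falls in the window containing `pos - 1`. Every
#' window is emitted, including zero counts.
#'
#' @param variants a `variant_table` (or any data frame with `chrom`
#'   and `pos`).
#' @param chrom_lengths named vector of chromosome lengths covering all
#'   variant chromosomes.
#' @param window_size window width in bp (e.g. 2e6, or 1e5 for
#'   fine-grained counts).
#' @return data frame `chrom, start, end, count` (0-based half-open).
#' @export
window_counts <- function(variants, chrom_lengths, window_size = 2e6) {
  if (window_size < 1) stop("window_size must be >= 1")
  bad <- setdiff(unique(variants$chrom), names(chrom_lengths))
  if (length(bad)) stop("chromosome(s) without declared length: ",
                        paste(bad, collapse = ", "))
  out <- lapply(names(chrom_lengths), function(cn) {
    len <- chrom_lengths[[cn]]
    starts <- seq(0L, max(0L, len - 1L), by = window_size)
    v <- variants[variants$chrom == cn, , drop = FALSE]
    if (any(v$pos > len)) stop("variant beyond declared length of ", cn)
    win <- (v$pos - 1L) %/% window_size
    cnt <- tabulate(win + 1L, nbins = length(starts))
    data.frame(chrom = cn, start = starts,
               end = pmin(starts + window_size, len), count = cnt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Aggregate fine window counts into coarser windows
#'
#' Sums constituent fine-window counts; the coarse width must be a
#' multiple of the fine width. Equivalent to direct counting at the
#' coarse width.
#'
#' @param fine_counts output of [window_counts()].
#' @param coarse_size target window width (multiple of the fine width).
#' @return data frame `chrom, start, end, count`.
#' @export
aggregate_windows <- function(fine_counts, coarse_size) {
  fine_size <- max(fine_counts$end - fine_counts$start)
  if (coarse_size %% fine_size != 0) {
    stop("coarse window size must be a multiple of the fine size")
  }
  key <- paste(fine_counts$chrom, fine_counts$start %/% coarse_size)
  agg <- lapply(split(fine_counts, factor(key, levels = unique(key))),
                function(g) {
    data.frame(chrom = g$chrom[1L], start = (g$start[1L] %/% coarse_size) *
                 coarse_size, end = max(g$end), count = sum(g$count),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Largest reference span among variants
#'
#' @param variants a `variant_table`.
#' @return maximum `nchar(ref)` in bp; 0 with a warning for an empty
#'   set.
#' @export
max_variant_span <- function(variants) {
  if (nrow(variants) == 0L) {
    warning("empty variant set")
    return(0L)
  }
  max(nchar(variants$ref))
}

#' Write BED3 intervals
#'
#' @param bed data frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param path output file.
#' @export
write_bed <- function(bed, path) {
  write.table(bed[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
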