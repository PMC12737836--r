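#' Alignment/calling configuration for in-silico genotyping
#'
#' Controls the mismatch-bounded ungapped placement search. The default
#' tolerates at most one mismatch in each flanking arm (`per_arm` mode);
#' `total` mode instead bounds the summed mismatch count across both
#' arms. The SNP base itself must always match one of the two probe
#' alleles exactly, and indels are excluded by construction (the model
#' is ungapped).
#'
#' @param max_flank_mismatch maximum mismatches tolerated per flanking
#'   arm (`per_arm` mode) or in both arms together (`total` mode).
#' @param mismatch_mode `"per_arm"` (default) or `"total"`.
#' @param require_unique call only when exactly one placement survives
#'   filtering (default TRUE).
#' @return a list of class `align_config`.
#' @export
align_config <- function(max_flank_mismatch = 1,
                         mismatch_mode = c("per_arm", "total"),
                         require_unique = TRUE) {
  mismatch_mode <- match.arg(mismatch_mode)
  if (max_flank_mismatch < 0) stop("max_flank_mismatch must be >= 0")
  structure(list(max_flank_mismatch = as.integer(max_flank_mismatch),
                 mismatch_mode = mismatch_mode,
                 require_unique = isTRUE(require_unique)),
            class = "align_config")
}

# total mismatch budget across both arms implied by the configuration
.mm_budget <- function(cfg) {
  if (cfg$mismatch_mode == "per_arm") 2L * cfg$max_flank_mismatch
  else cfg$max_flank_mismatch
}

as_genome_chars <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    setNames(as.character(genome), names(genome))
  } else if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome chromosomes must be named")
    toupper(genome)
  } else {
    stop("genome must be a named character vector or DNAStringSet")
  }
}

empty_hits <- function() {
  data.frame(probe_id = character(), target = character(),
             chrom = character(), pos = integer(), strand = character(),
             called_allele = character(), left_mm = integer(),
             right_mm = integer(), stringsAsFactors = FALSE)
}

# verify candidate placements (probe index, chrom start, strand) against
# the genome and return surviving hits
.verify_candidates <- function(cand, probes, chrom_str, chrom_name, target,
                               flank_len, cfg) {
  if (nrow(cand) == 0L) return(empty_hits())
  f <- flank_len
  plen <- 2L * f + 1L
  segs <- substring(chrom_str, cand$start, cand$start + plen - 1L)
  A <- matrix(unlist(strsplit(segs, "", fixed = TRUE), use.names = FALSE),
              nrow = nrow(cand), byrow = TRUE)
  pats <- ifelse(cand$strand == "+",
                 probes$.pat_fwd[cand$probe], probes$.pat_rc[cand$probe])
  B <- matrix(unlist(strsplit(pats, "", fixed = TRUE), use.names = FALSE),
              nrow = nrow(cand), byrow = TRUE)
  neq <- A != B
  mm_first <- rowSums(neq[, seq_len(f), drop = FALSE])
  mm_last <- rowSums(neq[, (f + 2L):plen, drop = FALSE])
  center <- A[, f + 1L]
  fwd <- cand$strand == "+"
  # in probe orientation: on the minus strand the first segment arm is the
  # probe's right arm and the SNP base is the complement of the genome base
  left_mm <- ifelse(fwd, mm_first, mm_last)
  right_mm <- ifelse(fwd, mm_last, mm_first)
  called <- ifelse(fwd, center, complement_base(center))
  a1 <- probes$allele1[cand$probe]
  a2 <- probes$allele2[cand$probe]
  allele_ok <- called == a1 | called == a2
  mm_ok <- if (cfg$mismatch_mode == "per_arm") {
    left_mm <= cfg$max_flank_mismatch & right_mm <= cfg$max_flank_mismatch
  } else {
    left_mm + right_mm <= cfg$max_flank_mismatch
  }
  keep <- allele_ok & mm_ok
  if (!any(keep)) return(empty_hits())
  data.frame(probe_id = probes$probe_id[cand$probe[keep]],
             target = target, chrom = chrom_name,
             pos = cand$start[keep] + f,
             strand = cand$strand[keep],
             called_allele = called[keep],
             left_mm = as.integer(left_mm[keep]),
             right_mm = as.integer(right_mm[keep]),
             stringsAsFactors = FALSE)
}

# placement search over one set of chromosomes for a whole probe table.
# Candidates come from exact seeding: each flanking arm is split into two
# disjoint half-arm seeds, so any placement within the mismatch budget
# (<= 3 total) leaves at least one seed exact (pigeonhole); candidates are
# then fully verified, which makes the search equivalent to an exhaustive
# scan of every offset and strand. Falls back to a direct
# mismatch-tolerant scan when the budget or flank geometry rules seeding
# out.
.search_placements <- function(probes, chroms, cfg, target) {
  stopifnot(is.data.frame(probes), nrow(probes) > 0L)
  f <- unique(nchar(probes$left_flank))
  if (length(f) != 1L || !all(nchar(probes$right_flank) == f)) {
    stop("all probes in one search must share the flank length")
  }
  plen <- 2L * f + 1L
  probes$.pat_fwd <- paste0(probes$left_flank, "N", probes$right_flank)
  probes$.pat_rc <- revcomp(probes$.pat_fwd)
  budget <- .mm_budget(cfg)
  h <- f %/% 2L
  use_seeds <- budget <= 3L && h >= 8L
  hits <- list()
  for (chrom_name in names(chroms)) {
    chrom_str <- chroms[[chrom_name]]
    clen <- nchar(chrom_str)
    if (clen < plen) next
    subject <- Biostrings::DNAString(chrom_str)
    if (use_seeds) {
      offs <- c(1L, f - h + 1L, f + 2L, 2L * f + 2L - h)
      seed_of <- function(p) substring(p, rep(offs, each = nrow(probes)),
                                       rep(offs + h - 1L, each = nrow(probes)))
      seeds <- c(seed_of(probes$.pat_fwd), seed_of(probes$.pat_rc))
      n <- nrow(probes)
      seed_probe <- rep(seq_len(n), times = 8L)
      seed_off <- rep(rep(offs, each = n), times = 2L)
      seed_strand <- rep(c("+", "-"), each = 4L * n)
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
      m <- Biostrings::matchPDict(pd, subject)
      cnt <- IRanges::elementNROWS(m)
      if (sum(cnt) == 0L) next
      idx <- rep(seq_along(cnt), cnt)
      p <- IRanges::start(unlist(m))
      start <- p - seed_off[idx] + 1L
      cand <- data.frame(probe = seed_probe[idx], start = start,
                         strand = seed_strand[idx], stringsAsFactors = FALSE)
      cand <- cand[cand$start >= 1L & cand$start + plen - 1L <= clen, , drop = FALSE]
      cand <- unique(cand)
    } else {
      cand_list <- vector("list", 2L * nrow(probes))
      k <- 0L
      for (i in seq_len(nrow(probes))) {
        for (strand in c("+", "-")) {
          pat <- if (strand == "+") probes$.pat_fwd[i] else probes$.pat_rc[i]
          m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                        max.mismatch = budget,
                                        fixed = "subject")
          k <- k + 1L
          if (length(m)) {
            cand_list[[k]] <- data.frame(probe = i, start = IRanges::start(m),
                                         strand = strand,
                                         stringsAsFactors = FALSE)
          }
        }
      }
      cand <- do.call(rbind, cand_list[!vapply(cand_list, is.null, logical(1))])
      if (is.null(cand) || nrow(cand) == 0L) next
      cand <- unique(cand)
    }
    hits[[chrom_name]] <- .verify_candidates(cand, probes, chrom_str,
                                             chrom_name, target, f, cfg)
  }
  if (length(hits) == 0L) return(empty_hits())
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out[order(match(out$probe_id, probes$probe_id), out$chrom, out$pos,
            out$strand), , drop = FALSE]
}

#' Find all filtered placements of one probe on a genome
#'
#' Returns every full-length ungapped placement of either allele
#' sequence, on both strands, at which the SNP base equals one allele
#' exactly and the flanking-arm mismatch counts satisfy the configured
#' bound. For minus-strand hits `pos` is the forward-strand coordinate
#' of the SNP base and `called_allele` is reported in probe orientation.
#' The result is identical to an exhaustive scan of every offset and
#' strand.
#'
#' @param probe one-row `probe_table` (or single row thereof).
#' @param genome named character vector of chromosome sequences, or a
#'   `DNAStringSet`.
#' @param cfg an [align_config()].
#' @return data frame of hits with columns `probe_id, target, chrom,
#'   pos, strand, called_allele, left_mm, right_mm`.
#' @export
find_placements <- function(probe, genome, cfg = align_config()) {
  chroms <- as_genome_chars(genome)
  probe <- as.data.frame(probe, stringsAsFactors = FALSE)
  rownames(probe) <- NULL
  .search_placements(probe, as.list(chroms), cfg, target = "genome")
}

#' Resolve placements into a single call
#'
#' A probe is called only when exactly one placement survived filtering;
#' zero placements give a `NO_CALL` of reason `absent`, two or more a
#' `NO_CALL` of reason `ambiguous`.
#'
#' @param hits data frame from [find_placements()].
#' @param cfg an [align_config()].
#' @return list with `status` (`"called"`, `"absent"` or `"ambiguous"`)
#'   and, when called, `hit` (the single surviving row).
#' @export
call_probe <- function(hits, cfg = align_config()) {
  n <- if (is.null(hits)) 0L else nrow(hits)
  if (n == 0L) return(list(status = "absent", hit = NULL))
  if (n == 1L) return(list(status = "called", hit = hits[1L, , drop = FALSE]))
  if (!cfg$require_unique) {
    if (length(unique(hits$called_allele)) == 1L) {
      return(list(status = "called", hit = hits[1L, , drop = FALSE]))
    }
  }
  list(status = "ambiguous", hit = NULL)
}

#' Default chromosome-to-subgenome partition
#'
#' Chromosome names starting with `A` or `B` followed by a digit map to
#' subgenome `A` or `B`; all other chromosomes map to the empty label
#' (undissected, as for diploid assemblies).
#'
#' @param genome genome container (names are used).
#' @return named character vector chrom -> label.
#' @export
default_partition <- function(genome) {
  chroms <- names(as_genome_chars(genome))
  lab <- ifelse(grepl("^A[0-9]", chroms), "A",
                ifelse(grepl("^B[0-9]", chroms), "B", ""))
  setNames(lab, chroms)
}

#' Genotype a genome assembly in silico
#'
#' Places every probe on the assembly and emits one call column per
#' subgenome label in the partition. The search space (and the
#' uniqueness requirement) is restricted to each label's chromosomes
#' separately, so homoeologous copies in an allotetraploid do not veto
#' markers. Assemblies are haploid, so calls are homozygous bases; zero
#' or ambiguous placements give the missing sentinel `N`.
#'
#' @param probes a `probe_table`.
#' @param genome named character vector of chromosomes or `DNAStringSet`.
#' @param sample_id sample name used to build column names
#'   (`<sample>_<label>`, or `<sample>` for the empty label).
#' @param partition named character vector chrom -> subgenome label;
#'   default derived with [default_partition()]. Every chromosome must
#'   be mapped.
#' @param cfg an [align_config()].
#' @param return_hits also attach the full hit table as attribute
#'   `"hits"`.
#' @return a `call_matrix` with one row per probe and one column per
#'   label; attribute `"log"` holds per-label counts of
#'   called/absent/ambiguous probes.
#' @export
genotype_genome <- function(probes, genome, sample_id = "sample",
                            partition = NULL, cfg = align_config(),
                            return_hits = FALSE) {
  chroms <- as_genome_chars(genome)
  if (is.null(partition)) partition <- default_partition(genome)
  unmapped <- setdiff(names(chroms), names(partition))
  if (length(unmapped)) {
    stop("chromosomes missing from partition: ", paste(unmapped, collapse = ", "))
  }
  labels <- unique(partition[names(chroms)])
  calls <- matrix("N", nrow = nrow(probes), ncol = length(labels),
                  dimnames = list(probes$probe_id, ifelse(labels == "",
                    sample_id, paste0(sample_id, "_", labels))))
  log <- list()
  all_hits <- list()
  for (j in seq_along(labels)) {
    lab <- labels[j]
    sub <- chroms[names(chroms)[partition[names(chroms)] == lab]]
    hits <- .search_placements(probes, as.list(sub), cfg, target = sample_id)
    if (return_hits) all_hits[[lab]] <- hits
    tab <- table(factor(hits$probe_id, levels = probes$probe_id))
    uniq <- names(tab)[tab == 1L]
    one <- hits[hits$probe_id %in% uniq, , drop = FALSE]
    calls[one$probe_id, j] <- one$called_allele
    log[[ifelse(lab == "", "genome", lab)]] <-
      c(called = length(uniq), absent = sum(tab == 0L),
        ambiguous = sum(tab > 1L))
  }
  out <- call_matrix(calls)
  attr(out, "log") <- log
  if (return_hits) attr(out, "hits") <- do.call(rbind, all_hits)
  out
}
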