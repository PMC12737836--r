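# shared fixtures and independent oracles (deliberately naive, loop-based
# implementations kept separate from the package's vectorized code paths)

small_config <- function(seed = 1, ...) {
  args <- modifyList(list(seed = seed, chrom_length = 50000,
                          n_species_A = 2, n_species_B = 2,
                          n_accessions_per_species = 3,
                          n_probes_per_subgenome = 120), list(...))
  do.call(sim_config, args)
}

random_genome <- function(len, n_chrom = 1, seed = 1, prefix = "chr") {
  set.seed(seed)
  setNames(vapply(seq_len(n_chrom), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1)), paste0(prefix, seq_len(n_chrom)))
}

# plant a probe allele into a genome string at a 1-based offset, with
# `n_mm` substitutions at the given flank positions (1-based within the
# 71-mer, excluding the center)
plant_probe <- function(genome_str, probe, at, allele = probe$allele1,
                        strand = "+", mm_at = integer()) {
  seq <- paste0(probe$left_flank, allele, probe$right_flank)
  ch <- strsplit(seq, "")[[1]]
  for (p in mm_at) {
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  }
  seq <- paste(ch, collapse = "")
  if (strand == "-") seq <- revcomp(seq)
  paste0(substr(genome_str, 1, at - 1), seq,
         substr(genome_str, at + nchar(seq), nchar(genome_str)))
}

random_probe <- function(id, flank_length = 35, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bases <- sample(c("A", "C", "G", "T"), 2L)
  probe_table(id,
              paste(sample(c("A", "C", "G", "T"), flank_length, TRUE),
                    collapse = ""),
              bases[1], bases[2],
              paste(sample(c("A", "C", "G", "T"), flank_length, TRUE),
                    collapse = ""))
}

# exhaustive-scan placement oracle: every offset, both strands, both
# alleles, straight from the placement definition
brute_force_placements <- function(probe, chroms, max_mm = 1,
                                   mode = c("per_arm", "total")) {
  mode <- match.arg(mode)
  f <- nchar(probe$left_flank)
  plen <- 2L * f + 1L
  hits <- list()
  for (cn in names(chroms)) {
    sv <- strsplit(chroms[[cn]], "")[[1]]
    L <- length(sv)
    if (L < plen) next
    W <- L - plen + 1L
    for (strand in c("+", "-")) {
      for (allele in c(probe$allele1, probe$allele2)) {
        pat <- paste0(probe$left_flank, allele, probe$right_flank)
        if (strand == "-") pat <- revcomp(pat)
        pv <- strsplit(pat, "")[[1]]
        first_mm <- integer(W); last_mm <- integer(W); center_ok <- logical(W)
        for (j in seq_len(plen)) {
          neq <- sv[j:(W + j - 1L)] != pv[j]
          if (j <= f) first_mm <- first_mm + neq
          else if (j >= f + 2L) last_mm <- last_mm + neq
          else center_ok <- !neq
        }
        lm <- if (strand == "+") first_mm else last_mm
        rm_ <- if (strand == "+") last_mm else first_mm
        ok <- center_ok & (if (mode == "per_arm") lm <= max_mm & rm_ <= max_mm
                           else lm + rm_ <= max_mm)
        off <- which(ok)
        if (length(off)) {
          hits[[length(hits) + 1L]] <- data.frame(
            probe_id = probe$probe_id, chrom = cn, pos = off + f,
            strand = strand, called_allele = allele,
            left_mm = lm[off], right_mm = rm_[off],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(probe_id = character(), chrom = character(),
                      pos = integer(), strand = character(),
                      called_allele = character(), left_mm = integer(),
                      right_mm = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
}

hit_key <- function(h) {
  if (nrow(h) == 0L) return(character())
  sort(paste(h$chrom, h$pos, h$strand, h$called_allele, h$left_mm, h$right_mm))
}

# naive IBS: per pair, loop over markers expanding IUPAC codes to allele
# multisets and counting the intersection
naive_ibs_pair <- function(x, y) {
  pair_of <- c(A = "AA", C = "CC", G = "GG", T = "TT", R = "AG", Y = "CT",
               S = "CG", W = "AT", K = "GT", M = "AC")
  scores <- c()
  for (k in seq_along(x)) {
    if (x[k] == "N" || y[k] == "N") next
    ax <- strsplit(pair_of[[x[k]]], "")[[1]]
    ay <- strsplit(pair_of[[y[k]]], "")[[1]]
    shared <- 0
    for (a in ax) {
      if (a %in% ay) {
        ay <- ay[-match(a, ay)]
        shared <- shared + 1
      }
    }
    scores <- c(scores, shared / 2)
  }
  mean(scores)
}

# naive per-step filter recounts
naive_polymorphic_ids <- function(m) {
  rownames(m)[apply(m, 1, function(r) length(unique(r[r != "N"])) >= 2)]
}
naive_maf_keep_ids <- function(m, thr = 0.05) {
  pair_of <- c(A = "AA", C = "CC", G = "GG", T = "TT", R = "AG", Y = "CT",
               S = "CG", W = "AT", K = "GT", M = "AC")
  keep <- vapply(rownames(m), function(id) {
    alleles <- unlist(strsplit(pair_of[m[id, ][m[id, ] != "N"]], ""))
    tb <- table(alleles)
    length(tb) == 2 && min(tb) / sum(tb) >= thr
  }, logical(1))
  rownames(m)[keep]
}
naive_missing_keep_ids <- function(m, thr = 0.03) {
  rownames(m)[rowMeans(m == "N") <= thr]
}

# a random additive tree and its exact leaf-to-leaf distance matrix
random_additive_tree <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = FALSE)
  tr$edge.length <- runif(length(tr$edge.length), 0.1, 1)
  tr
}

random_call_matrix <- function(n_markers, n_samples, seed = 1,
                               miss_rate = 0.05, het_rate = 0.1) {
  set.seed(seed)
  alleles <- replicate(n_markers, sample(c("A", "C", "G", "T"), 2),
                       simplify = FALSE)
  het_of <- function(a) {
    codes <- c(AG = "R", GA = "R", CT = "Y", TC = "Y", CG = "S", GC = "S",
               AT = "W", TA = "W", GT = "K", TG = "K", AC = "M", CA = "M")
    codes[[paste0(a[1], a[2])]]
  }
  m <- matrix("N", n_markers, n_samples,
              dimnames = list(sprintf("mk%03d", seq_len(n_markers)),
                              sprintf("s%02d", seq_len(n_samples))))
  for (i in seq_len(n_markers)) {
    a <- alleles[[i]]
    g <- sample(c(a, het_of(a)), n_samples, replace = TRUE,
                prob = c((1 - het_rate) / 2, (1 - het_rate) / 2, het_rate))
    g[runif(n_samples) < miss_rate] <- "N"
    m[i, ] <- g
  }
  call_matrix(m)
}
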