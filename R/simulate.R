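#' Configuration of the synthetic allotetraploid study
#'
#' Describes a panel of diploid species diverged from a common
#' proto-ancestor by substitutions only, plus one recent allotetraploid
#' formed by hybridization of two chosen diploid parents (all
#' tetraploids share that single origin). Divergences are per-branch
#' substitution rates (substitutions/site), so two accessions of one
#' species differ in expectation by about twice `accession_divergence`.
#' Substitution-only evolution keeps every genome the same length, so
#' coordinates are homologous across the whole panel and no alignment
#' step is needed anywhere downstream.
#'
#' @param seed RNG seed; identical config + seed gives byte-identical
#'   output.
#' @param n_chrom_per_subgenome chromosomes per (sub)genome.
#' @param chrom_length chromosome length in bp.
#' @param proto_divergence substitutions/site separating the A- and
#'   B-subgenome ancestors (split evenly over the two branches).
#' @param n_species_A,n_species_B diploid species per genome pool.
#' @param species_divergence per-branch rate from pool ancestor to each
#'   species ancestor.
#' @param n_accessions_per_species accessions sampled per species.
#' @param accession_divergence per-branch rate from species ancestor to
#'   each accession.
#' @param tetraploid_mutation rate applied to each tetraploid after
#'   hybridization.
#' @param n_tetraploids number of tetraploid samples (one shared origin).
#' @param he_segments optional homoeologous-exchange events: a list of
#'   lists with fields `subgenome_from` (`"A"` or `"B"`), `chrom`
#'   (index), `start`, `end` (1-based inclusive); the segment of the
#'   donor subgenome overwrites the homologous coordinates of the other
#'   subgenome in every tetraploid.
#' @param n_probes_per_subgenome array probes designed per genome pool.
#' @param flank_length probe flanking-arm length in bp (71 bp probes by
#'   default).
#' @param array_missing_rate per-call probability of a missing array
#'   call.
#' @param array_error_rate per-call probability that an array call is
#'   flipped to the other probe allele.
#' @param genic_fraction fraction of each tetraploid-A chromosome
#'   covered by the synthetic genic BED intervals.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chrom_per_subgenome = 2,
                       chrom_length = 200000,
                       proto_divergence = 0.03,
                       n_species_A = 4, n_species_B = 2,
                       species_divergence = 0.01,
                       n_accessions_per_species = 5,
                       accession_divergence = 0.002,
                       tetraploid_mutation = 0.0005,
                       n_tetraploids = 2,
                       he_segments = list(),
                       n_probes_per_subgenome = 800,
                       flank_length = 35,
                       array_missing_rate = 0.01,
                       array_error_rate = 0,
                       genic_fraction = 0.3) {
  cfg <- list(seed = check_seed(seed),
              n_chrom_per_subgenome = as.integer(n_chrom_per_subgenome),
              chrom_length = as.integer(chrom_length),
              proto_divergence = proto_divergence,
              n_species_A = as.integer(n_species_A),
              n_species_B = as.integer(n_species_B),
              species_divergence = species_divergence,
              n_accessions_per_species = as.integer(n_accessions_per_species),
              accession_divergence = accession_divergence,
              tetraploid_mutation = tetraploid_mutation,
              n_tetraploids = as.integer(n_tetraploids),
              he_segments = he_segments,
              n_probes_per_subgenome = as.integer(n_probes_per_subgenome),
              flank_length = as.integer(flank_length),
              array_missing_rate = array_missing_rate,
              array_error_rate = array_error_rate,
              genic_fraction = genic_fraction)
  rates <- c(cfg$proto_divergence, cfg$species_divergence,
             cfg$accession_divergence, cfg$tetraploid_mutation,
             cfg$array_missing_rate, cfg$array_error_rate,
             cfg$genic_fraction)
  if (any(rates < 0 | rates >= 1)) stop("all rates must lie in [0, 1)")
  if (cfg$chrom_length <= 2L * cfg$flank_length + 1L) {
    stop("chrom_length must exceed the probe length")
  }
  if (min(cfg$n_species_A, cfg$n_species_B) < 1L ||
      cfg$n_accessions_per_species < 2L) {
    stop("need at least one species per pool and two accessions per species")
  }
  class(cfg) <- "sim_config"
  cfg
}

# genomes are held internally as integer vectors (1..4 indexing ACGT),
# one per chromosome; substitution replaces a base by one of the other
# three uniformly
.mutate_genome <- function(genome, rate) {
  if (rate == 0) return(genome)
  lapply(genome, function(g) {
    n <- rbinom(1L, length(g), rate)
    if (n > 0L) {
      pos <- sample.int(length(g), n)
      g[pos] <- (g[pos] - 1L + sample.int(3L, n, replace = TRUE)) %% 4L + 1L
    }
    g
  })
}

.genome_to_char <- function(genome) {
  vapply(genome, function(g) paste(DNA_BASES[g], collapse = ""), character(1))
}

# positions whose flanks occur more than once (either strand) in the
# ancestor genome are rejected at probe-design time
.nonunique_kmers <- function(chrom_strs, k) {
  all_kmers <- unlist(lapply(chrom_strs, function(s) {
    n <- nchar(s)
    fwd <- substring(s, 1:(n - k + 1L), k:n)
    c(fwd, revcomp(fwd))
  }), use.names = FALSE)
  unique(all_kmers[duplicated(all_kmers)])
}

.design_probes <- function(pool, accession_genomes, ancestor, cfg) {
  f <- cfg$flank_length
  len <- cfg$chrom_length
  anc_chars <- .genome_to_char(ancestor)
  bad_kmers <- .nonunique_kmers(anc_chars, f)
  cand <- list()
  for (cn in names(ancestor)) {
    pres <- lapply(1:4, function(b)
      Reduce(`|`, lapply(accession_genomes, function(g) g[[cn]] == b)))
    nall <- pres[[1]] + pres[[2]] + pres[[3]] + pres[[4]]
    anc_g <- ancestor[[cn]]
    ok <- nall == 2L & pres_contains_anc(pres, anc_g)
    pos <- which(ok)
    pos <- pos[pos > f & pos <= len - f]
    if (length(pos)) {
      b1 <- ifelse(pres[[1]][pos], 1L, ifelse(pres[[2]][pos], 2L, 3L))
      b2 <- ifelse(pres[[4]][pos], 4L, ifelse(pres[[3]][pos], 3L, 2L))
      cand[[cn]] <- data.frame(chrom = cn, pos = pos,
                               base_lo = b1, base_hi = b2,
                               anc = anc_g[pos], stringsAsFactors = FALSE)
    }
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0L) {
    stop("no segregating sites available for probe design in pool ", pool)
  }
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  picked <- vector("list", cfg$n_probes_per_subgenome)
  blocked <- lapply(ancestor, function(g) logical(length(g)))
  n_picked <- 0L
  for (i in seq_len(nrow(cand))) {
    if (n_picked == cfg$n_probes_per_subgenome) break
    cn <- cand$chrom[i]; p <- cand$pos[i]
    lo <- max(1L, p - 2L * f); hi <- min(len, p + 2L * f)
    if (any(blocked[[cn]][lo:hi])) next
    left <- substr(anc_chars[[cn]], p - f, p - 1L)
    right <- substr(anc_chars[[cn]], p + 1L, p + f)
    if (left %in% bad_kmers || right %in% bad_kmers) next
    n_picked <- n_picked + 1L
    picked[[n_picked]] <- cand[i, , drop = FALSE]
    blocked[[cn]][lo:hi] <- TRUE
  }
  if (n_picked < cfg$n_probes_per_subgenome) {
    stop("requested ", cfg$n_probes_per_subgenome, " probes for pool ", pool,
         " but only ", n_picked, " placeable segregating sites are available")
  }
  sites <- do.call(rbind, picked[seq_len(n_picked)])
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  anc_base <- DNA_BASES[sites$anc]
  derived <- DNA_BASES[ifelse(sites$anc == sites$base_lo, sites$base_hi,
                              sites$base_lo)]
  ids <- sprintf("m%s%04d", pool, seq_len(n_picked))
  probes <- probe_table(
    probe_id = ids,
    left_flank = substr(anc_chars[sites$chrom], sites$pos - f, sites$pos - 1L),
    allele1 = anc_base, allele2 = derived,
    right_flank = substr(anc_chars[sites$chrom], sites$pos + 1L, sites$pos + f))
  truth <- data.frame(probe_id = ids, chrom = sites$chrom, pos = sites$pos,
                      ancestral = anc_base, derived = derived,
                      stringsAsFactors = FALSE)
  list(probes = probes, truth = truth)
}

# does the segregating pair at each position include the ancestor base
pres_contains_anc <- function(pres, anc_g) {
  out <- logical(length(anc_g))
  for (b in 1:4) {
    sel <- anc_g == b
    out[sel] <- pres[[b]][sel]
  }
  out
}

.check_he_segments <- function(he, cfg) {
  if (length(he) == 0L) return(invisible())
  key <- vapply(he, function(s) {
    stopifnot(s$subgenome_from %in% c("A", "B"),
              s$start >= 1, s$end <= cfg$chrom_length, s$start <= s$end)
    paste(s$subgenome_from, s$chrom)
  }, character(1))
  for (k in unique(key)) {
    segs <- he[key == k]
    iv <- do.call(rbind, lapply(segs, function(s) c(s$start, s$end)))
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    if (nrow(iv) > 1L && any(iv[-1L, 1L] <= iv[-nrow(iv), 2L])) {
      stop("overlapping he_segments")
    }
  }
  invisible()
}

#' Simulate a complete synthetic study with ground truth
#'
#' Generates the diploid species panel, the allotetraploid(s), an
#' Axiom-style probe set designed at sites segregating within each
#' genome pool (flanks taken from the pool ancestor and guaranteed
#' unique there, probes non-overlapping), noisy array genotype calls for
#' every diploid accession, and a truth bundle (true parents, true tree,
#' true variants against the tetraploid A subgenome, genic BED, per-probe
#' truth) that downstream stages can be validated against.
#'
#' @param config a [sim_config()].
#' @return list with `genomes` (sample -> named character vector of
#'   chromosomes; tetraploid chromosomes are renamed `A01..`/`B01..`),
#'   `probes` (a `probe_table`), `array_calls` (a `call_matrix`,
#'   diploid accessions only), `truth` (see Details) and `config`.
#'
#' @details `truth` contains `parent_A_id`, `parent_B_id`, `true_tree`
#'   (Newick over all diploid accessions plus dissected tetraploid
#'   subgenome tips), `true_variants` (variant table of two diploid
#'   lineages — the A parent and one accession from another A species —
#'   against tetraploid 1's A subgenome as reference), `lineage_close` /
#'   `lineage_far` (those two lineage ids), `genic_bed` (0-based
#'   half-open intervals on the tetraploid A chromosomes),
#'   `chrom_lengths`, and `probe_truth`.
#' @export
simulate_panel <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  .check_he_segments(cfg$he_segments, cfg)
  nc <- cfg$n_chrom_per_subgenome
  len <- cfg$chrom_length
  chrom_names <- sprintf("Chr%02d", seq_len(nc))

  proto <- setNames(lapply(seq_len(nc), function(i)
    sample.int(4L, len, replace = TRUE)), chrom_names)
  pool_anc <- list(A = .mutate_genome(proto, cfg$proto_divergence / 2),
                   B = .mutate_genome(proto, cfg$proto_divergence / 2))

  species <- list()
  accessions <- list()
  for (pool in c("A", "B")) {
    nsp <- if (pool == "A") cfg$n_species_A else cfg$n_species_B
    for (s in seq_len(nsp)) {
      sp_id <- paste0(pool, s)
      species[[sp_id]] <- .mutate_genome(pool_anc[[pool]],
                                         cfg$species_divergence)
      for (a in seq_len(cfg$n_accessions_per_species)) {
        accessions[[paste0(sp_id, "_", a)]] <-
          .mutate_genome(species[[sp_id]], cfg$accession_divergence)
      }
    }
  }
  acc_ids <- names(accessions)
  pool_of <- substr(acc_ids, 1L, 1L)

  parent_A_id <- sample(acc_ids[pool_of == "A"], 1L)
  parent_B_id <- sample(acc_ids[pool_of == "B"], 1L)
  tet_chroms <- c(sprintf("A%02d", seq_len(nc)), sprintf("B%02d", seq_len(nc)))
  hybrid <- setNames(c(accessions[[parent_A_id]], accessions[[parent_B_id]]),
                     tet_chroms)
  tets <- list()
  for (t in seq_len(cfg$n_tetraploids)) {
    tg <- .mutate_genome(hybrid, cfg$tetraploid_mutation)
    for (seg in cfg$he_segments) {
      from <- sprintf("%s%02d", seg$subgenome_from, seg$chrom)
      to <- sprintf("%s%02d", setdiff(c("A", "B"), seg$subgenome_from),
                    seg$chrom)
      tg[[to]][seg$start:seg$end] <- tg[[from]][seg$start:seg$end]
    }
    tets[[paste0("tet", t)]] <- tg
  }

  pr_A <- .design_probes("A", accessions[pool_of == "A"], pool_anc$A, cfg)
  pr_B <- .design_probes("B", accessions[pool_of == "B"], pool_anc$B, cfg)
  probes <- rbind(pr_A$probes, pr_B$probes)
  class(probes) <- c("probe_table", "data.frame")
  probe_truth <- rbind(pr_A$truth, pr_B$truth)

  calls <- matrix("N", nrow(probes), length(acc_ids),
                  dimnames = list(probes$probe_id, acc_ids))
  for (id in acc_ids) {
    g <- accessions[[id]]
    for (cn in unique(probe_truth$chrom)) {
      sel <- probe_truth$chrom == cn
      calls[sel, id] <- DNA_BASES[g[[cn]][probe_truth$pos[sel]]]
    }
  }
  # array noise: mask to missing with rate m, flip to the other probe
  # allele with rate e (only calls matching a probe allele can flip)
  ncell <- length(calls)
  if (cfg$array_error_rate > 0) {
    a1 <- matrix(probes$allele1, nrow(calls), ncol(calls))
    a2 <- matrix(probes$allele2, nrow(calls), ncol(calls))
    flip <- matrix(runif(ncell) < cfg$array_error_rate, nrow(calls))
    sel1 <- flip & calls == a1
    sel2 <- flip & calls == a2
    calls[sel1] <- a2[sel1]
    calls[sel2] <- a1[sel2]
  }
  if (cfg$array_missing_rate > 0) {
    calls[matrix(runif(ncell) < cfg$array_missing_rate, nrow(calls))] <- "N"
  }

  truth <- list(
    parent_A_id = parent_A_id, parent_B_id = parent_B_id,
    true_tree = .truth_newick(acc_ids, parent_A_id, parent_B_id,
                              names(tets), cfg),
    lineage_close = parent_A_id,
    lineage_far = .pick_far_lineage(acc_ids, pool_of, parent_A_id),
    chrom_lengths = setNames(rep(len, nc), sprintf("A%02d", seq_len(nc))),
    probe_truth = probe_truth)
  truth$true_variants <- .truth_variants(tets[[1L]], accessions,
                                         truth$lineage_close,
                                         truth$lineage_far, nc)
  truth$genic_bed <- .genic_bed(truth$chrom_lengths, cfg$genic_fraction)

  genomes <- c(lapply(accessions, .genome_to_char),
               lapply(tets, .genome_to_char))
  list(genomes = genomes, probes = probes,
       array_calls = call_matrix(calls), truth = truth, config = cfg)
}

# an A-pool accession outside the A parent's species (falls back to a
# conspecific accession when the pool has a single species)
.pick_far_lineage <- function(acc_ids, pool_of, parent_A_id) {
  sp <- sub("_[0-9]+$", "", parent_A_id)
  cand <- acc_ids[pool_of == "A" & !startsWith(acc_ids, paste0(sp, "_"))]
  if (length(cand) == 0L) cand <- setdiff(acc_ids[pool_of == "A"], parent_A_id)
  cand[1L]
}

# star-of-stars truth topology with expected per-branch lengths; the
# tetraploid subgenome tips attach at their parent accession
.truth_newick <- function(acc_ids, parent_A_id, parent_B_id, tet_ids, cfg) {
  tip <- function(id, pool) {
    parent <- if (pool == "A") parent_A_id else parent_B_id
    if (id == parent) {
      tt <- paste0(tet_ids, "_", pool, ":", cfg$tetraploid_mutation,
                   collapse = ",")
      sprintf("((%s):0,%s:0):%s", tt, id, cfg$accession_divergence)
    } else {
      paste0(id, ":", cfg$accession_divergence)
    }
  }
  pool_clade <- function(pool) {
    sp <- unique(sub("_[0-9]+$", "", acc_ids[startsWith(acc_ids, pool)]))
    clades <- vapply(sp, function(s) {
      accs <- acc_ids[startsWith(acc_ids, paste0(s, "_"))]
      sprintf("(%s):%s", paste(vapply(accs, tip, character(1), pool),
                               collapse = ","), cfg$species_divergence)
    }, character(1))
    sprintf("(%s):%s", paste(clades, collapse = ","),
            cfg$proto_divergence / 2)
  }
  sprintf("(%s,%s);", pool_clade("A"), pool_clade("B"))
}

# variants of the two chosen diploid lineages against tetraploid 1's A
# subgenome, in tetraploid-A coordinates (A01..)
.truth_variants <- function(tet_genome, accessions, close_id, far_id, nc) {
  rows <- list()
  for (i in seq_len(nc)) {
    tc <- sprintf("A%02d", i)
    dc <- sprintf("Chr%02d", i)
    ref <- tet_genome[[tc]]
    cl <- accessions[[close_id]][[dc]]
    fa <- accessions[[far_id]][[dc]]
    pos <- which(cl != ref | fa != ref)
    if (!length(pos)) next
    refb <- DNA_BASES[ref[pos]]
    clb <- DNA_BASES[cl[pos]]
    fab <- DNA_BASES[fa[pos]]
    # first alternate allele is the close lineage's base when it differs
    # from the reference; a second alternate appears only when the far
    # lineage carries a third base
    alt1 <- ifelse(clb != refb, clb, fab)
    gt_cl <- ifelse(clb == refb, 0L, 1L)
    gt_fa <- ifelse(fab == refb, 0L, ifelse(fab == alt1, 1L, 2L))
    alt <- ifelse(clb != refb & fab != refb & clb != fab,
                  paste(clb, fab, sep = ","), alt1)
    rows[[tc]] <- data.frame(chrom = tc, pos = pos, ref = refb, alt = alt,
                             close = gt_cl, far = gt_fa,
                             stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), close = integer(), far = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  names(out)[names(out) == "close"] <- close_id
  names(out)[names(out) == "far"] <- far_id
  variant_table(out, lineages = c(close_id, far_id))
}

# non-overlapping fixed-length synthetic gene intervals covering about
# `fraction` of each chromosome (0-based half-open)
.genic_bed <- function(chrom_lengths, fraction, gene_length = 2000L) {
  rows <- list()
  for (cn in names(chrom_lengths)) {
    len <- chrom_lengths[[cn]]
    n_genes <- floor(len * fraction / gene_length)
    if (n_genes < 1L) next
    slot <- len %/% n_genes
    off <- sample.int(max(1L, slot - gene_length), n_genes, replace = TRUE) - 1L
    start <- (seq_len(n_genes) - 1L) * slot + off
    rows[[cn]] <- data.frame(chrom = cn, start = start,
                             end = pmin(start + gene_length, len),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write simulated genomes as FASTA files
#'
#' @param genomes `genomes` element of [simulate_panel()] output.
#' @param outdir directory (created if needed); one `<sample>.fa` per
#'   sample.
#' @export
write_genomes <- function(genomes, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(genomes)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(genomes[[id]]),
                                file.path(outdir, paste0(id, ".fa")))
  }
  invisible(outdir)
}
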