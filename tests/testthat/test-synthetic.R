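test_that("simulation is deterministic and coordinate-homologous", {
  cfg <- small_config(seed = 42)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$genomes, p2$genomes)
  expect_identical(unclass(p1$array_calls), unclass(p2$array_calls))
  expect_identical(p1$truth$true_tree, p2$truth$true_tree)
  # substitution-only evolution: all diploid genomes have identical
  # chromosome names and lengths
  lens <- lapply(p1$genomes[!grepl("^tet", names(p1$genomes))],
                 function(g) nchar(g))
  expect_true(all(vapply(lens, identical, logical(1), lens[[1]])))
  # tetraploid = A parent chromosomes + B parent chromosomes
  expect_identical(names(p1$genomes$tet1), c("A01", "A02", "B01", "B02"))
  expect_identical(unname(nchar(p1$genomes$tet1)), rep(50000L, 4))
})

test_that("pairwise accession divergence matches the closed-form expectation", {
  # two accessions of one species are separated by two independent branches
  # of rate d, so the p-distance expectation is ~2d at small d
  d <- 0.002
  cfg <- small_config(seed = 7, chrom_length = 100000,
                      accession_divergence = d)
  p <- simulate_panel(cfg)
  g1 <- strsplit(paste(p$genomes[["A1_1"]], collapse = ""), "")[[1]]
  g2 <- strsplit(paste(p$genomes[["A1_2"]], collapse = ""), "")[[1]]
  pdist <- mean(g1 != g2)
  L <- length(g1)
  se <- sqrt(2 * d * (1 - 2 * d) / L)
  expect_lt(abs(pdist - 2 * d), 3 * se)
})

test_that("species divergence increases between-species p-distance", {
  pd <- vapply(c(0.005, 0.01, 0.02), function(dsp) {
    p <- simulate_panel(small_config(seed = 11, species_divergence = dsp,
                                     n_probes_per_subgenome = 20))
    g1 <- strsplit(paste(p$genomes[["A1_1"]], collapse = ""), "")[[1]]
    g2 <- strsplit(paste(p$genomes[["A2_1"]], collapse = ""), "")[[1]]
    mean(g1 != g2)
  }, numeric(1))
  expect_true(all(diff(pd) > 0))
})

test_that("array noise rates are calibrated", {
  m <- 0.05
  p <- simulate_panel(small_config(seed = 3, array_missing_rate = m))
  n <- length(p$array_calls)
  frac <- mean(p$array_calls == "N")
  expect_lt(abs(frac - m), 3 * sqrt(m * (1 - m) / n))

  # error flips: compare an e > 0 panel against the clean panel from the
  # same seed (identical up to the noise stage), restricted to the pool-A
  # markers and accessions where every true call is one of the two alleles
  e <- 0.05
  clean <- simulate_panel(small_config(seed = 5, array_missing_rate = 0))
  noisy <- simulate_panel(small_config(seed = 5, array_missing_rate = 0,
                                       array_error_rate = e))
  amk <- grep("^mA", rownames(clean$array_calls), value = TRUE)
  acc <- grep("^A", colnames(clean$array_calls), value = TRUE)
  x <- clean$array_calls[amk, acc]
  y <- noisy$array_calls[amk, acc]
  expect_lt(abs(mean(x != y) - e), 3 * sqrt(e * (1 - e) / length(x)))
  # flips always land on the other probe allele
  flipped <- which(x != y)
  a1 <- matrix(clean$probes[match(amk, clean$probes$probe_id), "allele1"],
               nrow(x), ncol(x))
  a2 <- matrix(clean$probes[match(amk, clean$probes$probe_id), "allele2"],
               nrow(x), ncol(x))
  expect_true(all(y[flipped] == a1[flipped] | y[flipped] == a2[flipped]))
})

test_that("probe design respects geometry, segregation and truth bookkeeping", {
  p <- simulate_panel(small_config(seed = 9))
  pr <- p$probes
  tr <- p$truth$probe_truth
  expect_equal(nrow(pr), 240)
  expect_true(all(nchar(pr$left_flank) == 35 & nchar(pr$right_flank) == 35))
  expect_true(all(pr$allele1 != pr$allele2))
  # every probe_truth position carries both alleles somewhere in the panel
  for (i in sample(nrow(tr), 25)) {
    pool <- substr(tr$probe_id[i], 2, 2)
    accs <- grep(paste0("^", pool), colnames(p$array_calls), value = TRUE)
    bases <- vapply(accs, function(id)
      substr(p$genomes[[id]][[tr$chrom[i]]], tr$pos[i], tr$pos[i]),
      character(1))
    expect_setequal(unique(bases), c(tr$ancestral[i], tr$derived[i]))
  }
  # parents exist in the accession panel
  expect_true(p$truth$parent_A_id %in% colnames(p$array_calls))
  expect_true(p$truth$parent_B_id %in% colnames(p$array_calls))
  # non-overlapping probes: within each design pool, SNP sites on one
  # chromosome are >= 71 bp apart (pools are designed on different
  # ancestors and may overlap each other at homologous coordinates)
  for (pool in c("mA", "mB")) {
    sub <- tr[startsWith(tr$probe_id, pool), ]
    for (cn in unique(sub$chrom)) {
      pos <- sort(sub$pos[sub$chrom == cn])
      if (length(pos) > 1) expect_true(all(diff(pos) >= 71))
    }
  }
})

test_that("excessive probe demand and overlapping exchange segments raise", {
  expect_error(simulate_panel(small_config(seed = 2, chrom_length = 5000,
                                           n_probes_per_subgenome = 500)),
               "placeable segregating sites")
  he <- list(list(subgenome_from = "A", chrom = 1, start = 100, end = 2000),
             list(subgenome_from = "A", chrom = 1, start = 1500, end = 2500))
  expect_error(simulate_panel(small_config(seed = 2, he_segments = he)),
               "overlapping")
})

test_that("homoeologous exchange copies the donor segment into the other subgenome", {
  he <- list(list(subgenome_from = "A", chrom = 1, start = 1000, end = 6000))
  p <- simulate_panel(small_config(seed = 13, he_segments = he,
                                   tetraploid_mutation = 0))
  tet <- p$genomes$tet1
  expect_identical(substr(tet[["B01"]], 1000, 6000),
                   substr(tet[["A01"]], 1000, 6000))
  # outside the segment the B chromosome still tracks the B parent
  pb <- p$genomes[[p$truth$parent_B_id]]
  expect_identical(substr(tet[["B01"]], 6001, 20000),
                   substr(pb[["Chr01"]], 6001, 20000))
})

test_that("truth bundle round-trips through disk formats", {
  p <- simulate_panel(small_config(seed = 21))
  outdir <- withr::local_tempdir()
  write_truth(p$truth, outdir)
  back <- read_truth(outdir)
  expect_identical(back$parent_A_id, p$truth$parent_A_id)
  expect_identical(back$parent_B_id, p$truth$parent_B_id)
  expect_identical(back$chrom_lengths, p$truth$chrom_lengths)
  expect_equal(back$probe_truth, p$truth$probe_truth)
  expect_equal(back$genic_bed, p$truth$genic_bed)
  # VCF round-trip preserves coordinates, alleles and genotypes
  tv <- p$truth$true_variants
  expect_equal(back$true_variants$pos, tv$pos)
  expect_equal(back$true_variants$ref, tv$ref)
  expect_equal(back$true_variants$alt, tv$alt)
  for (l in variant_lineages(tv)) {
    expect_equal(back$true_variants[[l]], tv[[l]])
  }
  # Newick parses and contains every diploid accession plus dissected tips
  tr <- read_newick(file.path(outdir, "true_tree.nwk"))
  expect_setequal(tr$tip.label,
                  c(colnames(p$array_calls), "tet1_A", "tet1_B",
                    "tet2_A", "tet2_B"))
})

test_that("with no post-hybridization mutation the parent lineage shows no variants", {
  p <- simulate_panel(small_config(seed = 31, tetraploid_mutation = 0))
  tv <- p$truth$true_variants
  close <- p$truth$lineage_close
  expect_identical(close, p$truth$parent_A_id)
  expect_true(all(tv[[close]] == 0L))
  expect_gt(nrow(tv), 0)  # the far lineage still differs from the reference
})

test_that("single substitutions appear in the truth VCF at 1-based positions", {
  # d_tet > 0 introduces tetraploid-private sites where the close lineage
  # carries the (reference-differing) alternate; check coordinate convention
  p <- simulate_panel(small_config(seed = 33))
  tv <- p$truth$true_variants
  ref_genome <- p$genomes$tet1
  close <- p$genomes[[p$truth$lineage_close]]
  i <- which(tv[[p$truth$lineage_close]] >= 1L)[1]
  chrom <- tv$chrom[i]
  dip_chrom <- sub("^A", "Chr", chrom)
  expect_identical(substr(ref_genome[[chrom]], tv$pos[i], tv$pos[i]), tv$ref[i])
  alt1 <- strsplit(tv$alt[i], ",")[[1]][tv[[p$truth$lineage_close]][i]]
  expect_identical(substr(close[[dip_chrom]], tv$pos[i], tv$pos[i]), alt1)
})
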