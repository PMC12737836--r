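test_that("bracket-notation probes parse, deduplicate and length-filter", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\tsequence",
               "p1\tCAGTCAGT[A/C]CAGTCAGT",
               "p2\tACGTACGT[G/T]ACGTACGT",
               "p2\tACGTACGT[G/T]ACGTACGT",
               "p3\tACGT[A/G]ACGTACGT"), tsv)
  pr <- parse_probes(tsv, flank_length = 8)
  expect_equal(pr$probe_id, "p1")
  expect_equal(pr$left_flank, "CAGTCAGT")
  expect_equal(pr$allele1, "A")
  expect_equal(pr$allele2, "C")
  expect_equal(pr$right_flank, "CAGTCAGT")
  expect_equal(attr(pr, "removed"), c(duplicate = 2L, non_full_length = 1L))
  expect_equal(expand_alleles(pr[1, ]),
               c("CAGTCAGTACAGTCAGT", "CAGTCAGTCCAGTCAGT"))

  writeLines(c("probe_id\tsequence", "bad\tACGT[A/]ACGT"), tsv)
  expect_error(parse_probes(tsv, flank_length = 4), "malformed")
})

test_that("expanded allele sequences are reverse-complement symmetric", {
  pr <- random_probe("p1", flank_length = 10, seed = 1)
  rc_pr <- probe_table("p1rc", revcomp(pr$right_flank),
                       complement_base(pr$allele1),
                       complement_base(pr$allele2), revcomp(pr$left_flank))
  expect_identical(revcomp(expand_alleles(pr)[1]), expand_alleles(rc_pr)[1])
  # degenerate flank-free probes expand to the bare alleles
  p0 <- probe_table("p0", "", "A", "C", "")
  expect_identical(expand_alleles(p0), c("A", "C"))
})

test_that("exact planting yields one hit with correct coordinates", {
  g <- random_genome(5000, seed = 2, prefix = "A0")
  pr <- random_probe("p1", seed = 3)
  g["A01"] <- plant_probe(g[["A01"]], pr, at = 1001)  # 0-based offset 1000
  h <- find_placements(pr, g)
  expect_equal(nrow(h), 1L)
  expect_equal(h$chrom, "A01")
  expect_equal(h$pos, 1036L)
  expect_equal(h$strand, "+")
  expect_equal(h$called_allele, pr$allele1)
  expect_equal(c(h$left_mm, h$right_mm), c(0L, 0L))
})

test_that("flank mismatches are bounded per arm and indistinguishable from a scan", {
  g <- random_genome(5000, seed = 4)
  pr <- random_probe("p1", seed = 5)
  # one mismatch in each arm still places; two in the left arm does not
  g1 <- g
  g1["chr1"] <- plant_probe(g[["chr1"]], pr, at = 2001, mm_at = c(10, 50))
  h <- find_placements(pr, g1)
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$left_mm, h$right_mm), c(1L, 1L))
  g2 <- g
  g2["chr1"] <- plant_probe(g[["chr1"]], pr, at = 2001, mm_at = c(10, 20))
  expect_equal(nrow(find_placements(pr, g2)), 0L)
  expect_equal(hit_key(brute_force_placements(pr, as.list(g2))), character())
  # the total-budget reading admits at most one mismatch anywhere
  cfg_tot <- align_config(max_flank_mismatch = 1, mismatch_mode = "total")
  expect_equal(nrow(find_placements(pr, g1, cfg_tot)), 0L)
  g3 <- g
  g3["chr1"] <- plant_probe(g[["chr1"]], pr, at = 2001, mm_at = 10)
  expect_equal(nrow(find_placements(pr, g3, cfg_tot)), 1L)
})

test_that("multi-locus planting returns all hits and calling rejects them", {
  g <- random_genome(6000, seed = 6)
  pr <- random_probe("p1", seed = 7)
  g["chr1"] <- plant_probe(g[["chr1"]], pr, at = 501)
  g["chr1"] <- plant_probe(g[["chr1"]], pr, at = 4001, allele = pr$allele2,
                           strand = "-")
  h <- find_placements(pr, g)
  expect_equal(nrow(h), 2L)
  expect_setequal(h$strand, c("+", "-"))
  # minus-strand hit reports the forward coordinate of the SNP base and
  # the allele in probe orientation
  hm <- h[h$strand == "-", ]
  expect_equal(hm$pos, 4036L)
  expect_equal(hm$called_allele, pr$allele2)
  expect_identical(call_probe(h)$status, "ambiguous")
  expect_identical(call_probe(h[1, ])$status, "called")
  expect_identical(call_probe(h[0, ])$status, "absent")
})

test_that("placement search equals the exhaustive scan on random probes", {
  g <- random_genome(20000, seed = 8)
  set.seed(9)
  for (k in 1:25) {
    pr <- random_probe(paste0("p", k))
    gk <- g
    scenario <- k %% 5
    if (scenario >= 1) {
      at <- sample(10000, 1) + 100
      gk["chr1"] <- plant_probe(g[["chr1"]], pr, at = at,
                                allele = sample(c(pr$allele1, pr$allele2), 1),
                                strand = sample(c("+", "-"), 1),
                                mm_at = sample(c(1:35, 37:71),
                                               min(scenario - 1, 2)))
    }
    h <- find_placements(pr, gk)
    o <- brute_force_placements(pr, as.list(gk))
    expect_identical(hit_key(h), hit_key(o))
  }
})

test_that("dissected genotyping emits one column per subgenome label", {
  p <- simulate_panel(small_config(seed = 15))
  g <- genotype_genome(p$probes, p$genomes$tet1, sample_id = "tet1")
  expect_identical(colnames(g), c("tet1_A", "tet1_B"))
  expect_identical(rownames(g), p$probes$probe_id)
  lg <- attr(g, "log")
  expect_identical(names(lg), c("A", "B"))
  expect_true(all(vapply(lg, sum, numeric(1)) == nrow(p$probes)))
  # diploid: single unlabeled column
  gd <- genotype_genome(p$probes, p$genomes$A1_1, sample_id = "A1_1")
  expect_identical(colnames(gd), "A1_1")
  # unmapped chromosome errors
  expect_error(genotype_genome(p$probes, p$genomes$tet1, sample_id = "x",
                               partition = c(A01 = "A")), "missing from partition")
})

test_that("a probe placed in both subgenomes is called independently per partition", {
  g <- random_genome(4000, seed = 10, prefix = "A0")
  gb <- random_genome(4000, seed = 11, prefix = "B0")
  pr <- random_probe("p1", seed = 12)
  g["A01"] <- plant_probe(g[["A01"]], pr, at = 301)
  gb["B01"] <- plant_probe(gb[["B01"]], pr, at = 1301, allele = pr$allele2)
  tet <- c(g, gb)
  calls <- genotype_genome(pr, tet, sample_id = "t")
  expect_identical(unname(calls["p1", ]), c(pr$allele1, pr$allele2))
  # a second copy within one subgenome vetoes only that subgenome
  tet2 <- tet
  tet2["A01"] <- plant_probe(tet[["A01"]], pr, at = 2301)
  calls2 <- genotype_genome(pr, tet2, sample_id = "t")
  expect_identical(unname(calls2["p1", ]), c("N", pr$allele2))
})

test_that("calls are invariant to reverse-complementing or shifting chromosomes", {
  p <- simulate_panel(small_config(seed = 17, n_probes_per_subgenome = 60))
  sub <- p$probes[seq(1, 120, by = 4), ]
  g <- p$genomes$A2_1
  fwd <- genotype_genome(sub, g, sample_id = "s")
  rc <- setNames(revcomp(g), names(g))
  expect_identical(unclass(genotype_genome(sub, rc, sample_id = "s")),
                   unclass(fwd))
  # prepending 1 kb of novel sequence shifts every hit by exactly 1000
  pad <- paste(rep("ACGTG", 200), collapse = "")
  shifted <- setNames(paste0(pad, g), names(g))
  pr1 <- sub[5, ]
  h0 <- find_placements(pr1, g)
  h1 <- find_placements(pr1, shifted)
  if (nrow(h0) > 0) expect_equal(h1$pos, h0$pos + 1000L)
})

test_that("zero-noise in-silico genotyping reproduces the array column exactly", {
  p <- simulate_panel(small_config(seed = 19, array_missing_rate = 0,
                                   array_error_rate = 0))
  for (id in c("A1_1", "B2_3")) {
    ins <- genotype_genome(p$probes, p$genomes[[id]], sample_id = id)
    called <- ins[, 1] != "N"
    expect_gt(sum(called), 0)
    expect_identical(ins[called, 1], p$array_calls[called, id])
  }
})
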