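test_that("pseudosequence p-distances use the IUPAC shared-allele rule", {
  ps <- c(a = "AAAA", b = "AACC", c = "AAAA")
  d <- as.matrix(pdistance_matrix(ps))
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "b"], 0.5)
  # het vs hom at one site scores half
  expect_equal(as.matrix(pdistance_matrix(c(x = "A", y = "M")))["x", "y"], 0.5)
  # missing sites are excluded pairwise
  expect_equal(as.matrix(pdistance_matrix(c(x = "ANCC", y = "ACCA")))["x", "y"],
               1 / 3, tolerance = 1e-12)
  expect_error(pdistance_matrix(c(x = "NN", y = "NN")), "no comparable sites")
  expect_error(pdistance_matrix(c(x = "AA", y = "AAA")), "equal length")
})

test_that("neighbor joining solves the three-point configuration", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(as.dist(d))
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
  expect_error(neighbor_joining(as.dist(d[1:2, 1:2])), "at least 3")
})

test_that("neighbor joining resolves the four-point topology with the right internal edge", {
  ids <- c("A", "B", "C", "D")
  d <- matrix(0, 4, 4, dimnames = list(ids, ids))
  d["A", "B"] <- d["B", "A"] <- 5
  d["C", "D"] <- d["D", "C"] <- 9
  d["A", "C"] <- d["C", "A"] <- 7
  d["A", "D"] <- d["D", "A"] <- 8
  d["B", "C"] <- d["C", "B"] <- 8
  d["B", "D"] <- d["D", "B"] <- 9
  tr <- neighbor_joining(as.dist(d))
  # four-point condition: internal edge = ((dAC + dBD) - (dAB + dCD)) / 2 = 1
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_equal(sum(internal), 1)
  expect_identical(find_sister(tr, "A")$sister, "B")
  # across the internal edge the adjacent clades {A} and {B} tie in size;
  # the lexicographic rule picks {A}
  expect_identical(find_sister(tr, c("C", "D"))$sister, "A")
})

test_that("neighbor joining recovers random additive trees exactly", {
  for (s in 1:8) {
    tr0 <- random_additive_tree(sample(4:12, 1), seed = 200 + s)
    d0 <- cophenetic(tr0)
    est <- neighbor_joining(as.dist(d0))
    expect_equal(ape::dist.topo(ape::unroot(tr0), ape::unroot(est)), 0,
                 ignore_attr = TRUE)
    o <- rownames(d0)
    expect_equal(cophenetic(est)[o, o], d0, tolerance = 1e-10)
  }
})

test_that("taxon order does not change the inferred tree", {
  tr0 <- random_additive_tree(8, seed = 300)
  d0 <- cophenetic(tr0)
  est1 <- neighbor_joining(as.dist(d0))
  perm <- sample(rownames(d0))
  est2 <- neighbor_joining(as.dist(d0[perm, perm]))
  expect_equal(ape::dist.topo(est1, est2), 0, ignore_attr = TRUE)
  o <- rownames(d0)
  expect_equal(cophenetic(est2)[o, o], cophenetic(est1)[o, o],
               tolerance = 1e-10)
})

test_that("bootstrap supports are frequencies of replicate bipartitions", {
  set.seed(1)
  # two clearly separated clades: the separating split must reach 1.0
  base1 <- paste(sample(c("A", "C"), 120, TRUE), collapse = "")
  base2 <- paste(sample(c("G", "T"), 120, TRUE), collapse = "")
  jitter <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(length(ch), k)
    ch[i] <- ifelse(ch[i] %in% c("A", "C"), "T", "A")
    paste(ch, collapse = "")
  }
  ps <- c(a1 = jitter(base1, 2), a2 = jitter(base1, 2), a3 = jitter(base1, 3),
          b1 = jitter(base2, 2), b2 = jitter(base2, 2), b3 = jitter(base2, 3))
  tr <- bootstrap_support(ps, n_resamples = 100, seed = 5)
  expect_equal(clade_support(tr, c("a1", "a2", "a3")), 1)
  # B = 1 gives supports in {0, 1}
  tr1 <- bootstrap_support(ps, n_resamples = 1, seed = 6)
  supp <- attr(tr1, "support")
  expect_true(all(supp[!is.na(supp)] %in% c(0, 1)))
  # tip order permutation leaves supports of corresponding splits unchanged
  tr2 <- bootstrap_support(ps[c(4, 1, 5, 2, 6, 3)], n_resamples = 100, seed = 5)
  expect_equal(clade_support(tr2, c("a1", "a2", "a3")),
               clade_support(tr, c("a1", "a2", "a3")))
  expect_equal(clade_support(tr2, c("a1", "a2")),
               clade_support(tr, c("a1", "a2")))
})

test_that("support of the true species split grows with species divergence", {
  support_at <- function(dsp) {
    p <- simulate_panel(small_config(seed = 55, species_divergence = dsp,
                                     n_probes_per_subgenome = 80))
    accs <- grep("^A", colnames(p$array_calls), value = TRUE)
    ps <- pseudosequences(call_matrix(unclass(p$array_calls)[, accs]))
    tr <- bootstrap_support(ps, n_resamples = 60, seed = 7)
    clade_support(tr, grep("^A1_", accs, value = TRUE))
  }
  s <- vapply(c(0.002, 0.01, 0.05), support_at, numeric(1))
  expect_true(all(diff(s) >= 0))
  expect_gte(s[3], 0.95)
})

test_that("sister-group queries read across the stem edge", {
  tr <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  expect_identical(find_sister(tr, c("D", "E"))$sister, "C")
  expect_identical(find_sister(tr, c("A", "B"))$sister, "C")
  # for tip C the two adjacent clades tie at two tips each; the
  # lexicographic rule picks {A,B}
  expect_identical(find_sister(tr, "C")$sister, c("A", "B"))
  # complement rule: sister of all-but-one tip is that tip
  expect_identical(find_sister(tr, c("A", "B", "C", "D"))$sister, "E")
  # non-clade focal sets error
  expect_error(find_sister(tr, c("A", "D")), "do not form a clade")
  expect_error(find_sister(tr, c("A", "B", "C", "D", "E")), "cover the whole")
})

test_that("Newick round-trips preserve topology, lengths and supports", {
  tr0 <- random_additive_tree(10, seed = 400)
  tr0$node.label <- as.character(round(runif(tr0$Nnode), 3))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr0, path)
  back <- read_newick(path)
  expect_identical(back$tip.label, tr0$tip.label)
  expect_equal(back$edge.length, tr0$edge.length, tolerance = 1e-9)
  expect_identical(back$node.label, tr0$node.label)
  # single cherry
  write_newick(ape::read.tree(text = "(a:1,b:2);"), path)
  expect_equal(length(read_newick(path)$tip.label), 2)
  writeLines("((a,b,(c;", path)
  expect_error(read_newick(path), "malformed")
})
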