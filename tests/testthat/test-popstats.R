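test_that("column selection removes every gapped or ambiguous column", {
  aln <- hap_alignment(c("a", "b", "c"),
                       c("AC-TN", "ACGTA", "ACGTA"))
  expect_identical(select_used_columns(aln), c(1L, 2L, 4L))
  clean <- hap_alignment(c("a", "b"), c("ACGT", "ACGA"))
  expect_identical(select_used_columns(clean), 1:4)
  allgap <- hap_alignment(c("a", "b"), c("--", "AC"))
  expect_error(select_used_columns(allgap), "no columns")
})

test_that("haplotype collapsing tallies counts per population", {
  aln <- hap_alignment(c("a", "b", "c"), c("ACGT", "ACGT", "ACGA"))
  pops <- c(a = "P1", b = "P1", c = "P2")
  inc <- collapse_haplotypes(aln, pops)
  expect_identical(inc$haplotype_ids, c("Hap_1", "Hap_2"))
  expect_identical(unname(inc$counts),
                   matrix(c(2L, 0L, 0L, 1L), nrow = 2))
  expect_identical(unname(inc$sequence_haplotype),
                   c("Hap_1", "Hap_1", "Hap_2"))

  # all identical sequences collapse to a single shared haplotype
  same <- hap_alignment(c("a", "b", "c"), c("AAAA", "AAAA", "AAAA"))
  inc1 <- collapse_haplotypes(same, c(a = "P1", b = "P2", c = "P3"))
  expect_identical(nrow(inc1$counts), 1L)
  expect_identical(sum(inc1$counts > 0), 3L)

  # identity is defined on used columns only: sequences differing only in
  # a gapped column are one haplotype
  gapped <- hap_alignment(c("a", "b"), c("A-GT", "ACGT"))
  inc2 <- collapse_haplotypes(gapped, c(a = "P1", b = "P2"))
  expect_identical(nrow(inc2$counts), 1L)
})

test_that("site classification partitions polymorphic sites", {
  # columns: (A,A,A,G) singleton; (A,A,G,G) informative; (A,A,G,C)
  # singleton (no second residue reaches two copies); (A,A,A,A) invariant;
  # (A,G,G,C) singleton too — G alone reaches two copies
  aln <- hap_alignment(
    c("s1", "s2", "s3", "s4"),
    c("AAAAA", "AAAAG", "AGGAG", "GGCAC"))
  sc <- classify_sites(aln)
  expect_identical(sc$polymorphic_sites, c(1L, 2L, 3L, 5L))
  expect_identical(sc$singleton_sites, c(1L, 3L, 5L))
  expect_identical(sc$parsimony_informative_sites, 2L)
  expect_identical(sc$Nps, sc$Svs + sc$Pis)

  # enumerate residue patterns over 4 sequences: the partition is exact
  pats <- expand.grid(b1 = c("A", "G"), b2 = c("A", "G", "C"),
                      b3 = c("A", "G", "C"), b4 = c("A", "C"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pats))) {
    col <- unlist(pats[i, ])
    a2 <- hap_alignment(paste0("q", 1:4), col)
    sc2 <- classify_sites(a2)
    tab <- table(col)
    expect_identical(sc2$Nps, as.integer(length(tab) >= 2))
    expect_identical(sc2$Pis, as.integer(sum(tab >= 2) >= 2))
    expect_identical(sc2$Nps, sc2$Svs + sc2$Pis)
  }

  expect_true(classify_sites(aln, ids = "s1")$degenerate)
})

test_that("haplotype diversity equals the differing-pair fraction", {
  expect_equal(haplotype_diversity(c(5))$Hd, 0)
  expect_equal(haplotype_diversity(c(2, 2))$Hd, 2 / 3)
  expect_equal(haplotype_diversity(rep(1, 7))$Hd, 1)
  expect_true(haplotype_diversity(c(1))$degenerate)

  set.seed(11)
  for (i in 1:50) {
    counts <- sample(1:6, sample(2:5, 1), replace = TRUE)
    expect_equal(haplotype_diversity(counts)$Hd, oracle_hd(counts),
                 tolerance = 1e-12)
  }
})

test_that("Pi and K match brute-force pair enumeration", {
  aln <- hap_alignment(c("a", "b"),
                       c("AAAAAAAAAA", "AAAAAAAAAG"))
  ns <- nucleotide_stats(aln)
  expect_equal(ns$K, 1)
  expect_equal(ns$Pi, 0.1)
  expect_identical(ns$Pi * ns$L_used, ns$K)

  same <- hap_alignment(c("a", "b", "c"), rep("ACGTAC", 3))
  expect_equal(nucleotide_stats(same)$K, 0)

  for (seed in 1:25) {
    r <- random_test_alignment(seed, n_max = 12, L_max = 30)
    ns <- nucleotide_stats(r$aln)
    expect_equal(ns$K, oracle_K(r$aln$seqs), tolerance = 1e-12)
    expect_equal(ns$Pi, ns$K / r$L, tolerance = 1e-12)
  }
})

test_that("pairwise difference counts agree with ape", {
  skip_if_not_installed("ape")
  r <- random_test_alignment(99, n_max = 15, L_max = 40)
  m <- do.call(rbind, strsplit(tolower(r$aln$seqs), ""))
  rownames(m) <- r$aln$ids
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(m), model = "N"))
  d <- hapconserv:::pairwise_differences(
    hapconserv:::alignment_matrix(r$aln))
  expect_equal(unname(d), unname(ref[r$aln$ids, r$aln$ids]),
               tolerance = 1e-12)
})

test_that("distance matrix holds within- and between-population p-distances", {
  # two populations fixed for sequences 2 apart out of 100 sites
  s1 <- paste(rep("A", 100), collapse = "")
  s2 <- paste(c(rep("A", 98), "G", "G"), collapse = "")
  aln <- hap_alignment(c("a1", "a2", "b1", "b2"), c(s1, s1, s2, s2))
  pops <- c(a1 = "P1", a2 = "P1", b1 = "P2", b2 = "P2")
  dm <- population_distance_matrix(aln, pops)
  expect_equal(dm$values["P1", "P2"], 0.02)
  expect_equal(unname(diag(dm$values)), c(0, 0))
  expect_true(isSymmetric(dm$values))

  # three-population toy set against the brute-force oracle
  r <- random_test_alignment(7, n_max = 18, L_max = 30, n_pops = 3)
  dm2 <- population_distance_matrix(r$aln, r$pops)
  for (a in 1:3) for (b in 1:3) {
    ia <- r$aln$seqs[unname(r$pops) == paste0("P", a)]
    ib <- r$aln$seqs[unname(r$pops) == paste0("P", b)]
    expected <- if (a == b) oracle_K(ia) / r$L else oracle_dxy(ia, ib, r$L)
    expect_equal(unname(dm2$values[a, b]), expected, tolerance = 1e-12)
  }
})

test_that("Fst hits its boundary cases and matches the oracle", {
  s1 <- paste(rep("A", 50), collapse = "")
  s2 <- paste(c("G", rep("A", 49)), collapse = "")
  fixed <- hap_alignment(c("a1", "a2", "b1", "b2"), c(s1, s1, s2, s2))
  pops <- c(a1 = "P1", a2 = "P1", b1 = "P2", b2 = "P2")
  fn <- fst_nm_matrix(fixed, pops)
  expect_equal(fn$fst$values["P1", "P2"], 1)
  expect_equal(fn$nm$values["P1", "P2"], 0)

  # identical composition: no divergence, Fst undefined and flagged
  ident <- hap_alignment(c("a1", "a2", "b1", "b2"), rep(s1, 4))
  fn0 <- fst_nm_matrix(ident, pops)
  expect_true(fn0$fst$flags["P1", "P2"])
  expect_true(is.na(fn0$fst$values["P1", "P2"]))

  # mixed but identical distributions: Fst <= 0, Nm infinite and flagged
  mix <- hap_alignment(c("a1", "a2", "b1", "b2"), c(s1, s2, s1, s2))
  fnm <- fst_nm_matrix(mix, pops)
  expect_lte(fnm$fst$values["P1", "P2"], 0)
  expect_identical(fnm$nm$values["P1", "P2"], Inf)
  expect_true(fnm$nm$flags["P1", "P2"])

  r <- random_test_alignment(13, n_max = 16, L_max = 30, n_pops = 2)
  fn2 <- fst_nm_matrix(r$aln, r$pops)
  ia <- r$aln$seqs[unname(r$pops) == "P1"]
  ib <- r$aln$seqs[unname(r$pops) == "P2"]
  f <- oracle_fst(ia, ib)
  expect_equal(unname(fn2$fst$values["P1", "P2"]), f, tolerance = 1e-12)
  if (f > 0) {
    expect_equal(unname(fn2$nm$values["P1", "P2"]), (1 - f) / (4 * f),
                 tolerance = 1e-12)
  }
})

test_that("sharing summary counts unique and shared haplotypes per region", {
  counts <- matrix(c(1L, 1L, 0L,
                     2L, 0L, 0L), nrow = 2, byrow = TRUE,
                   dimnames = list(c("Hap_1", "Hap_2"),
                                   c("P1", "P2", "P3")))
  inc <- structure(list(haplotype_ids = rownames(counts), counts = counts,
                        populations = colnames(counts)),
                   class = "hap_incidence")
  regions <- c(P1 = "West", P2 = "East", P3 = "East")
  sh <- sharing_summary(inc, regions)
  expect_identical(sh$unique_counts, c(West = 1L, East = 0L))
  expect_equal(sh$shared_counts["West", "East"], 1)

  # fully private haplotypes share nothing
  priv <- matrix(diag(3L), 3, dimnames = list(paste0("Hap_", 1:3),
                                              c("P1", "P2", "P3")))
  incp <- structure(list(haplotype_ids = rownames(priv),
                         counts = priv, populations = colnames(priv)),
                    class = "hap_incidence")
  shp <- sharing_summary(incp, c(P1 = "r1", P2 = "r2", P3 = "r3"))
  offdiag <- shp$shared_counts[upper.tri(shp$shared_counts)]
  expect_true(all(offdiag == 0))

  # random incidence against direct set intersections
  for (seed in 1:20) {
    cfg <- random_incidence(seed, n_populations = 4, max_haplotypes = 15)
    g <- generate_alignment(cfg)
    inc2 <- collapse_haplotypes(g$alignment, g$pops)
    reg <- stats::setNames(c("A", "A", "B", "B"), cfg$populations)
    sh2 <- sharing_summary(inc2, reg)
    in_a <- rowSums(inc2$counts[, c("P1", "P2"), drop = FALSE] > 0) > 0
    in_b <- rowSums(inc2$counts[, c("P3", "P4"), drop = FALSE] > 0) > 0
    expect_identical(unname(sh2$unique_counts["A"]), sum(in_a & !in_b))
    expect_identical(unname(sh2$unique_counts["B"]), sum(in_b & !in_a))
    expect_equal(unname(sh2$shared_counts["A", "B"]), sum(in_a & in_b))
  }
})

test_that("diversity panel assembles per-population statistics coherently", {
  cfg <- random_incidence(5, n_populations = 3, max_haplotypes = 12,
                          max_copies = 4)
  g <- generate_alignment(cfg)
  panel <- diversity_panel(g$alignment, g$pops)
  inc <- collapse_haplotypes(g$alignment, g$pops)
  expect_identical(panel$population, inc$populations)
  expect_equal(panel$H, unname(colSums(inc$counts > 0)))
  expect_equal(panel$S, unname(colSums(inc$counts)))
  expect_true(all(panel$Nps == panel$Svs + panel$Pis))
  expect_true(all(panel$Hd >= 0 & panel$Hd <= 1))
  expect_equal(panel$Pi * length(inc$used_columns), panel$K,
               tolerance = 1e-12)
  expect_identical(panel$Hd == 0, panel$H == 1 | panel$degenerate)

  # a single-sequence population is reported degenerate with zeros
  aln <- hap_alignment(c("a", "b", "c"), c("AAAA", "AATA", "CCCC"))
  pan1 <- diversity_panel(aln, c(a = "P1", b = "P1", c = "P2"))
  expect_true(pan1$degenerate[pan1$population == "P2"])
  expect_equal(pan1$Hd[pan1$population == "P2"], 0)
})
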