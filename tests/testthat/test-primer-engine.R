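test_that("gc_content matches direct counting", {
  expect_equal(gc_content("ATGC"), 50)
  expect_equal(gc_content("AAAA"), 0)
  expect_equal(gc_content("GGGCCC"), 100)
  expect_equal(gc_content(c("AT", "GC")), c(0, 100))
})

test_that("primer_tm agrees with an independent NN summation and behaves sensibly", {
  # frozen 20-mer fixture, value from the hand summation in helper-oracles.R
  s20 <- "AGCGTACGTTAGCATGCAAT"
  expect_equal(primer_tm(s20), 54.813625, tolerance = 1e-6)
  expect_equal(primer_tm(s20), oracle_nn_tm(s20), tolerance = 0.01)
  set.seed(5)
  for (s in random_dna(6, 22)) {
    expect_equal(primer_tm(s), oracle_nn_tm(s), tolerance = 0.01)
    # appending a GC clamp never lowers Tm on these fixtures
    expect_gte(primer_tm(paste0(s, "GC")), primer_tm(s))
  }
  # self-complementary duplexes get the symmetry correction (x = 1, dS - 1.4)
  pal <- "GGGATATCCC"
  expect_identical(pal, revcomp(pal))
  expect_equal(primer_tm(pal), oracle_nn_tm(pal), tolerance = 0.01)
  expect_error(primer_tm("ACGTNACGTT"), class = "isoprime_value_error")
  expect_error(primer_tm("ACGT"), class = "isoprime_value_error")
})

test_that("dimer_score matches the all-offset brute force oracle", {
  expect_equal(dimer_score("AAAA", "TTTT"), naive_dimer_score("AAAA", "TTTT"))
  expect_gte(dimer_score("AAAA", "TTTT"), 4)     # maximal run for length 4
  expect_equal(dimer_score("AAAA", "AAAA"), 0)   # no complementary positions
  a <- "ACGGTTACGGATCAGGTCAA"
  expect_equal(dimer_score(a, revcomp(a)), naive_dimer_score(a, revcomp(a)))
  set.seed(11)
  pa <- random_dna(25, 18)
  pb <- random_dna(25, 21)
  for (i in seq_along(pa)) {
    expect_equal(dimer_score(pa[i], pb[i]), naive_dimer_score(pa[i], pb[i]))
    expect_equal(dimer_score(pa[i], pa[i]), naive_dimer_score(pa[i], pa[i]))
  }
})

test_that("candidates anchor on an engineered divergent column and respect filters", {
  # two genes identical except one column at position 50
  set.seed(3)
  base <- random_dna(1, 120)
  g1 <- base
  ch <- substr(g1, 50, 50)
  substr(g1, 50, 50) <- setdiff(c("A", "C", "G", "T"), ch)[1]
  fam <- toy_family(c(g1, base), c("g1", "g2"))
  cand <- enumerate_candidates(fam, "g1")
  anch <- cand[cand$anchored, ]
  expect_gt(nrow(anch), 0)
  # every anchored candidate's 3' terminus sits on template position 50
  three_prime <- ifelse(anch$strand == "forward", anch$start + anch$length - 1L, anch$start)
  expect_true(all(three_prime == 50))
  # all candidates satisfy length and GC constraints
  cons <- design_constraints()
  expect_true(all(cand$length >= cons$primer_len[1] & cand$length <= cons$primer_len[2]))
  expect_true(all(cand$gc >= cons$gc[1] & cand$gc <= cons$gc[2]))
})

test_that("templates with no SNPs or with ambiguous bases yield no anchored candidates", {
  set.seed(4)
  fam <- toy_family(c(random_dna(1, 80)), "g1")
  fam2 <- rbind(fam, fam)
  fam2$record_id <- c("g1_a1", "g2_a1"); fam2$gene_id <- c("g1", "g2")
  fam2$allele_id <- c("a1", "a1")
  cand <- enumerate_candidates(fam2, "g1")
  expect_equal(nrow(cand), 0L)
  expect_match(attr(cand, "undesignable"), "no gene-differentiating")
  # degenerate template bases abort windows containing them
  s <- paste0(strrep("ACGT", 10), "N", strrep("TGCA", 10))
  s2 <- s; substr(s2, 5, 5) <- "G"
  fam3 <- toy_family(c(s, s2), c("g1", "g2"))
  cand3 <- enumerate_candidates(fam3, "g1")
  if (nrow(cand3)) {
    expect_true(all(cand3$start + cand3$length - 1L < 41 | cand3$start > 41))
  }
})

test_that("allele-differentiating SNPs are tolerated only at the 5' end", {
  set.seed(8)
  base <- random_dna(1, 120)
  # gene-diff column at 60 for g1; allele-diff column at 30 within g1
  g1a1 <- base; substr(g1a1, 60, 60) <- setdiff(c("A","C","G","T"), substr(base, 60, 60))[1]
  g1a2 <- g1a1; substr(g1a2, 30, 30) <- setdiff(c("A","C","G","T"), substr(g1a1, 30, 30))[1]
  fam <- toy_family(c(g1a1, g1a2, base), c("g1", "g1", "g2"), c("a1", "a2", "a1"))
  cand <- enumerate_candidates(fam, "g1")
  w5 <- design_constraints()$five_prime_allele_window
  covers30 <- cand$start <= 30 & cand$start + cand$length - 1L >= 30
  fwd_bad <- cand$strand == "forward" & covers30 & (30 - cand$start + 1L) > w5
  rev_bad <- cand$strand == "reverse" & covers30 &
    (cand$start + cand$length - 1L - 30 + 1L) > w5
  expect_false(any(fwd_bad | rev_bad))
})

test_that("pairing enforces the anchor, allele and amplicon rules", {
  sim <- simulate_family(n_genes = 3, seq_length = 400, gene_divergence = 0.12,
                         allele_divergence = 0.01, seed = 21)
  cand <- enumerate_candidates(sim$family, "g01")
  pairs <- suppressWarnings(pair_primers(cand))
  expect_gt(nrow(pairs), 0)
  cons <- design_constraints()
  # at least one anchored primer per pair
  expect_true(all(pairs$anchored_f | pairs$anchored_r))
  # allele-SNP-bearing primers in at most one position
  expect_true(all((pairs$snp_allele_f > 0) + (pairs$snp_allele_r > 0) <= 1))
  # amplicon inside the soft range (slack included)
  expect_true(all(pairs$amplicon_length >= cons$amplicon_len[1] * (1 - cons$amplicon_slack)))
  expect_true(all(pairs$amplicon_length <= cons$amplicon_len[2] * (1 + cons$amplicon_slack)))
  expect_true(all(pairs$amplicon_length > pairs$len_f & pairs$amplicon_length > pairs$len_r))
  # dimer screening applied
  expect_true(all(pairs$heterodimer <= cons$dimer_score_max))
  # Ta recommendation clamped to the optimized range
  expect_true(all(pairs$ta >= 61 & pairs$ta <= 63))
  # no valid pair -> empty result with per-constraint tallies
  none <- pair_primers(cand[cand$strand == "forward", ])
  expect_equal(nrow(none), 0L)
  expect_true(is.numeric(attr(none, "rejections")))
})

test_that("emitted panel rows re-validate against annotate_primer_snps (idempotence)", {
  sim <- simulate_family(n_genes = 4, seq_length = 400, gene_divergence = 0.10,
                         allele_divergence = 0.005, seed = 31)
  panel <- suppressWarnings(design_panel(sim$family))
  expect_gt(nrow(panel), 0)
  sites <- discover_snps(sim$family)
  cons <- consensus_sequence(sim$family)
  for (i in seq_len(nrow(panel))) {
    g <- panel$gene_id[i]
    ann_f <- annotate_primer_snps(sim$family, g, panel$start[i], nchar(panel$seq_f[i]),
                                  sites = sites, consensus = cons)
    expect_equal(ann_f$snp_gene, panel$snp_gene_f[i])
    expect_equal(ann_f$snp_allele, panel$snp_allele_f[i])
    expect_equal(ann_f$snp_cons, panel$snp_cons_f[i])
    r_start <- panel$start[i] + panel$amplicon_length[i] - nchar(panel$seq_r[i])
    ann_r <- annotate_primer_snps(sim$family, g, r_start, nchar(panel$seq_r[i]),
                                  sites = sites, consensus = cons)
    expect_equal(ann_r$snp_gene, panel$snp_gene_r[i])
    expect_equal(ann_r$snp_allele, panel$snp_allele_r[i])
  }
})

test_that("design_panel covers simulated families and handles degenerate ones", {
  sim <- simulate_family(n_genes = 5, seq_length = 500, gene_divergence = 0.10,
                         allele_divergence = 0.005, seed = 41)
  panel <- suppressWarnings(design_panel(sim$family))
  expect_equal(nrow(panel), 5L)
  spec <- panel_specificity(panel, sim$family)
  expect_true(all(spec$verdict == "specific"))

  # single-gene family: one row, uniqueness waived with a warning
  single <- sim$family[sim$family$gene_id == "g01", ]
  w <- capture_warnings(p1 <- design_panel(single))
  expect_true(any(grepl("waived", w)))
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$snp_gene_f + p1$snp_gene_r, 0)
  expect_match(attr(p1, "report")$status[1], "waived")

  expect_error(design_panel(sim$family[0, ]), class = "isoprime_value_error")
})

test_that("the published panel passes pair-rule validation (shared primers included)", {
  panel <- mald1_panel()
  rules <- validate_pair_rules(panel)
  expect_true(all(rules$pass))
  # the shared subfamily-I forward primer itself is unanchored; its partners are
  shared <- panel[panel$primer_name_f == "qMd1.01/02F", ]
  expect_equal(nrow(shared), 2L)
  expect_true(all(shared$snp_gene_f == 0 & shared$snp_gene_r >= 1))
})
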