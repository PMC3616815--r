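test_that("classify_column handles the exhaustive two-gene cases", {
  # both genes unanimous with disjoint residues: both gene-differentiating
  c1 <- classify_column(list(g1 = c("A", "A"), g2 = c("C", "C")))
  expect_setequal(c1$gene_diff, c("g1", "g2"))
  expect_length(c1$allele_diff, 0)

  # g1 polymorphic; g2's residue is shared by a g1 allele, so neither is
  # gene-differentiating
  c2 <- classify_column(list(g1 = c("A", "C"), g2 = c("C", "C")))
  expect_equal(c2$allele_diff, "g1")
  expect_length(c2$gene_diff, 0)

  # single gene, unanimous alleles: both sets empty
  c3 <- classify_column(list(g1 = c("A", "A")))
  expect_length(c3$gene_diff, 0)
  expect_length(c3$allele_diff, 0)

  # a gap blocks gene-differentiating status
  c4 <- classify_column(list(g1 = c("A", "-"), g2 = c("C", "C")))
  expect_false("g1" %in% c4$gene_diff)
  # g2 still differentiating: no non-gap g1 allele carries C
  expect_true("g2" %in% c4$gene_diff)

  # ambiguity codes mismatch everything: never support unanimity,
  # count as within-gene disagreement
  c5 <- classify_column(list(g1 = c("A", "N"), g2 = c("C", "C")))
  expect_false("g1" %in% c5$gene_diff)
  expect_true("g1" %in% c5$allele_diff)
})

test_that("discover_snps finds exactly the polymorphic non-gap columns", {
  fam <- toy_family(c("AATT", "AGTT"), c("g1", "g2"))
  s <- discover_snps(fam)
  expect_equal(s$column, 2L)

  # identical sequences: no sites
  fam2 <- toy_family(c("AATT", "AATT"), c("g1", "g2"))
  expect_equal(nrow(discover_snps(fam2)), 0L)

  # all-gap column skipped; single record errors
  fam3 <- toy_family(c("A-T", "A-A"), c("g1", "g2"))
  expect_equal(discover_snps(fam3)$column, 3L)
  expect_error(discover_snps(fam3[1, ]), class = "isoprime_value_error")
})

test_that("consensus is column majority with alphabetical tie-break", {
  fam <- toy_family(c("AAC", "AGC", "TGA"), c("g1", "g2", "g3"))
  # col1: A,A,T -> A; col2: A,G,G -> G; col3: C,C,A -> C
  expect_equal(consensus_sequence(fam), "AGC")
  tie <- toy_family(c("AT", "AG"), c("g1", "g2"))
  # col2 tie G/T -> alphabetical G
  expect_equal(substr(consensus_sequence(tie), 2, 2), "G")
})

test_that("annotate_primer_snps counts engineered columns under the footprint", {
  base <- paste0(rep("ACGT", 6), collapse = "")   # 24 nt monomorphic backbone
  # g1 differs from g2/g3 at position 12 (gene-diff for g1);
  # g1's alleles differ at position 3 (allele-diff in g1)
  s_g1a1 <- base; substr(s_g1a1, 12, 12) <- "A"
  s_g1a2 <- s_g1a1; substr(s_g1a2, 3, 3) <- "T"
  fam <- toy_family(c(s_g1a1, s_g1a2, base, base, base),
                    c("g1", "g1", "g2", "g3", "g4"),
                    c("a1", "a2", "a1", "a1", "a1"))
  # footprint over a monomorphic region
  expect_equal(unlist(annotate_primer_snps(fam, "g1", 16, 8)),
               c(snp_cons = 0L, snp_gene = 0L, snp_allele = 0L))
  # footprint ending on the engineered gene-diff column
  ann <- annotate_primer_snps(fam, "g1", 1, 12)
  expect_equal(ann$snp_gene, 1L)
  expect_equal(ann$snp_allele, 1L)   # position 3 also inside
  expect_gte(ann$snp_cons, 1L)       # reference residue off-consensus at col 12
  # footprint covering only the within-gene polymorphic column
  ann2 <- annotate_primer_snps(fam, "g1", 1, 5)
  expect_equal(ann2$snp_allele, 1L)
  expect_equal(ann2$snp_gene, 0L)
  expect_error(annotate_primer_snps(fam, "g1", 20, 10), class = "isoprime_bounds_error")
})

test_that("classification is mutually exclusive and order-invariant on random families", {
  for (seed in 1:8) {
    sim <- simulate_family(n_genes = 4, alleles_per_gene = 3, seq_length = 120,
                           gene_divergence = 0.2, allele_divergence = 0.05,
                           seed = seed)
    sites <- discover_snps(sim$family)
    # mutual exclusion invariant
    for (i in seq_len(nrow(sites))) {
      expect_length(intersect(sites$gene_diff[[i]], sites$allele_diff[[i]]), 0)
    }
    # permutation invariance of record order
    perm <- sim$family[sample(nrow(sim$family)), ]
    sites_p <- discover_snps(perm)
    expect_equal(sites_p$column, sites$column)
    expect_equal(lapply(sites_p$gene_diff, sort), lapply(sites$gene_diff, sort))
    expect_equal(lapply(sites_p$allele_diff, sort), lapply(sites$allele_diff, sort))
  }
})

test_that("adding an allele can only shrink other genes' gene-diff memberships", {
  for (seed in 1:5) {
    sim <- simulate_family(n_genes = 3, alleles_per_gene = 2, seq_length = 150,
                           gene_divergence = 0.25, allele_divergence = 0.02,
                           seed = seed)
    fam <- sim$family
    before <- discover_snps(fam)
    # give g1 a heavily mutated extra allele
    set.seed(seed + 1000)
    donor <- strsplit(fam$seq[fam$gene_id == "g01"][1], "")[[1]]
    hit <- sample(length(donor), 10)
    donor[hit] <- vapply(donor[hit], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
    fam2 <- rbind(fam, tibble::tibble(record_id = "g01_aX", gene_id = "g01",
                                      allele_id = "aX", molecule = "cds",
                                      seq = paste0(donor, collapse = "")))
    after <- discover_snps(fam2)
    for (i in seq_len(nrow(before))) {
      col <- before$column[i]
      j <- match(col, after$column)
      gd_before <- setdiff(before$gene_diff[[i]], "g01")
      gd_after <- if (is.na(j)) character(0) else setdiff(after$gene_diff[[j]], "g01")
      # other genes' memberships only shrink or persist
      expect_true(all(gd_after %in% gd_before))
    }
  }
})
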