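test_that("local alignment score equals full Smith-Waterman on random pairs", {
  set.seed(101)
  for (i in 1:25) {
    pr <- mutated_pair(sample(60:220, 1), n_sub = sample(0:12, 1),
                       n_indel = sample(0:2, 1))
    h <- align_local(pr$a, pr$b, both_strands = FALSE,
                     params = align_params("nt", min_score = 1L))
    expect_equal(h$score, oracle_sw_score(pr$a, pr$b),
                 info = paste("pair", i))
  }
})

test_that("local alignment score matches Biostrings pairwiseAlignment", {
  set.seed(102)
  for (i in 1:5) {
    pr <- mutated_pair(sample(500:2000, 1), n_sub = 40, n_indel = 2)
    h <- align_local(pr$a, pr$b, both_strands = FALSE)
    pa <- Biostrings::pairwiseAlignment(
      pr$a, pr$b, type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2, baseOnly = TRUE),
      gapOpening = 5, gapExtension = 1)
    expect_equal(h$score, Biostrings::score(pa))
  }
})

test_that("identical proteins align at identity 1 and full coverage", {
  set.seed(103)
  p <- random_proteins(1, 300)
  h <- align_local(p, p, alphabet = "aa")
  expect_equal(h$identity, 1.0)
  expect_equal(h$query_coverage, 1.0)
})

test_that("implanted mismatches give the expected identity", {
  set.seed(104)
  pr <- mutated_pair(300, n_sub = 15)
  h <- align_local(pr$a, pr$b, both_strands = FALSE,
                   params = align_params("nt", min_score = 1L))
  # local alignment may trim mutated ends; identity can only exceed the
  # global 0.95 by end-clipping
  expect_gte(h$identity, 0.95 - 1e-9)
  g <- align_genomes(pr$a, pr$b)
  ai <- average_identity(g)
  expect_equal(ai$average_identity, 1 - 15 / 300, tolerance = 1e-9)
})

test_that("reverse-complement queries hit the minus strand at the same identity", {
  set.seed(105)
  a <- rand_seq(400, 0.5)
  h_fwd <- align_local(a, a)
  h_rc <- align_local(revcomp(a), a)
  expect_equal(h_rc$strand, "-")
  expect_equal(h_rc$identity, h_fwd$identity)
  expect_equal(h_rc$score, h_fwd$score)
})

test_that("empty sequences are rejected", {
  expect_error(align_local("", "ACGT"), "empty")
})

test_that("genome alignment SNP calls equal the full-DP oracle", {
  set.seed(106)
  for (i in 1:20) {
    pr <- mutated_pair(sample(80:250, 1), n_sub = sample(1:10, 1),
                       n_indel = sample(0:1, 1), indel_len = 4L)
    g <- align_genomes(pr$a, pr$b)
    o <- oracle_snps(pr$a, pr$b, oracle_global(pr$a, pr$b))
    expect_equal(g$snps$query_pos, o$query_pos, info = paste("pair", i))
    expect_equal(g$snps$target_pos, o$target_pos, info = paste("pair", i))
  }
})

test_that("anchored genome alignment agrees with the DP oracle on larger pairs", {
  set.seed(107)
  for (i in 1:4) {
    pr <- mutated_pair(1500, n_sub = 30, n_indel = 1, indel_len = 6L)
    # force the anchored route by shrinking the single-pass budget
    g_anchor <- align_genomes(pr$a, pr$b, max_dp_cells = 1e4)
    o <- oracle_snps(pr$a, pr$b, oracle_global(pr$a, pr$b))
    expect_equal(sort(g_anchor$snps$query_pos), sort(o$query_pos))
  }
})

test_that("self-alignment yields one block, no SNPs, no indels", {
  set.seed(108)
  a <- rand_seq(3000, 0.45)
  g <- align_genomes(a, a)
  expect_equal(nrow(g$blocks), 1L)
  expect_equal(nrow(g$snps), 0L)
  expect_equal(nrow(g$indels), 0L)
  expect_equal(average_identity(g)$average_identity, 1.0)
})

test_that("a clean deletion is called as one indel with no SNPs inside", {
  set.seed(109)
  a <- rand_seq(30000, 0.45)
  b <- paste0(subseq0(a, 0, 10000), subseq0(a, 17000, 30000))
  g <- align_genomes(a, b)
  expect_equal(nrow(g$snps), 0L)
  expect_equal(nrow(g$indels), 1L)
  expect_equal(g$indels$length, 7000L)
  expect_equal(g$indels$side, "target")
})

test_that("disjoint random sequences give an empty block set", {
  set.seed(110)
  g <- align_genomes(rand_seq(1500, 0.3), rand_seq(1500, 0.7))
  expect_equal(nrow(g$blocks), 0L)
  expect_error(average_identity(g), "no homology")
})

test_that("SNP multiset is symmetric in the argument order", {
  set.seed(111)
  pr <- mutated_pair(5000, n_sub = 60)
  g1 <- align_genomes(pr$a, pr$b)
  g2 <- align_genomes(pr$b, pr$a)
  expect_equal(sort(g1$snps$query_pos), sort(g2$snps$target_pos))
  expect_equal(sort(g1$snps$target_pos), sort(g2$snps$query_pos))
})

test_that("average identity is the length-weighted block mean", {
  blocks <- tibble::tibble(query_start = c(0L, 2000L), query_end = c(1000L, 3000L),
                           target_start = c(0L, 2000L), target_end = c(1000L, 3000L),
                           cols = c(1000L, 1000L), matches = c(1000L, 900L),
                           identity = c(1.0, 0.9))
  ai <- average_identity(blocks)
  expect_equal(ai$average_identity, 0.95)
  expect_equal(ai$aligned_length, 2000L)
})

test_that("ambiguity codes never match", {
  a <- paste0(strrep("ACGT", 30), "NNNNN", strrep("ACGT", 30))
  g <- align_genomes(a, a)
  # N-N columns are neither matches nor SNP calls
  expect_equal(nrow(g$snps), 0L)
  expect_lt(average_identity(g)$average_identity, 1.0)
})
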