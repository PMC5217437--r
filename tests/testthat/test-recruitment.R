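test_that("RPKG has its unit value for 1 read / 1 Kb / 1 Gb", {
  set.seed(601)
  r <- replicon("R1", rand_seq(1000, 0.5))
  pr <- recruit(setNames(subseq0(r$seq, 100, 200), "r1"), r,
                metagenome_bp = 1e9)
  expect_equal(pr$rpkg, 1.0)
  expect_equal(pr$n_recruited, 1L)
})

test_that("error-free reads from the replicon are all recruited at 99/70", {
  A <- generate_ancestor(sim_config(seed = 602, genome_length = 30000),
                         id = "A")$replicon
  reads <- generate_metagenome(list(A = A), c(A = 1), 500, error_rate = 0,
                               seed = 603)
  pr <- recruit(reads, A)
  expect_equal(pr$n_recruited, 500L)
  expect_true(all(pr$hits$identity >= 0.99))
  expect_true(all(pr$hits$aligned_fraction >= 0.70))
})

test_that("the 99% cutoff is a strict subset of the 95% cutoff on a divergent relative", {
  A <- generate_ancestor(sim_config(seed = 604, genome_length = 40000),
                         id = "A")$replicon
  B <- derive_strain(A, snp_rate = 0.03, seed = 605, id = "B")$replicon
  reads <- generate_metagenome(list(B = B), c(B = 1), 600, error_rate = 0,
                               seed = 606)
  p99 <- recruit(reads, A, recruit_params(0.99, 0.70))
  p95 <- recruit(reads, A, recruit_params(0.95, 0.70))
  expect_true(all(p99$hits$read_id %in% p95$hits$read_id))
  # binomial oracle at the permissive cutoff: reads with <= 5 mismatches in
  # 100 bp pass 95% comfortably; nearly all reads qualify
  frac95 <- p95$n_recruited / 600
  frac99 <- p99$n_recruited / 600
  p_pass95 <- stats::pbinom(5, 100, 0.03)
  expect_gt(frac95, p_pass95 - 3 * sqrt(p_pass95 * (1 - p_pass95) / 600))
  # the stringent cutoff drops recruitment several-fold (binomial: only
  # reads with <= 1 mismatch can pass without end-clipping)
  expect_lt(frac99, 0.5 * frac95)
  expect_gt(frac99, stats::pbinom(0, 100, 0.03 + 0.01) / 2)
})

test_that("a replicon absent from the community recruits nothing", {
  set.seed(607)
  A <- replicon("A", rand_seq(20000, 0.45))
  other <- replicon("X", rand_seq(20000, 0.45))
  reads <- generate_metagenome(list(A = A), c(A = 1), 300, seed = 608)
  panel <- recruit_panel(reads, list(A = A, X = other))
  expect_equal(panel$summary$rpkg[panel$summary$replicon == "X"], 0)
  expect_gt(panel$summary$rpkg[panel$summary$replicon == "A"], 0)
})

test_that("doubling the metagenome with unrelated reads halves RPKG", {
  set.seed(609)
  A <- replicon("A", rand_seq(15000, 0.45))
  reads <- generate_metagenome(list(A = A), c(A = 1), 400, error_rate = 0,
                               seed = 610)
  pr1 <- recruit(reads, A)
  pr2 <- recruit(reads, A, metagenome_bp = 2 * pr1$metagenome_bp)
  expect_equal(pr2$rpkg, pr1$rpkg / 2)
})

test_that("community abundances reappear in per-Kb normalised recruitment", {
  A <- generate_ancestor(sim_config(seed = 611, genome_length = 25000),
                         id = "A")$replicon
  B <- derive_strain(A, snp_rate = 0.2, seed = 612, id = "B")$replicon
  reads <- generate_metagenome(list(A = A, B = B), c(A = 0.7, B = 0.3),
                               2000, error_rate = 0, seed = 613)
  panel <- recruit_panel(reads, list(A = A, B = B))
  s <- panel$summary
  ratio <- s$rpkg[s$replicon == "A"] / s$rpkg[s$replicon == "B"]
  n <- 2000
  sd3 <- 3 * sqrt(n * 0.7 * 0.3)
  lo <- (0.7 * n - sd3) / (0.3 * n + sd3)
  hi <- (0.7 * n + sd3) / (0.3 * n - sd3)
  expect_gt(ratio, lo)
  expect_lt(ratio, hi)
})

test_that("positional coverage sums to total aligned bases", {
  set.seed(614)
  A <- replicon("A", rand_seq(10000, 0.45))
  reads <- generate_metagenome(list(A = A), c(A = 1), 200, error_rate = 0,
                               seed = 615)
  pr <- recruit(reads, A)
  expect_equal(sum(pr$coverage),
               sum(pr$hits$end - pr$hits$position))
})

test_that("subsampling reads leaves RPKG unchanged in expectation", {
  set.seed(616)
  A <- replicon("A", rand_seq(20000, 0.45))
  reads <- generate_metagenome(list(A = A), c(A = 1), 1000, error_rate = 0,
                               seed = 617)
  pr_full <- recruit(reads, A)
  rpkgs <- sapply(1:3, function(i) {
    sub <- reads[sample(nrow(reads), 500), ]
    recruit(sub, A)$rpkg
  })
  # halving reads halves both count and metagenome size
  expect_lt(abs(mean(rpkgs) - pr_full$rpkg) / pr_full$rpkg, 0.05)
})

test_that("an empty read set is rejected", {
  expect_error(recruit(character(0), replicon("A", rand_seq(2000, .5))),
               "empty")
})
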