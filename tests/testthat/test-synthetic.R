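test_that("ancestor generation hits its GC and coding-density targets", {
  cfg <- sim_config(seed = 7, genome_length = 50000, gc_target = 0.45,
                    gene_density = 0.85)
  anc <- generate_ancestor(cfg)
  r <- anc$replicon
  expect_equal(nchar(r$seq), 50000L)
  expect_gte(gc_content(r$seq), 0.44)
  expect_lte(gc_content(r$seq), 0.46)
  cds <- r$features[r$features$type == "CDS", ]
  cov <- sum(cds$end - cds$start) / nchar(r$seq)
  expect_gte(cov, 0.80)
  expect_lte(cov, 0.90)
  expect_true("prfC" %in% r$features$gene)
  expect_true(any(r$features$type == "tRNA"))
})

test_that("every generated CDS is a valid ORF", {
  cfg <- sim_config(seed = 8, genome_length = 20000)
  r <- generate_ancestor(cfg)$replicon
  prots <- proteome(r, trim_stop = FALSE)
  expect_true(all(substr(prots, 1, 1) == "M"))
  expect_true(all(substr(prots, nchar(prots), nchar(prots)) == "*"))
  # no internal stop
  expect_false(any(grepl("\\*", substr(prots, 1, nchar(prots) - 1))))
})

test_that("infeasible gene density is rejected", {
  expect_error(sim_config(gene_density = 0.99), "gene_density")
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 11, genome_length = 15000)
  r1 <- generate_ancestor(cfg)$replicon
  r2 <- generate_ancestor(cfg)$replicon
  expect_identical(r1$seq, r2$seq)
  expect_identical(r1$features, r2$features)
})

test_that("derive_strain with zero rates reproduces the parent", {
  r <- generate_ancestor(sim_config(seed = 12, genome_length = 12000))$replicon
  d <- derive_strain(r, snp_rate = 0, indel_rate = 0, seed = 1)
  expect_identical(d$replicon$seq, r$seq)
  expect_equal(nrow(d$truth$snps), 0L)
})

test_that("recorded SNPs recount exactly by position-wise comparison", {
  r <- generate_ancestor(sim_config(seed = 13, genome_length = 100000))$replicon
  d <- derive_strain(r, seed = 5, n_snps = 53)
  av <- strsplit(r$seq, "")[[1]]
  bv <- strsplit(d$replicon$seq, "")[[1]]
  mism <- which(av != bv) - 1L
  expect_equal(sort(mism), sort(d$truth$snps$pos))
  expect_equal(length(mism), 53L)
  expect_false(any(duplicated(d$truth$snps$pos)))
})

test_that("rate-driven SNP counts follow the binomial oracle", {
  r <- generate_ancestor(sim_config(seed = 14, genome_length = 10000))$replicon
  d <- derive_strain(r, snp_rate = 0.02, seed = 6)
  frac <- nrow(d$truth$snps) / 10000
  sd3 <- 3 * sqrt(0.02 * 0.98 / 10000)
  expect_lt(abs(frac - 0.02), sd3)
})

test_that("conjugative element construction round-trips its mobility class", {
  for (cls in c("C", "MB", "NMB")) {
    el <- build_conjugative_element(paste0("p", cls), cls, seed = 3)
    expect_equal(classify_mobility(el$replicon)$class, cls)
  }
})

test_that("MB elements dropping 5 of 12 MPF genes are mobilizable", {
  el <- build_conjugative_element("pMB", "MB", seed = 4, n_mpf_drop = 5)
  call <- classify_mobility(el$replicon)
  expect_equal(call$class, "MB")
  expect_equal(call$n_mpf_present, 7L)
})

test_that("cargo cassettes land at their recorded coordinates", {
  el <- build_conjugative_element("pC", "NMB", cargo = c("cas1", "cas2"),
                                  seed = 5)
  tr <- el$truth$cassettes
  expect_equal(nrow(tr), 2L)
  lib <- sim_config()$cassette_library
  for (i in seq_len(nrow(tr))) {
    s <- subseq0(el$replicon$seq, tr$start[i], tr$end[i])
    expect_equal(nchar(s), lib$length[lib$cassette_id == tr$cassette_id[i]])
  }
})

test_that("unknown cassette ids are rejected", {
  expect_error(build_conjugative_element("p", "C", cargo = "nope", seed = 1),
               "unknown cassette")
})

test_that("ICE integration inserts 5' of prfC and excision restores the host", {
  chrom <- generate_ancestor(sim_config(seed = 16, genome_length = 30000))$replicon
  ice <- replicon("ICEx", rand_seq(8000, 0.42), role = "ICE")
  before <- chrom$features[chrom$features$gene == "prfC", ]
  res <- implant_ice(chrom, ice)
  after <- res$replicon$features[res$replicon$features$gene == "prfC", ]
  expect_equal(nchar(res$replicon$seq), 38000L)
  shift <- if (before$strand == "-") 0L else 8000L
  expect_equal(after$start, before$start + shift)
  tr <- res$truth$integration
  expect_equal(tr$end - tr$start, 8000L)
  restored <- excise_interval(res$replicon, tr$start, tr$end)
  expect_identical(restored$seq, chrom$seq)
})

test_that("two ICE variants share identical flanks around the insertion", {
  chrom <- generate_ancestor(sim_config(seed = 17, genome_length = 25000))$replicon
  r1 <- implant_ice(chrom, replicon("I1", rand_seq(5000, 0.4), role = "ICE"))
  r2 <- implant_ice(chrom, replicon("I2", rand_seq(6000, 0.4), role = "ICE"))
  t1 <- r1$truth$integration; t2 <- r2$truth$integration
  expect_equal(t1$start, t2$start)
  expect_identical(subseq0(r1$replicon$seq, 0, t1$start),
                   subseq0(r2$replicon$seq, 0, t2$start))
  expect_identical(subseq0(r1$replicon$seq, t1$end, nchar(r1$replicon$seq)),
                   subseq0(r2$replicon$seq, t2$end, nchar(r2$replicon$seq)))
  expect_false(identical(subseq0(r1$replicon$seq, t1$start, t1$end),
                         subseq0(r2$replicon$seq, t2$start, t2$end)))
})

test_that("implanting without prfC fails", {
  bare <- replicon("bare", rand_seq(12000, 0.5))
  expect_error(implant_ice(bare, replicon("I", rand_seq(1000, 0.5))),
               "prfC")
})

test_that("tRNA island implant duplicates the 3'-end and round-trips", {
  chrom <- generate_ancestor(sim_config(seed = 18, genome_length = 30000))$replicon
  isl <- replicon("isl", rand_seq(6000, 0.40))
  res <- implant_trna_island(chrom, isl, k = 15)
  td <- res$truth$trna_dup
  dup <- subseq0(res$replicon$seq, td$start, td$end)
  trna <- res$replicon$features[res$replicon$features$type == "tRNA", ][1, ]
  expect_identical(dup, subseq0(res$replicon$seq, trna$end - 15L, trna$end))
  det <- detect_trna_duplication(res$replicon)
  expect_equal(det$dup_start, td$start)
  expect_equal(det$dup_end, td$end)
})

test_that("k = 0 yields no duplication downstream", {
  chrom <- generate_ancestor(sim_config(seed = 19, genome_length = 20000))$replicon
  res <- implant_trna_island(chrom, replicon("isl", rand_seq(4000, 0.4)), k = 0)
  expect_null(res$truth$trna_dup)
  expect_equal(nrow(detect_trna_duplication(res$replicon)), 0L)
})

test_that("CRISPR arrays have the prescribed structure", {
  arr <- generate_crispr_array(n_repeats = 5, repeat_len = 28, spacer_len = 32,
                               seed = 2)
  expect_equal(nchar(arr$seq), 5 * 28 + 4 * 32)
  expect_equal(length(arr$spacers), 4L)
  expect_false(any(duplicated(arr$spacers)))
  expect_equal(nrow(arr$truth), 5L)
})

test_that("metagenome reads respect abundance, origin and error bookkeeping", {
  A <- replicon("A", rand_seq(20000, 0.45))
  B <- replicon("B", rand_seq(15000, 0.50))
  reads <- generate_metagenome(list(A = A, B = B), c(A = 0.7, B = 0.3),
                               n_reads = 10000, error_rate = 0, seed = 21)
  nA <- sum(reads$source == "A")
  expect_lt(abs(nA - 7000), 3 * sqrt(10000 * 0.7 * 0.3))
  # error-free reads are exact (reverse-complemented) substrings
  idx <- sample(nrow(reads), 200)
  for (i in idx) {
    src <- if (reads$source[i] == "A") A$seq else B$seq
    sub <- subseq0(src, reads$start[i], reads$end[i])
    if (reads$strand[i] == "-") sub <- revcomp(sub)
    expect_identical(reads$seq[i], sub)
  }
})

test_that("single-replicon communities yield only that source", {
  A <- replicon("A", rand_seq(5000, 0.45))
  reads <- generate_metagenome(list(A = A), c(A = 1), 500, seed = 22)
  expect_true(all(reads$source == "A"))
})

test_that("read errors are recounted from the truth record", {
  A <- replicon("A", rand_seq(10000, 0.45))
  reads <- generate_metagenome(list(A = A), c(A = 1), 300, error_rate = 0.02,
                               seed = 23)
  for (i in which(reads$n_errors > 0)[1:20]) {
    sub <- subseq0(A$seq, reads$start[i], reads$end[i])
    if (reads$strand[i] == "-") sub <- revcomp(sub)
    mism <- sum(strsplit(reads$seq[i], "")[[1]] != strsplit(sub, "")[[1]])
    expect_equal(mism, reads$n_errors[i])
  }
})
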