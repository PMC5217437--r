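make_feat <- function(id, start, end, strand = "+", gene = NA, product = NA,
                      type = "CDS") {
  tibble::tibble(feature_id = id, type = type, start = as.integer(start),
                 end = as.integer(end), strand = strand, gene = gene,
                 product = product)
}

test_that("mobility classification covers the three classes", {
  for (cls in c("C", "MB", "NMB")) {
    el <- build_conjugative_element(paste0("p", cls), cls, seed = 41)
    call <- classify_mobility(el$replicon)
    expect_equal(call$class, cls)
    if (cls == "C") expect_equal(call$mpf_completeness, 1)
    if (cls == "NMB") expect_false(call$mob_present)
  }
})

test_that("mobility depends only on marker presence, not feature order", {
  el <- build_conjugative_element("pX", "MB", seed = 42)$replicon
  set.seed(43)
  shuffled <- replicon(el$id, el$seq,
                       el$features[sample(nrow(el$features)), ],
                       role = el$role)
  expect_equal(classify_mobility(el)$class, classify_mobility(shuffled)$class)
})

test_that("rule tables missing required categories are rejected", {
  rules <- default_marker_rules()
  expect_error(classify_mobility(
    build_conjugative_element("p", "C", seed = 1)$replicon,
    rules[rules$category != "MOB", ]), "MOB")
})

test_that("seeded CRISPR arrays are recovered with byte-identical spacers", {
  set.seed(44)
  for (i in 1:6) {
    n_rep <- sample(6:10, 1)
    arr <- generate_crispr_array(n_repeats = n_rep, repeat_len = sample(25:35, 1),
                                 spacer_len = sample(28:38, 1), seed = 400 + i)
    host <- rand_seq(15000, 0.45)
    at <- sample(2000:10000, 1)
    det <- detect_crispr(splice_seq(host, at, arr$seq))
    expect_equal(nrow(det), 1L, info = paste("array", i))
    expect_equal(det$n_repeats, n_rep)
    expect_identical(det$spacers[[1]], arr$spacers)
    expect_equal(det$start, at)
  }
})

test_that("random sequences contain no CRISPR arrays", {
  set.seed(45)
  for (i in 1:3) {
    expect_equal(nrow(detect_crispr(rand_seq(100000, 0.45))), 0L)
  }
})

test_that("one mismatched repeat does not break detection", {
  arr <- generate_crispr_array(n_repeats = 7, seed = 46)
  host <- rand_seq(8000, 0.45)
  seqv <- splice_seq(host, 4000, arr$seq)
  v <- strsplit(seqv, "")[[1]]
  p <- 4000 + 60 + 12  # interior of the second repeat
  v[p + 1] <- setdiff(c("A", "C", "G", "T"), v[p + 1])[1]
  det <- detect_crispr(paste(v, collapse = ""))
  expect_equal(nrow(det), 1L)
  expect_equal(det$n_repeats, 7L)
})

test_that("spacer matching applies identity, length and strand rules", {
  set.seed(47)
  sp <- rand_seq(30, 0.5)
  tg <- paste0(rand_seq(400, 0.5), sp, rand_seq(400, 0.5))
  expect_equal(match_spacers(c(s = sp), list(T1 = tg))$identity, 1.0)
  v <- strsplit(sp, "")[[1]]
  for (p in c(10, 20)) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  sp2 <- paste(v, collapse = "")
  expect_equal(nrow(match_spacers(c(s = sp2), list(T1 = tg),
                                  min_identity = 0.93)), 1L)
  expect_equal(nrow(match_spacers(c(s = sp2), list(T1 = tg),
                                  min_identity = 0.95)), 0L)
  m_rc <- match_spacers(c(s = sp), list(T1 = revcomp(tg)))
  expect_equal(nrow(m_rc), 1L)
  expect_equal(m_rc$strand, "-")
})

test_that("TA loci require family, strand and gap agreement", {
  set.seed(48)
  seqv <- rand_seq(12000, 0.45)
  feats <- rbind(
    make_feat("t1", 100, 400, "+", gene = "relE1"),
    make_feat("a1", 480, 700, "+", gene = "relB1"),     # 80 bp gap: locus
    make_feat("t2", 3000, 3300, "+", gene = "hipA"),
    make_feat("a2", 8300, 8600, "+", gene = "hipB"),    # 5 kb apart: no locus
    make_feat("t3", 9000, 9300, "+", gene = "mazF"),
    make_feat("a3", 9350, 9600, "-", gene = "mazE"))    # wrong strand
  r <- replicon("p", seqv, feats, role = "plasmid")
  inv <- scan_ta_rm(r)
  expect_equal(nrow(inv$ta), 1L)
  expect_equal(inv$ta$family, "relBE")
  expect_equal(inv$ta$gap, 80L)
})

test_that("RM systems report complete pairs and surviving components", {
  set.seed(49)
  seqv <- rand_seq(15000, 0.45)
  feats <- rbind(
    make_feat("r1", 100, 1000, "+", gene = "hsdR"),
    make_feat("m1", 1100, 2000, "+", gene = "hsdM"),     # complete Type I
    make_feat("m2", 9000, 9900, "+", gene = "mod"))      # lone Type III MTase
  r <- replicon("p", seqv, feats, role = "plasmid")
  inv <- scan_ta_rm(r)
  expect_equal(sum(inv$rm$status == "complete"), 1L)
  lone <- inv$rm[inv$rm$status == "incomplete", ]
  expect_equal(lone$component, "MTase")
  expect_equal(lone$type, "TypeIII")
})

test_that("TA family counts are additive over concatenated replicons", {
  set.seed(50)
  mk <- function(id, offset) {
    feats <- rbind(
      make_feat(paste0(id, "t"), offset + 100, offset + 400, "+", gene = "vapC"),
      make_feat(paste0(id, "a"), offset + 450, offset + 700, "+", gene = "vapB"))
    feats
  }
  s1 <- rand_seq(2000, .45); s2 <- rand_seq(2000, .45)
  r1 <- replicon("r1", s1, mk("x", 0))
  r2 <- replicon("r2", s2, mk("y", 0))
  rc <- replicon("rc", paste0(s1, s2), rbind(mk("x", 0), mk("y", 2000)))
  n1 <- nrow(scan_ta_rm(r1)$ta)
  n2 <- nrow(scan_ta_rm(r2)$ta)
  nc <- nrow(scan_ta_rm(rc)$ta)
  expect_equal(nc, n1 + n2)
})

test_that("nested tRNA islands report the outermost duplication", {
  chrom <- generate_ancestor(sim_config(seed = 51, genome_length = 25000))$replicon
  inner <- implant_trna_island(chrom, replicon("i1", rand_seq(3000, .4)),
                               k = 15)
  # implant a second island at the same tRNA of the product
  outer <- implant_trna_island(inner$replicon,
                               replicon("i2", rand_seq(2000, .4)), k = 15)
  det <- detect_trna_duplication(outer$replicon)
  expect_equal(nrow(det), 1L)
  # outermost = farthest duplicated copy
  far <- max(inner$truth$trna_dup$end + 2000 + 15, outer$truth$trna_dup$end)
  expect_equal(det$island_end, far)
})

test_that("chromid diagnosis needs essential markers plus redundant tRNAs", {
  set.seed(52)
  chrom <- generate_ancestor(sim_config(seed = 53, genome_length = 30000))$replicon
  mkpl <- function(markers, with_trna) {
    feats <- list()
    pos <- 100L
    prods <- c("DNA ligase", "DNA polymerase III subunit beta",
               "DNA topoisomerase IV subunit A",
               "DNA topoisomerase IV subunit B", "RecA protein")
    for (i in seq_len(markers)) {
      feats[[i]] <- make_feat(paste0("m", i), pos, pos + 900, "+",
                              product = prods[i])
      pos <- pos + 1000L
    }
    if (with_trna) {
      feats[[length(feats) + 1]] <- make_feat("tr", pos, pos + 76, "+",
                                              gene = "tRNA-Met", type = "tRNA")
    }
    replicon("meg", rand_seq(20000, .42),
             dplyr::bind_rows(feats), role = "plasmid")
  }
  rep5 <- diagnose_chromid(mkpl(5, TRUE), chrom)
  expect_equal(rep5$verdict, "chromid")
  expect_equal(rep5$n_markers, 5L)
  rep0 <- diagnose_chromid(mkpl(0, TRUE), chrom)
  expect_equal(rep0$verdict, "plasmid")
  # markers present but no redundant tRNA on the chromosome
  bare_chrom <- replicon("bc", rand_seq(25000, .45))
  rep_no <- diagnose_chromid(mkpl(5, TRUE), bare_chrom)
  expect_false(rep_no$trna_redundant)
  expect_equal(rep_no$verdict, "plasmid")
})
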