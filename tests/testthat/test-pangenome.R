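test_that("reciprocal best hits recover shared single-copy genes", {
  set.seed(301)
  shared <- random_proteins(8, 150, prefix = "s")
  prots <- list(
    G1 = setNames(c(shared, random_proteins(2, 150, prefix = "u1")),
                  paste0("g1_", 1:10)),
    G2 = setNames(c(shared, random_proteins(1, 150, prefix = "u2")),
                  paste0("g2_", 1:9)),
    G3 = setNames(c(shared, random_proteins(2, 150, prefix = "u3")),
                  paste0("g3_", 1:10)))
  og <- find_orthologs(prots)
  expect_equal(length(unique(og$group[og$core])), 8L)
})

test_that("a duplicated gene disqualifies its group from the core", {
  set.seed(302)
  shared <- random_proteins(4, 150)
  prots <- list(
    G1 = setNames(c(shared, shared[1]), paste0("a", 1:5)),  # duplicate of s1
    G2 = setNames(shared, paste0("b", 1:4)))
  og <- find_orthologs(prots)
  dup_groups <- og$group[og$genome == "G1" & og$protein_id %in% c("a1", "a5")]
  expect_true(all(!og$core[og$group %in% dup_groups]))
  expect_equal(length(unique(og$group[og$core])), 3L)
})

test_that("center-star alignment of identical members has no variable sites", {
  set.seed(303)
  p <- random_proteins(1, 120)[[1]]
  prots <- list(G1 = c(x = p), G2 = c(y = p), G3 = c(z = p))
  og <- find_orthologs(prots)
  ca <- align_core_and_concatenate(og, prots)
  expect_equal(ca$variable_sites, 0L)
  expect_equal(unname(ca$aln[1]), p)
})

test_that("one planted substitution yields one variable site", {
  set.seed(304)
  p <- random_proteins(1, 120)[[1]]
  v <- strsplit(p, "")[[1]]
  v[50] <- if (v[50] == "A") "V" else "A"
  p2 <- paste(v, collapse = "")
  prots <- list(G1 = c(x = p), G2 = c(y = p2), G3 = c(z = p))
  og <- find_orthologs(prots)
  ca <- align_core_and_concatenate(og, prots)
  expect_equal(ca$variable_sites, 1L)
})

test_that("K2P distance matches the closed form and ape::dist.dna", {
  aln <- c(a = strrep("A", 100),
           b = paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85)))
  d <- distance_matrix(aln, "K2P")
  expect_equal(d["a", "b"],
               -0.5 * log(1 - 2 * 0.1 - 0.05) - 0.25 * log(1 - 2 * 0.05),
               tolerance = 1e-9)
  expect_equal(round(d["a", "b"], 5), 0.17018)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(unname(aln)), "")))
  expect_equal(d["a", "b"], as.numeric(ape::dist.dna(bin, model = "K80")),
               tolerance = 1e-9)
})

test_that("identical rows are at distance zero; saturation warns", {
  aln <- c(a = strrep("ACGT", 25), b = strrep("ACGT", 25))
  expect_equal(distance_matrix(aln, "K2P")["a", "b"], 0)
  sat <- c(a = strrep("A", 100), b = strrep("C", 100))  # Q = 1
  expect_warning(d <- distance_matrix(sat, "K2P"), "satur")
  expect_true(is.infinite(d["a", "b"]))
})

test_that("Poisson distance matches its closed form", {
  aln <- c(a = strrep("AR", 50), b = paste0(strrep("AR", 40), strrep("GG", 10)))
  d <- distance_matrix(aln, "Poisson")
  pd <- sum(strsplit(aln[1], "")[[1]] != strsplit(aln[2], "")[[1]]) / 100
  expect_equal(d["a", "b"], -log(1 - pd))
})

test_that("three-taxon NJ solves the three-point equations exactly", {
  D <- matrix(c(0, 5, 9, 5, 0, 8, 9, 8, 0), 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- neighbor_joining(D)
  # leaf branch lengths: x = (5+9-8)/2 = 3, y = 2, z = 6
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl[c("x", "y", "z")]), c(3, 2, 6))
})

test_that("NJ recovers additive trees and ignores taxon order", {
  set.seed(305)
  for (i in 1:10) {
    tr <- ape::rtree(sample(6:10, 1))
    D <- ape::cophenetic.phylo(tr)
    nj1 <- neighbor_joining(D)
    expect_equal(phangorn::RF.dist(ape::unroot(tr), nj1), 0)
    perm <- sample(rownames(D))
    nj2 <- neighbor_joining(D[perm, perm])
    expect_equal(phangorn::RF.dist(nj1, nj2), 0)
  }
})

test_that("negative NJ branches are clamped with the deficit moved over", {
  set.seed(306)
  tr <- ape::rtree(8)
  D <- ape::cophenetic.phylo(tr) + matrix(runif(64, 0, 1e-3), 8)
  D <- (D + t(D)) / 2; diag(D) <- 0
  out <- neighbor_joining(D)
  expect_true(all(out$edge.length >= 0))
})

test_that("identical elements have a full-length invariant core", {
  set.seed(307)
  a <- replicon("E1", rand_seq(8000, 0.45), role = "ICE")
  b <- replicon("E2", a$seq, role = "ICE")
  core <- extract_ice_core(list(E1 = a, E2 = b))
  expect_equal(core$core_length, 8000L)
  expect_equal(core$variable_sites, 0L)
  expect_equal(core$average_identity, 1.0)
})

test_that("shared pieces below min_block are excluded from the core", {
  set.seed(308)
  common1 <- rand_seq(3000, 0.45)
  tiny <- rand_seq(400, 0.45)
  common2 <- rand_seq(3000, 0.45)
  e1 <- replicon("E1", paste0(common1, tiny, common2), role = "ICE")
  # second element lacks the 400-bp piece, carries junk instead
  e2 <- replicon("E2", paste0(common1, rand_seq(2500, 0.45), common2),
                 role = "ICE")
  e3 <- replicon("E3", paste0(common1, tiny, common2), role = "ICE")
  core <- extract_ice_core(list(E1 = e1, E2 = e2, E3 = e3), min_block = 500)
  expect_lte(core$core_length, 6000L + 100L)
  expect_equal(core$n_blocks, 2L)
})

test_that("ICE family core statistics match the implanted truth", {
  fam <- simulate_ice_family(n_elements = 5, backbone_len = 46000,
                             divergence = 0.035, seed = 309)
  core <- extract_ice_core(fam$elements)
  expect_lt(abs(core$core_length - 46000) / 46000, 0.05)
  expect_lt(abs(100 * core$average_identity - 96.5), 0.5)
  truth_sites <- length(unique(unlist(lapply(fam$truth,
                                             function(t) t$snps$pos))))
  expect_lt(abs(core$variable_sites - truth_sites) / truth_sites, 0.05)
})

test_that("element order does not change the core", {
  fam <- simulate_ice_family(n_elements = 3, backbone_len = 20000,
                             divergence = 0.02, seed = 310)
  c1 <- extract_ice_core(fam$elements)
  c2 <- extract_ice_core(rev(fam$elements))
  expect_equal(c1$core_length, c2$core_length)
  expect_equal(c1$variable_sites, c2$variable_sites)
})

test_that("SNP effects follow the genetic code", {
  seqv <- paste0("ATG", "CTT", "GGG", "TAA")   # M L G *
  feats <- tibble::tibble(feature_id = "g1", type = "CDS", start = 0L,
                          end = 12L, strand = "+", gene = "g1", product = NA)
  r <- replicon("chr", paste0(seqv, "AAAA"), feats)
  snps <- tibble::tibble(query_pos = c(5L, 3L, 13L),
                         target_base = c("G", "A", "C"))
  out <- classify_snps(snps, r)
  # CTT -> CTG: Leu -> Leu
  expect_equal(out$effect[1], "synonymous")
  # CTT -> ATT: Leu -> Ile
  expect_equal(out$effect[2], "nonsynonymous")
  expect_equal(out$effect[3], "intergenic")
})

test_that("minus-strand SNP effects are codon aware", {
  orf <- paste0("ATG", "CTT", "TAA")
  seqv <- paste0("GG", mobilomics::revcomp(orf), "GG")
  feats <- tibble::tibble(feature_id = "g1", type = "CDS", start = 2L,
                          end = 11L, strand = "-", gene = "g1", product = NA)
  r <- replicon("chr", seqv, feats)
  # plus-strand position of codon-2 third base (CTT -> CTG on the ORF):
  # ORF offset 5 maps to plus position start + (end-start-1-5) = 2 + 3 = 5
  # plus-strand base there is complement of G = C
  snps <- tibble::tibble(query_pos = 5L, target_base = "C")
  out <- classify_snps(snps, r)
  expect_equal(out$effect, "synonymous")
})
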