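test_that("ANI of a genome with itself is 100 with full coverage", {
  set.seed(201)
  a <- replicon("A", rand_seq(12000, 0.45))
  r <- compute_ani(a, a)
  expect_equal(r$ani, 100.0)
  expect_gte(r$fraction_aligned, 0.99)
})

test_that("ANI tracks the implanted divergence of a strain pair", {
  anc <- generate_ancestor(sim_config(seed = 202, genome_length = 60000))$replicon
  # two strains each at half the divergence: pairwise mismatch ~ 1.7%
  s1 <- derive_strain(anc, snp_rate = 0.017 / 2, seed = 203, id = "S1")$replicon
  s2 <- derive_strain(anc, snp_rate = 0.017 / 2, seed = 204, id = "S2")$replicon
  r <- compute_ani(s1, s2)
  expect_lt(abs(r$ani - 98.3), 0.2)
})

test_that("unrelated sequences recruit no ANI fragments", {
  set.seed(205)
  r <- compute_ani(rand_seq(5000, 0.2), rand_seq(5000, 0.8))
  expect_true(is.na(r$ani) || r$ani < 80)
})

test_that("genomes shorter than one fragment are rejected", {
  expect_error(compute_ani(rand_seq(500, .5), rand_seq(5000, .5)), "fragment")
})

test_that("genospecies clustering is single linkage at the threshold", {
  ani <- tibble::tibble(
    genome_a = c("A", "C", "A", "A", "B", "B"),
    genome_b = c("B", "D", "C", "D", "C", "D"),
    ani = c(96, 97, 80, 80, 80, 80))
  cl <- cluster_genospecies(ani, 95)
  expect_equal(length(unique(cl$genospecies)), 2L)
  expect_equal(cl$genospecies[cl$genome == "A"],
               cl$genospecies[cl$genome == "B"])
  # all pairs above threshold -> one genospecies
  ani$ani <- 96
  expect_equal(length(unique(cluster_genospecies(ani, 95)$genospecies)), 1L)
})

test_that("raising the ANI threshold never merges genospecies", {
  set.seed(206)
  ids <- LETTERS[1:6]
  pairs <- t(utils::combn(ids, 2))
  ani <- tibble::tibble(genome_a = pairs[, 1], genome_b = pairs[, 2],
                        ani = runif(nrow(pairs), 80, 100))
  n_prev <- 0L
  for (thr in c(85, 90, 95, 99)) {
    n <- length(unique(cluster_genospecies(ani, thr)$genospecies))
    expect_gte(n, n_prev)
    n_prev <- n
  }
})

test_that("sharing network counts distinct shared protein pairs", {
  set.seed(207)
  shared <- random_proteins(10, 150, prefix = "s")
  pa <- c(shared, random_proteins(3, 150, prefix = "qa"))
  names(pa) <- paste0("a", seq_along(pa))
  pb <- c(shared, random_proteins(2, 150, prefix = "qb"))
  names(pb) <- paste0("b", seq_along(pb))
  net <- build_sharing_network(list(E1 = pa, E2 = pb))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$weight, 10L)
  # no self loops
  expect_false(any(net$edges$a == net$edges$b))
})

test_that("a chain of sharing forms a single component with singletons kept", {
  set.seed(208)
  sAB <- random_proteins(4, 150, prefix = "ab")
  sBC <- random_proteins(4, 150, prefix = "bc")
  pA <- sAB; names(pA) <- paste0("a", 1:4)
  pB <- c(sAB, sBC); names(pB) <- paste0("b", 1:8)
  pC <- sBC; names(pC) <- paste0("c", 1:4)
  pD <- random_proteins(3, 150, prefix = "d")
  net <- build_sharing_network(list(A = pA, B = pB, C = pC, D = pD))
  comp <- net$components
  expect_equal(comp$component[comp$element == "A"],
               comp$component[comp$element == "C"])
  expect_false(any(net$edges$a == "A" & net$edges$b == "C"))
  expect_equal(length(unique(comp$component)), 2L)  # {A,B,C} and {D}
})

test_that("edge weights are invariant under element relabeling", {
  set.seed(209)
  shared <- random_proteins(5, 150)
  p1 <- shared; names(p1) <- paste0("x", 1:5)
  p2 <- shared; names(p2) <- paste0("y", 1:5)
  n1 <- build_sharing_network(list(M = p1, N = p2))
  n2 <- build_sharing_network(list(N = p2, M = p1))
  expect_equal(sort(n1$edges$weight), sort(n2$edges$weight))
})

test_that("homolog scan counts planted homologs once each", {
  set.seed(210)
  planted <- random_proteins(8, 180, prefix = "h")
  queries <- c(planted, random_proteins(4, 180, prefix = "q"))
  names(queries) <- paste0("q", seq_along(queries))
  target <- c(planted, random_proteins(6, 180, prefix = "t"))
  names(target) <- paste0("t", seq_along(target))
  hs <- homolog_scan(queries, list(chr = target), min_identity = 0.70)
  expect_equal(unname(hs$counts$n_homologs), 8L)
})

test_that("homolog counts are monotone in the identity threshold", {
  set.seed(211)
  planted <- random_proteins(6, 180)
  queries <- planted; names(queries) <- paste0("q", 1:6)
  # degrade half the targets to ~60% identity
  degrade <- function(p, frac) {
    v <- strsplit(p, "")[[1]]
    idx <- sample(length(v), round(frac * length(v)))
    v[idx] <- sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], length(idx),
                     replace = TRUE)
    paste(v, collapse = "")
  }
  target <- c(vapply(planted[1:3], degrade, character(1), frac = 0.4),
              planted[4:6])
  names(target) <- paste0("t", 1:6)
  n50 <- unname(homolog_scan(queries, list(chr = target),
                             min_identity = 0.50)$counts$n_homologs)
  n70 <- unname(homolog_scan(queries, list(chr = target),
                             min_identity = 0.70)$counts$n_homologs)
  expect_gte(n50, n70)
  expect_equal(n70, 3L)
})

test_that("disjoint proteomes share nothing", {
  set.seed(212)
  hs <- homolog_scan(random_proteins(3, 120, prefix = "a"),
                     list(chr = random_proteins(3, 120, prefix = "b")),
                     min_identity = 0.70)
  expect_equal(unname(hs$counts$n_homologs), 0L)
})
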