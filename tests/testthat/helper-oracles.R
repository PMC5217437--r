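# Independent reference implementations used as oracles.
# Plain-R dynamic programming, written from the textbook recurrences; kept
# deliberately separate from the package's C++ kernels.

# Affine-gap global alignment (Gotoh). Returns score and the aligned column
# path as 0-based indices (-1 = gap). Preference order on ties: diagonal,
# then gap-in-a (consuming b), then gap-in-b; gap opening preferred over
# extension on equal score.
oracle_global <- function(a, b, match = 1L, mismatch = -2L, gap_open = 5L,
                          gap_ext = 1L) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  H <- matrix(NEG, n + 1L, m + 1L)
  E <- matrix(NEG, n + 1L, m + 1L)  # gap in a (consumes b)
  F_ <- matrix(NEG, n + 1L, m + 1L) # gap in b (consumes a)
  TH <- matrix(0L, n + 1L, m + 1L)  # 1 diag, 2 E, 3 F
  TE <- matrix(FALSE, n + 1L, m + 1L) # opened from H
  TF <- matrix(FALSE, n + 1L, m + 1L)
  H[1, 1] <- 0
  for (j in seq_len(m)) {
    e1 <- E[1, j] - gap_ext
    e2 <- H[1, j] - gap_open - gap_ext
    E[1, j + 1] <- max(e1, e2)
    TE[1, j + 1] <- e2 >= e1
    H[1, j + 1] <- E[1, j + 1]
    TH[1, j + 1] <- 2L
  }
  for (i in seq_len(n)) {
    f1 <- F_[i, 1] - gap_ext
    f2 <- H[i, 1] - gap_open - gap_ext
    F_[i + 1, 1] <- max(f1, f2)
    TF[i + 1, 1] <- f2 >= f1
    H[i + 1, 1] <- F_[i + 1, 1]
    TH[i + 1, 1] <- 3L
    for (j in seq_len(m)) {
      e1 <- E[i + 1, j] - gap_ext
      e2 <- H[i + 1, j] - gap_open - gap_ext
      e <- max(e1, e2)
      f1 <- F_[i, j + 1] - gap_ext
      f2 <- H[i, j + 1] - gap_open - gap_ext
      f <- max(f1, f2)
      s <- if (av[i] == bv[j] && av[i] %in% c("A", "C", "G", "T")) match else mismatch
      d <- H[i, j] + s
      h <- max(d, e, f)
      E[i + 1, j + 1] <- e
      F_[i + 1, j + 1] <- f
      H[i + 1, j + 1] <- h
      TE[i + 1, j + 1] <- e2 >= e1
      TF[i + 1, j + 1] <- f2 >= f1
      TH[i + 1, j + 1] <- if (d >= e && d >= f) 1L else if (e >= f) 2L else 3L
    }
  }
  qi <- integer(0); ti <- integer(0)
  i <- n; j <- m; st <- 0L
  while (i > 0L || j > 0L) {
    if (st == 0L) {
      src <- TH[i + 1, j + 1]
      if (src == 1L) {
        qi <- c(i - 1L, qi); ti <- c(j - 1L, ti)
        i <- i - 1L; j <- j - 1L
      } else if (src == 2L) st <- 1L else st <- 2L
    } else if (st == 1L) {
      qi <- c(-1L, qi); ti <- c(j - 1L, ti)
      op <- TE[i + 1, j + 1]
      j <- j - 1L
      st <- if (op) 0L else 1L
    } else {
      qi <- c(i - 1L, qi); ti <- c(-1L, ti)
      op <- TF[i + 1, j + 1]
      i <- i - 1L
      st <- if (op) 0L else 2L
    }
  }
  list(score = H[n + 1, m + 1], q_idx = qi, t_idx = ti)
}

# mismatched aligned columns of an oracle path
oracle_snps <- function(a, b, path) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  al <- path$q_idx >= 0L & path$t_idx >= 0L
  qp <- path$q_idx[al]; tp <- path$t_idx[al]
  ok <- av[qp + 1L] %in% c("A", "C", "G", "T") &
    bv[tp + 1L] %in% c("A", "C", "G", "T")
  mism <- ok & av[qp + 1L] != bv[tp + 1L]
  data.frame(query_pos = qp[mism], target_pos = tp[mism])
}

# Smith-Waterman optimal local score (score only)
oracle_sw_score <- function(a, b, match = 1L, mismatch = -2L, gap_open = 5L,
                            gap_ext = 1L) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  Hp <- rep(0, m + 1L)
  Fv <- rep(NEG, m + 1L)
  best <- 0
  for (i in seq_len(n)) {
    Hc <- rep(0, m + 1L)
    e <- NEG
    for (j in seq_len(m)) {
      e <- max(e - gap_ext, Hc[j] - gap_open - gap_ext)
      Fv[j + 1] <- max(Fv[j + 1] - gap_ext, Hp[j + 1] - gap_open - gap_ext)
      s <- if (av[i] == bv[j] && av[i] %in% c("A", "C", "G", "T")) match else mismatch
      h <- max(0, Hp[j] + s, e, Fv[j + 1])
      Hc[j + 1] <- h
      if (h > best) best <- h
    }
    Hp <- Hc
  }
  best
}

# random mutated pair: substitutions plus optional clean indels
mutated_pair <- function(len, n_sub, n_indel = 0L, indel_len = 3L, gc = 0.5) {
  a <- rand_seq(len, gc)
  bv <- strsplit(a, "")[[1]]
  sub_pos <- sample(len, n_sub)
  for (p in sub_pos) bv[p] <- sample(setdiff(c("A", "C", "G", "T"), bv[p]), 1)
  b <- paste(bv, collapse = "")
  if (n_indel > 0L) {
    for (k in seq_len(n_indel)) {
      p <- sample(nchar(b) - indel_len, 1)
      if (runif(1) < 0.5) {
        b <- paste0(substr(b, 1, p), substr(b, p + indel_len + 1, nchar(b)))
      } else {
        b <- paste0(substr(b, 1, p), rand_seq(indel_len, gc),
                    substr(b, p + 1, nchar(b)))
      }
    }
  }
  list(a = a, b = b, sub_pos = sort(sub_pos))
}

# small random protein set built from valid ORF translations
random_proteins <- function(n, n_codons = 200L, gc = 0.45, prefix = "p") {
  pool <- mobilomics:::codon_pool(gc)
  setNames(vapply(seq_len(n), function(i) {
    mobilomics:::translate_cds(mobilomics:::random_orf(n_codons, pool))
  }, character(1)), paste0(prefix, seq_len(n)))
}
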