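#' Codon adaptation index weights from a reference gene set
#'
#' Sharp & Li relative adaptiveness: within each synonymous family the
#' weight of a codon is its reference frequency divided by the family
#' maximum. Codons absent from the reference receive a floor weight of
#' 0.01 and are flagged.
#'
#' @param ref_cds character vector of in-frame CDS sequences.
#' @return tibble: codon, aa, w, floored.
#' @export
cai_weights <- function(ref_cds) {
  gc_tab <- Biostrings::GENETIC_CODE
  counts <- setNames(numeric(length(gc_tab)), names(gc_tab))
  for (s in ref_cds) {
    s <- substr(s, 1L, nchar(s) - nchar(s) %% 3L)
    cods <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    tb <- table(cods)
    ok <- names(tb) %in% names(counts)
    counts[names(tb)[ok]] <- counts[names(tb)[ok]] + as.numeric(tb[ok])
  }
  out <- tibble(codon = names(gc_tab), aa = unname(gc_tab),
                n = unname(counts))
  out <- out |>
    filter(aa != "*") |>
    group_by(aa) |>
    mutate(w = n / max(max(n), 1)) |>
    ungroup()
  out$floored <- out$w < 0.01
  out$w[out$floored] <- 0.01
  out |> select(codon, aa, w, floored)
}

# CAI of one CDS given a weight table; single-codon families excluded
cai_of_gene <- function(cds, wtab) {
  cds <- substr(cds, 1L, nchar(cds) - nchar(cds) %% 3L)
  if (nchar(cds) < 3L) return(NA_real_)
  cods <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  wmap <- setNames(wtab$w, wtab$codon)
  fam_size <- table(wtab$aa)
  multi <- wtab$codon[wtab$aa %in% names(fam_size)[fam_size > 1L]]
  use <- cods %in% multi
  if (!any(use)) return(NA_real_)
  exp(mean(log(wmap[cods[use]])))
}

# windowed k-mer counts for both strands pooled
both_strand_counts <- function(s, width) {
  d <- Biostrings::DNAString(s)
  f <- Biostrings::oligonucleotideFrequency(d, width = width)
  r <- Biostrings::oligonucleotideFrequency(Biostrings::reverseComplement(d),
                                            width = width)
  f + r
}

# tetranucleotide z-scores against an order-2 Markov expectation
tetra_z <- function(n4, n3, n2) {
  tets <- names(n4)
  left <- substr(tets, 1L, 3L)
  right <- substr(tets, 2L, 4L)
  mid <- substr(tets, 2L, 3L)
  e <- ifelse(n2[mid] > 0, n3[left] * n3[right] / n2[mid], 0)
  v <- ifelse(n2[mid] > 0,
              e * ((n2[mid] - n3[left]) * (n2[mid] - n3[right])) / n2[mid]^2,
              0)
  z <- ifelse(v > 0, (as.numeric(n4) - e) / sqrt(v), 0)
  tibble(tetramer = tets, obs = as.numeric(n4), expected = as.numeric(e),
         z = as.numeric(z))
}

#' Composition profile of a replicon
#'
#' GC content and GC skew in windows (wrapping for circular replicons),
#' tetranucleotide z-scores against an order-2 Markov expectation (both
#' strands pooled), codon adaptation index against a reference gene set
#' (default: CDS annotated as ribosomal proteins) and coding density.
#'
#' @param rep a [replicon()].
#' @param window window size in bp (default 5000).
#' @param cai_reference character vector of reference CDS sequences; the
#'   default uses the replicon's features with product matching
#'   "ribosomal protein".
#' @param circular treat the replicon as circular (default TRUE).
#' @return object of class `composition`: list with `gc`, `cai`,
#'   `coding_density`, `windows` (start, end, gc, gc_skew), `tetra`
#'   (z-score tibble), `cai_by_gene`.
#' @export
composition <- function(rep, window = 5000L, cai_reference = NULL,
                        circular = TRUE) {
  stopifnot(is_replicon(rep))
  s <- rep$seq
  L <- nchar(s)
  starts <- seq(0L, max(L - 1L, 0L), by = window)
  wins <- vapply(starts, function(st) {
    en <- st + window
    if (en <= L) subseq0(s, st, en)
    else if (circular) paste0(subseq0(s, st, L), subseq0(s, 0L, en - L))
    else subseq0(s, st, L)
  }, character(1))
  counts <- do.call(rbind, lapply(wins, function(w) {
    Biostrings::letterFrequency(Biostrings::DNAString(w), c("G", "C"))
  }))
  wlen <- nchar(wins)
  gcw <- rowSums(counts) / wlen
  skew <- ifelse(rowSums(counts) > 0,
                 (counts[, "G"] - counts[, "C"]) / rowSums(counts), 0)
  cds <- rep$features[rep$features$type == "CDS", ]
  cdens <- if (nrow(cds) > 0L) {
    sum(interval_union(cds$start, cds$end) |> (\(u) u$end - u$start)()) / L
  } else 0
  ref <- cai_reference
  if (is.null(ref)) {
    ri <- which(grepl("ribosomal protein", cds$product %||% character(0)))
    ref <- vapply(ri, function(i) feature_seq(rep, cds[i, ]), character(1))
  }
  wtab <- if (length(ref) > 0L) cai_weights(ref) else NULL
  cai_gene <- if (!is.null(wtab) && nrow(cds) > 0L) {
    tibble(feature_id = cds$feature_id,
           mid = as.integer((cds$start + cds$end) %/% 2L),
           cai = vapply(seq_len(nrow(cds)), function(i) {
             cai_of_gene(feature_seq(rep, cds[i, ]), wtab)
           }, numeric(1)))
  } else tibble(feature_id = character(), mid = integer(), cai = numeric())
  n4 <- both_strand_counts(s, 4L)
  n3 <- both_strand_counts(s, 3L)
  n2 <- both_strand_counts(s, 2L)
  structure(list(id = rep$id, length = L, gc = gc_content(s),
                 coding_density = cdens,
                 cai = if (nrow(cai_gene)) mean(cai_gene$cai, na.rm = TRUE)
                 else NA_real_,
                 cai_floored = !is.null(wtab) && any(wtab$floored),
                 windows = tibble(start = starts,
                                  end = starts + as.integer(wlen),
                                  gc = gcw, gc_skew = skew),
                 tetra = tetra_z(n4, n3, n2),
                 cai_by_gene = cai_gene),
            class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  cat(sprintf("<composition> %s: GC %.3f, CAI %.3f, coding density %.3f\n",
              x$id, x$gc, x$cai, x$coding_density))
  invisible(x)
}

#' @rdname composition
#' @param x a `composition`.
#' @param ... unused.
#' @method glance composition
#' @export
glance.composition <- function(x, ...) {
  tibble(id = x$id, length = x$length, gc = x$gc, cai = x$cai,
         coding_density = x$coding_density)
}

cosine_dist <- function(a, b) {
  if (all(a == 0) || all(b == 0)) return(NA_real_)
  1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

arc_intervals <- function(b1, b2, L) {
  # two arcs of a circular replicon split at b1 < b2 (0-based)
  list(arc1 = tibble(start = b1, end = b2),
       arc2 = tibble(start = c(b2, 0L), end = c(L, b1)))
}

arc_seq <- function(s, iv) {
  paste(vapply(seq_len(nrow(iv)), function(i) {
    subseq0(s, iv$start[i], iv$end[i])
  }, character(1)), collapse = "")
}

#' Composition contrast between two modules of a replicon
#'
#' Splits a circular replicon at two breakpoints into two arcs and
#' contrasts their composition: |delta GC|, |delta CAI|, |delta coding
#' density| and the cosine distance between tetranucleotide z-score
#' vectors. Significance is assessed by a permutation test that shuffles
#' window (and gene) arc labels.
#'
#' @param rep a [replicon()].
#' @param breakpoints two 0-based coordinates (order irrelevant).
#' @param window window size for the permutation units (default 5000).
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for the permutation test.
#' @param cai_reference optional reference CDS set (default: ribosomal
#'   proteins of the whole replicon).
#' @return object of class `module_contrast`: `contrast` tibble (metric,
#'   arc1, arc2, delta, p_value) plus per-arc summaries.
#' @export
compare_modules <- function(rep, breakpoints, window = 5000L, n_perm = 1000L,
                            seed = 1L, cai_reference = NULL) {
  stopifnot(is_replicon(rep), length(breakpoints) == 2L)
  L <- nchar(rep$seq)
  b1 <- min(breakpoints); b2 <- max(breakpoints)
  stopifnot(b1 >= 0, b2 <= L, b1 < b2)
  arcs <- arc_intervals(as.integer(b1), as.integer(b2), as.integer(L))
  seqs <- lapply(arcs, arc_seq, s = rep$seq)
  # window units: cut each arc into `window`-sized pieces (last piece kept)
  unit_tbl <- bind_rows(lapply(names(arcs), function(an) {
    sarc <- seqs[[an]]
    la <- nchar(sarc)
    st <- seq(0L, max(la - 1L, 0L), by = window)
    en <- pmin(st + window, la)
    tibble(arc = an, seq = substring(sarc, st + 1L, en))
  }))
  N4 <- do.call(rbind, lapply(unit_tbl$seq, both_strand_counts, width = 4L))
  N3 <- do.call(rbind, lapply(unit_tbl$seq, both_strand_counts, width = 3L))
  N2 <- do.call(rbind, lapply(unit_tbl$seq, both_strand_counts, width = 2L))
  unit_gc <- vapply(unit_tbl$seq, gc_content, numeric(1), USE.NAMES = FALSE)
  # coding density per unit: fraction of unit covered by CDS (arc-local)
  cds <- rep$features[rep$features$type == "CDS", ]
  to_arc_pos <- function(pos) {
    # map replicon position to (arc, offset)
    ifelse(pos >= b1 & pos < b2, pos - b1,
           ifelse(pos >= b2, pos - b2, pos + (L - b2)))
  }
  arc_of <- function(pos) ifelse(pos >= b1 & pos < b2, "arc1", "arc2")
  unit_tbl$start_local <- unlist(lapply(names(arcs), function(an) {
    la <- nchar(seqs[[an]])
    seq(0L, max(la - 1L, 0L), by = window)
  }))
  cover <- numeric(nrow(unit_tbl))
  if (nrow(cds) > 0L) {
    mids <- (cds$start + cds$end) %/% 2L
    for (i in seq_len(nrow(cds))) {
      # attribute the CDS to units of its own arc by local coordinates
      an <- arc_of(mids[i])
      lo <- to_arc_pos(cds$start[i]); hi <- lo + (cds$end[i] - cds$start[i])
      sel <- which(unit_tbl$arc == an)
      for (u in sel) {
        us <- unit_tbl$start_local[u]; ue <- us + nchar(unit_tbl$seq[u])
        ov <- max(0, min(hi, ue) - max(lo, us))
        cover[u] <- cover[u] + ov
      }
    }
  }
  unit_tbl$coding <- cover / nchar(unit_tbl$seq)
  unit_tbl$gc <- unit_gc
  unit_tbl$len <- nchar(unit_tbl$seq)
  # CAI per gene with arc label
  comp_all <- composition(rep, window = window, cai_reference = cai_reference)
  cai_gene <- comp_all$cai_by_gene
  cai_gene$arc <- arc_of(cai_gene$mid)
  # observed + permuted deltas
  tet_names <- colnames(N4)
  tet_left <- substr(tet_names, 1L, 3L)
  tet_right <- substr(tet_names, 2L, 4L)
  tet_mid <- substr(tet_names, 2L, 3L)
  tetra_vec <- function(idx) {
    n4 <- colSums(N4[idx, , drop = FALSE])
    n3 <- colSums(N3[idx, , drop = FALSE])
    n2 <- colSums(N2[idx, , drop = FALSE])
    e <- ifelse(n2[tet_mid] > 0, n3[tet_left] * n3[tet_right] / n2[tet_mid], 0)
    v <- ifelse(n2[tet_mid] > 0,
                e * ((n2[tet_mid] - n3[tet_left]) *
                       (n2[tet_mid] - n3[tet_right])) / n2[tet_mid]^2, 0)
    ifelse(v > 0, (n4 - e) / sqrt(v), 0)
  }
  metric_deltas <- function(arc_lab, cai_lab) {
    i1 <- which(arc_lab == "arc1"); i2 <- which(arc_lab == "arc2")
    w1 <- unit_tbl$len[i1]; w2 <- unit_tbl$len[i2]
    gc1 <- sum(unit_tbl$gc[i1] * w1) / sum(w1)
    gc2 <- sum(unit_tbl$gc[i2] * w2) / sum(w2)
    cd1 <- sum(unit_tbl$coding[i1] * w1) / sum(w1)
    cd2 <- sum(unit_tbl$coding[i2] * w2) / sum(w2)
    cai1 <- suppressWarnings(mean(cai_gene$cai[cai_lab == "arc1"], na.rm = TRUE))
    cai2 <- suppressWarnings(mean(cai_gene$cai[cai_lab == "arc2"], na.rm = TRUE))
    c(gc = abs(gc1 - gc2), coding_density = abs(cd1 - cd2),
      cai = abs(cai1 - cai2),
      tetra = cosine_dist(tetra_vec(i1), tetra_vec(i2)))
  }
  obs <- metric_deltas(unit_tbl$arc, cai_gene$arc)
  set.seed(seed)
  n_ge <- setNames(numeric(length(obs)), names(obs))
  for (b in seq_len(n_perm)) {
    perm_arc <- sample(unit_tbl$arc)
    perm_cai <- if (nrow(cai_gene)) sample(cai_gene$arc) else character(0)
    pd <- metric_deltas(perm_arc, perm_cai)
    n_ge <- n_ge + as.numeric(!is.na(pd) & !is.na(obs) & pd >= obs)
  }
  pvals <- ifelse(is.na(obs), NA_real_, (1 + n_ge) / (n_perm + 1))
  contrast <- tibble(metric = names(obs), delta = unname(obs),
                     p_value = unname(pvals))
  structure(list(id = rep$id, breakpoints = c(b1, b2), contrast = contrast,
                 arcs = tibble(arc = c("arc1", "arc2"),
                               length = vapply(seqs, nchar, numeric(1)),
                               gc = vapply(seqs, gc_content, numeric(1))),
                 n_perm = n_perm),
            class = "module_contrast")
}

#' @export
print.module_contrast <- function(x, ...) {
  cat(sprintf("<module_contrast> %s split at %d/%d\n", x$id,
              x$breakpoints[1], x$breakpoints[2]))
  print(as.data.frame(x$contrast))
  invisible(x)
}

#' @rdname compare_modules
#' @param x a `module_contrast`.
#' @param ... unused.
#' @method tidy module_contrast
#' @export
tidy.module_contrast <- function(x, ...) x$contrast
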