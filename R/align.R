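#' Alignment scoring parameters
#'
#' Bundles the scoring scheme shared by all alignment entry points. A gap of
#' length L costs `gap_open + L * gap_ext`. Identity is always computed as
#' matches / alignment columns, gap columns included; ambiguity codes (N, X)
#' never match.
#'
#' @param alphabet "nt" (match/mismatch scoring) or "aa" (BLOSUM62).
#' @param match,mismatch nucleotide scores (ignored for "aa").
#' @param gap_open,gap_ext affine gap penalties (positive numbers).
#' @param k seed k-mer length used when the search space is too large for a
#'   full dynamic-programming matrix.
#' @param band_pad half-width added around a seed diagonal cluster.
#' @param max_candidates number of seed diagonal clusters evaluated per query.
#' @param min_score minimum local alignment score for a reportable hit.
#' @param full_limit matrix-cell budget below which full (unbanded)
#'   Smith-Waterman is used instead of the seeded search.
#' @return a list of class `align_params`.
#' @export
align_params <- function(alphabet = c("nt", "aa"), match = 1L, mismatch = -2L,
                         gap_open = if (alphabet[1] == "aa") 10L else 5L,
                         gap_ext = 1L,
                         k = if (alphabet[1] == "aa") 5L else 13L,
                         band_pad = 24L, max_candidates = 5L,
                         min_score = 15L, full_limit = 2e6) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "nt") {
    syms <- "ACGT"
    submat <- matrix(as.integer(mismatch), 4, 4)
    diag(submat) <- as.integer(match)
    wild <- as.integer(mismatch)
  } else {
    data("BLOSUM62", package = "Biostrings", envir = environment())
    b62 <- get("BLOSUM62", envir = environment())
    letters_aa <- "ARNDCQEGHILKMFPSTWYVBZX*"
    syms_v <- strsplit(letters_aa, "")[[1]]
    submat <- b62[syms_v, syms_v]
    storage.mode(submat) <- "integer"
    syms <- letters_aa
    wild <- -4L
  }
  structure(list(alphabet = alphabet, syms = syms, submat = submat,
                 wild = wild, gap_open = as.integer(gap_open),
                 gap_ext = as.integer(gap_ext), k = as.integer(k),
                 band_pad = as.integer(band_pad),
                 max_candidates = as.integer(max_candidates),
                 min_score = min_score, full_limit = full_limit),
            class = "align_params")
}

# many queries vs one target, forward strand only; returns raw stat matrix
sw_map <- function(queries, target, p) {
  cpp_map_queries(queries, target, p$syms, p$submat, p$wild, p$gap_open,
                  p$gap_ext, p$k, p$band_pad, p$max_candidates, p$full_limit)
}

empty_hits <- function() {
  tibble(query_id = character(), target_id = character(),
         query_start = integer(), query_end = integer(),
         target_start = integer(), target_end = integer(),
         strand = character(), score = numeric(), identity = numeric(),
         query_coverage = numeric())
}

#' Best local alignment between two sequences
#'
#' Seeded, banded Smith-Waterman with affine gaps; for small problems the
#' full matrix is used so the reported score is the exact optimum. For
#' nucleotide input both strands are searched and the better hit reported
#' (coordinates always refer to the forward-strand input).
#'
#' @param query,target sequences (single strings or [replicon()]s).
#' @param alphabet "nt" or "aa".
#' @param params an [align_params()]; defaults to the alphabet's defaults.
#' @param both_strands search the reverse complement of the query too
#'   (nucleotide only).
#' @return a one-row tibble (a pairwise hit) or a zero-row tibble when no
#'   alignment reaches `min_score`.
#' @export
align_local <- function(query, target, alphabet = c("nt", "aa"),
                        params = NULL, both_strands = NULL) {
  alphabet <- match.arg(alphabet)
  p <- params %||% align_params(alphabet)
  qid <- seq_id(query, "query")
  tid <- seq_id(target, "target")
  q <- as_seq(query)
  t <- as_seq(target)
  if (nchar(q) == 0L || nchar(t) == 0L) abort("empty sequence")
  both_strands <- both_strands %||% (alphabet == "nt")
  hits <- list(list(strand = "+", m = sw_map(q, t, p)))
  if (both_strands) {
    hits <- c(hits, list(list(strand = "-", m = sw_map(cpp_revcomp(q), t, p))))
  }
  best <- NULL
  for (h in hits) {
    m <- h$m
    if (m[1, "score"] < 0) next
    if (is.null(best) || m[1, "score"] > best$m[1, "score"]) {
      best <- h
    }
  }
  if (is.null(best) || best$m[1, "score"] < p$min_score) return(empty_hits())
  m <- best$m[1, ]
  qs <- m[["qstart"]]; qe <- m[["qend"]]
  if (best$strand == "-") {
    n <- nchar(q)
    tmp <- qs
    qs <- n - qe
    qe <- n - tmp
  }
  tibble(query_id = qid, target_id = tid,
         query_start = as.integer(qs), query_end = as.integer(qe),
         target_start = as.integer(m[["tstart"]]),
         target_end = as.integer(m[["tend"]]),
         strand = best$strand, score = m[["score"]],
         identity = m[["matches"]] / m[["cols"]],
         query_coverage = (qe - qs) / nchar(q))
}

# ---- whole-genome alignment ------------------------------------------------

# assemble block/snp/indel tables from aligned column chunks
# chunks: list of list(q_idx, t_idx) (0-based, -1 = gap)
collate_alignment <- function(chunks, a, b, merge_gap) {
  araw <- charToRaw(a)
  braw <- charToRaw(b)
  valid_raw <- charToRaw("ACGT")
  blocks <- list(); snps <- list(); indels <- list()
  for (ch in chunks) {
    qi <- ch$q_idx; ti <- ch$t_idx
    nch <- length(qi)
    if (nch == 0L) next
    # column state: 0 = aligned, 1 = gap in query, 2 = gap in target
    state <- integer(nch)
    state[qi < 0L] <- 1L
    state[ti < 0L] <- 2L
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    # indels: one record per gap run; position = coordinate after the last
    # consumed base on the gapped side (0 at chunk start)
    gap_idx <- which(r$values != 0L)
    if (length(gap_idx) > 0L) {
      side <- ifelse(r$values[gap_idx] == 1L, "query", "target")
      i0 <- starts[gap_idx]; i1 <- ends[gap_idx]
      prev_q <- ifelse(i0 > 1L, qi[pmax(i0 - 1L, 1L)], -1L)
      prev_t <- ifelse(i0 > 1L, ti[pmax(i0 - 1L, 1L)], -1L)
      indels[[length(indels) + 1L]] <- tibble(
        side = side,
        query_pos = as.integer(ifelse(side == "query", prev_q + 1L, qi[i0])),
        target_pos = as.integer(ifelse(side == "target", prev_t + 1L, ti[i0])),
        length = i1 - i0 + 1L)
    }
    # SNPs and per-column matches over aligned columns
    match_col <- logical(nch)
    ai <- which(state == 0L)
    if (length(ai) > 0L) {
      qa <- araw[qi[ai] + 1L]
      tb_ <- braw[ti[ai] + 1L]
      ok <- (qa %in% valid_raw) & (tb_ %in% valid_raw)
      mism <- ok & (qa != tb_)
      if (any(mism)) {
        w <- ai[mism]
        snps[[length(snps) + 1L]] <- tibble(
          query_pos = qi[w], target_pos = ti[w],
          query_base = rawToChar(araw[qi[w] + 1L], multiple = TRUE),
          target_base = rawToChar(braw[ti[w] + 1L], multiple = TRUE))
      }
      match_col[ai] <- ok & (qa == tb_)
    }
    # blocks: aligned runs, merged across gap runs shorter than merge_gap
    al <- which(r$values == 0L)
    if (length(al) > 0L) {
      grp <- integer(length(al))
      g <- 1L
      grp[1] <- g
      if (length(al) > 1L) {
        for (i in 2:length(al)) {
          sep <- starts[al[i]] - ends[al[i - 1L]] - 1L
          if (sep >= merge_gap) g <- g + 1L
          grp[i] <- g
        }
      }
      cmatch <- cumsum(match_col)
      for (gg in unique(grp)) {
        runs <- al[grp == gg]
        i0 <- starts[runs[1]]; i1 <- ends[runs[length(runs)]]
        cols <- i1 - i0 + 1L
        nmatch <- cmatch[i1] - (if (i0 > 1L) cmatch[i0 - 1L] else 0L)
        blocks[[length(blocks) + 1L]] <- tibble(
          query_start = qi[i0], query_end = qi[i1] + 1L,
          target_start = ti[i0], target_end = ti[i1] + 1L,
          cols = cols, matches = as.integer(nmatch),
          identity = nmatch / cols)
      }
    }
  }
  list(blocks = if (length(blocks)) bind_rows(blocks) else
         tibble(query_start = integer(), query_end = integer(),
                target_start = integer(), target_end = integer(),
                cols = integer(), matches = integer(), identity = numeric()),
       snps = if (length(snps)) bind_rows(snps) else
         tibble(query_pos = integer(), target_pos = integer(),
                query_base = character(), target_base = character()),
       indels = if (length(indels)) bind_rows(indels) else
         tibble(side = character(), query_pos = integer(),
                target_pos = integer(), length = integer()))
}

#' Anchor-chained whole-genome alignment with SNP and indel calling
#'
#' Finds maximal exact matches unique in both sequences (MUM-like anchors) of
#' at least `min_anchor` bp, chains them collinearly, closes inter-anchor
#' gaps by full affine-gap global alignment, and reports homologous blocks,
#' SNPs, indels and unaligned intervals. Gap pairs whose global alignment
#' score is not positive are treated as presence/absence differences
#' (unaligned on both sides) rather than force-aligned. Small inputs skip
#' anchoring and are aligned by a single full dynamic-programming pass.
#'
#' @param a,b sequences or [replicon()]s (a is the "query"/reference side).
#' @param min_anchor minimum anchor length, >= 12 (default 20).
#' @param merge_gap adjacent aligned runs separated by fewer than this many
#'   gap columns are reported as one block (default 90).
#' @param params nucleotide [align_params()] for gap closure.
#' @param max_dp_cells matrix budget for the single-pass route.
#' @param gap_dp_cells matrix budget for closing one inter-anchor gap;
#'   larger gap pairs are left unaligned.
#' @return an object of class `genome_alignment` with elements `blocks`,
#'   `snps`, `indels`, `unaligned_query`, `unaligned_target`.
#' @export
align_genomes <- function(a, b, min_anchor = 20L, merge_gap = 90L,
                          params = NULL, max_dp_cells = 4.5e6,
                          gap_dp_cells = 2.5e7) {
  if (min_anchor < 12L) abort("min_anchor must be >= 12")
  p <- params %||% align_params("nt")
  qid <- seq_id(a, "a"); tid <- seq_id(b, "b")
  a <- as_seq(a); b <- as_seq(b)
  na <- nchar(a); nb <- nchar(b)
  gdp <- function(x, y) {
    cpp_global_align(x, y, p$syms, p$submat, p$wild, p$gap_open, p$gap_ext)
  }
  chunks <- list()
  if (as.numeric(na + 1) * (nb + 1) <= max_dp_cells) {
    g <- gdp(a, b)
    if (g$score > 0) chunks[[1]] <- g
  } else {
    anchors <- cpp_find_anchors(a, b, as.integer(min_anchor))
    if (nrow(anchors) > 0L) {
      chain <- cpp_chain_anchors(anchors, 128L)
      anc <- anchors[chain, , drop = FALSE]
      cur_q <- integer(0); cur_t <- integer(0)
      qpos <- 0L; tpos <- 0L
      flush <- function() {
        if (length(cur_q)) {
          chunks[[length(chunks) + 1L]] <<- list(q_idx = cur_q, t_idx = cur_t)
          cur_q <<- integer(0); cur_t <<- integer(0)
        }
      }
      close_gap <- function(q0, q1, t0, t1) {
        ga <- q1 - q0; gb <- t1 - t0
        if (ga == 0L && gb == 0L) return(invisible())
        if (ga == 0L || gb == 0L) {
          qidx <- if (ga > 0L) q0:(q1 - 1L) else rep(-1L, gb)
          tidx <- if (gb > 0L) t0:(t1 - 1L) else rep(-1L, ga)
          cur_q <<- c(cur_q, qidx); cur_t <<- c(cur_t, tidx)
          return(invisible())
        }
        if (as.numeric(ga + 1) * (gb + 1) <= gap_dp_cells) {
          g <- gdp(subseq0(a, q0, q1), subseq0(b, t0, t1))
          # large gap pairs that align with non-positive score are
          # presence/absence differences (VR material), not homology;
          # small gaps (SNP/indel scale) are always incorporated
          if (g$score > 0 || min(ga, gb) < 200L) {
            qi <- g$q_idx; ti <- g$t_idx
            qi[qi >= 0L] <- qi[qi >= 0L] + q0
            ti[ti >= 0L] <- ti[ti >= 0L] + t0
            cur_q <<- c(cur_q, qi); cur_t <<- c(cur_t, ti)
            return(invisible())
          }
        }
        flush()  # unaligned on both sides; reported via block complement
      }
      for (i in seq_len(nrow(anc))) {
        a0 <- anc[i, 1]; b0 <- anc[i, 2]; len <- anc[i, 3]
        # trim any overlap with the previously emitted region (anchors in a
        # chain may overlap by a few bases from chance extensions)
        trim <- max(0L, qpos - a0, tpos - b0)
        a0 <- a0 + trim; b0 <- b0 + trim; len <- len - trim
        if (len <= 0L) next
        close_gap(qpos, a0, tpos, b0)
        cur_q <- c(cur_q, a0:(a0 + len - 1L))
        cur_t <- c(cur_t, b0:(b0 + len - 1L))
        qpos <- a0 + len
        tpos <- b0 + len
      }
      close_gap(qpos, na, tpos, nb)
      flush()
    }
  }
  parts <- collate_alignment(chunks, a, b, merge_gap)
  uq <- interval_complement(parts$blocks$query_start, parts$blocks$query_end, na)
  ut <- interval_complement(parts$blocks$target_start, parts$blocks$target_end, nb)
  structure(list(query_id = qid, target_id = tid, query_len = na,
                 target_len = nb, blocks = parts$blocks, snps = parts$snps,
                 indels = parts$indels,
                 unaligned_query = mutate(uq, length = end - start),
                 unaligned_target = mutate(ut, length = end - start)),
            class = "genome_alignment")
}

#' @export
print.genome_alignment <- function(x, ...) {
  cat(sprintf("<genome_alignment> %s vs %s: %d blocks, %d SNPs, %d indels\n",
              x$query_id, x$target_id, nrow(x$blocks), nrow(x$snps),
              nrow(x$indels)))
  invisible(x)
}

#' Length-weighted average identity of an alignment
#'
#' @param x a `genome_alignment` (or its `blocks` tibble).
#' @return a list with `average_identity` (fraction) and `aligned_length`
#'   (alignment columns).
#' @export
average_identity <- function(x) {
  blocks <- if (inherits(x, "genome_alignment")) x$blocks else x
  if (nrow(blocks) == 0L) abort("no homology between the sequences")
  list(average_identity = sum(blocks$identity * blocks$cols) / sum(blocks$cols),
       aligned_length = sum(blocks$cols))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname align_genomes
#' @param x a `genome_alignment`.
#' @param ... unused.
#' @method tidy genome_alignment
#' @export
tidy.genome_alignment <- function(x, ...) {
  mutate(x$blocks, query_id = x$query_id, target_id = x$target_id,
         .before = 1)
}

#' @rdname align_genomes
#' @method glance genome_alignment
#' @export
glance.genome_alignment <- function(x, ...) {
  ai <- if (nrow(x$blocks)) average_identity(x) else
    list(average_identity = NA_real_, aligned_length = 0L)
  tibble(query_id = x$query_id, target_id = x$target_id,
         n_blocks = nrow(x$blocks), n_snps = nrow(x$snps),
         n_indels = nrow(x$indels),
         aligned_length = ai$aligned_length,
         average_identity = ai$average_identity)
}
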