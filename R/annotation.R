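#' Marker rule tables
#'
#' Rule-based marker detection drives mobility classification, the
#' toxin-antitoxin (TA) and restriction-modification (RM) inventories and
#' the chromid diagnosis. A rule table is a tibble with columns:
#' `category` (MOB, MPF, TA_toxin, TA_antitoxin, RM_REase, RM_MTase,
#' essential_single_copy), `family` (e.g. relBE, HipAB, MazFE, vapBC,
#' parED; TypeI-TypeIV for RM), `field` ("gene" or "product"),
#' `pattern` (regex on that field), `exemplar` (optional protein sequence),
#' `min_identity` (for exemplar matching) and `required` (MPF completeness).
#' The shipped default covers the five canonical TA families, RM Types
#' I-IV, a 12-gene MPF (T4SS) set, three relaxase families and the
#' essential single-copy markers used for chromid calling.
#'
#' @param path path to a tab-separated rule table; "." means NA.
#' @return a tibble rule table.
#' @export
read_marker_rules <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = ".")
  need <- c("category", "family", "field", "pattern")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste("rule table lacks columns:", paste(missing, collapse = ", ")))
  }
  if (!"exemplar" %in% names(df)) df$exemplar <- NA_character_
  if (!"min_identity" %in% names(df)) df$min_identity <- NA_real_
  if (!"required" %in% names(df)) df$required <- NA
  df$required <- as.logical(df$required)
  as_tibble(df)
}

#' @rdname read_marker_rules
#' @export
default_marker_rules <- function() {
  read_marker_rules(system.file("extdata", "marker_rules.tsv",
                                package = "mobilomics"))
}

# features of `element` matching one rule row (regex or exemplar mode)
rule_matches <- function(element, rule, prots = NULL, params = NULL) {
  f <- element$features
  if (!is.na(rule$pattern) && nzchar(rule$pattern)) {
    field <- f[[rule$field %||% "gene"]]
    hit <- !is.na(field) & grepl(rule$pattern, field)
    return(f$feature_id[hit])
  }
  if (!is.na(rule$exemplar)) {
    p <- params %||% align_params("aa")
    prots <- prots %||% proteome(element)
    if (length(prots) == 0L) return(character(0))
    m <- sw_map(prots, rule$exemplar, p)
    idn <- m[, "matches"] / pmax(m[, "cols"], 1)
    cov <- (m[, "qend"] - m[, "qstart"]) / nchar(prots)
    hit <- m[, "score"] >= p$min_score &
      idn >= (rule$min_identity %||% 0.5) & cov >= 0.5
    return(names(prots)[hit])
  }
  character(0)
}

#' Classify the mobility of a conjugative element
#'
#' Rule-based MOB/MPF logic: `C` (conjugative) requires a relaxase (any MOB
#' rule) plus the complete required MPF (T4SS) gene set; `MB` (mobilizable)
#' a relaxase with an incomplete T4SS; `NMB` (non-mobilizable) no relaxase.
#' The call depends only on marker presence, never on feature order.
#'
#' @param element a [replicon()] with features.
#' @param rules a marker rule table ([default_marker_rules()]).
#' @return a one-row tibble: element, class, mob_present, mpf_completeness,
#'   n_mpf_present, n_mpf_required; the per-rule presence map is attached as
#'   attribute "evidence".
#' @export
classify_mobility <- function(element, rules = default_marker_rules()) {
  stopifnot(is_replicon(element))
  mob_rules <- rules[rules$category == "MOB", ]
  mpf_rules <- rules[rules$category == "MPF", ]
  if (nrow(mob_rules) < 1L || nrow(mpf_rules) < 8L) {
    abort("rule table needs at least one MOB and eight MPF rows")
  }
  prots <- NULL
  present <- function(rule_df) {
    vapply(seq_len(nrow(rule_df)), function(i) {
      length(rule_matches(element, rule_df[i, ], prots)) > 0L
    }, logical(1))
  }
  mob_p <- present(mob_rules)
  mpf_p <- present(mpf_rules)
  req <- mpf_rules$required %in% TRUE
  n_req <- sum(req)
  completeness <- if (n_req > 0L) mean(mpf_p[req]) else 0
  mob <- any(mob_p)
  class <- if (mob && completeness == 1) "C" else if (mob) "MB" else "NMB"
  out <- tibble(element = element$id, class = class, mob_present = mob,
                mpf_completeness = completeness,
                n_mpf_present = sum(mpf_p[req]), n_mpf_required = n_req)
  attr(out, "evidence") <- tibble(
    category = c(mob_rules$category, mpf_rules$category),
    family = c(mob_rules$family, mpf_rules$family),
    pattern = c(mob_rules$pattern, mpf_rules$pattern),
    present = c(mob_p, mpf_p))
  out
}

# ---- CRISPR ----------------------------------------------------------------

#' Detect CRISPR arrays
#'
#' Finds chains of at least `min_repeats` near-identical direct repeats
#' separated by regularly sized spacers. Candidate arrays are seeded by
#' 8-mers recurring at CRISPR-like periods, repeat boundaries are grown by
#' column consensus (each repeat unit may diverge from the consensus by at
#' most `max_repeat_mismatch` bases; imperfect terminal columns are
#' trimmed), and overlapping candidates are resolved by most repeats, then
#' leftmost.
#'
#' @param x sequence or [replicon()].
#' @param min_repeats minimum number of repeats (default 3).
#' @param repeat_len_range allowed repeat length in bp (default 23-55).
#' @param max_repeat_mismatch per-repeat mismatch budget against the
#'   consensus (default 1).
#' @return tibble with one row per array: start, end, n_repeats,
#'   repeat_consensus, and a list-column `spacers`.
#' @export
detect_crispr <- function(x, min_repeats = 3L, repeat_len_range = c(23L, 55L),
                          max_repeat_mismatch = 1L) {
  s <- as_seq(x)
  L <- nchar(s)
  empty <- tibble(start = integer(), end = integer(), n_repeats = integer(),
                  repeat_consensus = character(), spacers = list())
  if (L < repeat_len_range[1] * min_repeats) return(empty)
  kseed <- 8L
  min_period <- repeat_len_range[1] + ceiling(0.6 * repeat_len_range[1])
  max_period <- repeat_len_range[2] + ceiling(2.5 * repeat_len_range[2])
  kmers <- substring(s, 1:(L - kseed + 1L), kseed:L)
  occ <- split(seq_len(L - kseed + 1L), kmers)
  occ <- occ[lengths(occ) >= min_repeats & lengths(occ) <= 100L]
  cands <- list()
  for (pos in occ) {
    d <- diff(pos)
    okd <- d >= min_period & d <= max_period
    if (!any(okd)) next
    r <- rle(okd)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (ri in which(r$values & r$lengths >= min_repeats - 1L)) {
      units <- pos[starts[ri]:(ends[ri] + 1L)]
      cands[[length(cands) + 1L]] <- units
    }
  }
  if (length(cands) == 0L) return(empty)
  ord <- order(-lengths(cands), vapply(cands, min, numeric(1)))
  cands <- cands[ord]
  chars <- strsplit(s, "")[[1]]
  masked <- logical(L)
  arrays <- list()
  for (units in cands) {
    if (any(masked[units])) next
    n <- length(units)
    need <- max(n - 1L, ceiling(0.75 * n))
    budget <- rep(max_repeat_mismatch, n)
    grow <- function(offsets, budget) {
      # offsets: current repeat interval relative to seed start (c(lo, hi))
      repeat {
        cand_cols <- c(offsets[1] - 1L, offsets[2] + 1L)
        grew <- FALSE
        for (side in 1:2) {
          o <- cand_cols[side]
          width <- offsets[2] - offsets[1] + 1L
          if (width >= repeat_len_range[2]) break
          idx <- units + o
          if (any(idx < 1L | idx > L)) next
          col <- chars[idx]
          tabc <- sort(table(col), decreasing = TRUE)
          if (length(tabc) > 1L && tabc[1] == tabc[2]) next
          cons <- names(tabc)[1]
          agree <- col == cons
          if (sum(agree) < need) next
          nb <- budget - as.integer(!agree)
          if (any(nb < 0L)) next
          budget <- nb
          if (side == 1L) offsets[1] <- o else offsets[2] <- o
          grew <- TRUE
        }
        if (!grew) break
      }
      list(offsets = offsets, budget = budget)
    }
    g <- grow(c(0L, kseed - 1L), budget)
    lo <- g$offsets[1]; hi <- g$offsets[2]
    # trim terminal columns where any unit disagrees with the consensus
    col_perfect <- function(o) {
      col <- chars[units + o]
      length(unique(col)) == 1L
    }
    while (hi - lo + 1L > kseed && !col_perfect(lo)) lo <- lo + 1L
    while (hi - lo + 1L > kseed && !col_perfect(hi)) hi <- hi - 1L
    rlen <- hi - lo + 1L
    if (rlen < repeat_len_range[1] || rlen > repeat_len_range[2]) next
    rstarts <- units + lo
    spacer_lens <- diff(rstarts) - rlen
    if (any(spacer_lens < 0.6 * rlen | spacer_lens > 2.5 * rlen)) next
    med <- median(spacer_lens)
    if (any(abs(spacer_lens - med) > 0.25 * med)) next
    cons <- vapply(lo:hi, function(o) {
      tabc <- sort(table(chars[units + o]), decreasing = TRUE)
      names(tabc)[1]
    }, character(1))
    a_start <- rstarts[1] - 1L           # 0-based
    a_end <- rstarts[n] - 1L + rlen
    spacers <- vapply(seq_len(n - 1L), function(i) {
      substr(s, rstarts[i] + rlen, rstarts[i + 1L] - 1L)
    }, character(1))
    masked[(a_start + 1L):a_end] <- TRUE
    arrays[[length(arrays) + 1L]] <- tibble(
      start = a_start, end = a_end, n_repeats = n,
      repeat_consensus = paste(cons, collapse = ""),
      spacers = list(spacers))
  }
  if (length(arrays) == 0L) return(empty)
  bind_rows(arrays) |> arrange(start)
}

#' Match CRISPR spacers against target sequences
#'
#' Best hit per spacer per target over both strands; a match must reach
#' `min_identity` and, when `require_full_length`, cover the whole spacer.
#'
#' @param spacers named (or unnamed) character vector of spacer sequences.
#' @param targets named list of sequences or [replicon()]s.
#' @param min_identity identity threshold (default 0.93).
#' @param require_full_length require the full spacer aligned.
#' @param params nucleotide [align_params()]; defaults to a short-query
#'   parameterisation.
#' @return tibble: spacer_id, target, identity, strand, target_start,
#'   target_end.
#' @export
match_spacers <- function(spacers, targets, min_identity = 0.93,
                          require_full_length = TRUE, params = NULL) {
  p <- params %||% align_params("nt", k = 7L, min_score = 10L)
  if (is.null(names(spacers))) {
    names(spacers) <- sprintf("spacer%d", seq_along(spacers))
  }
  if (is_replicon(targets)) targets <- list(targets)
  if (is.null(names(targets))) {
    names(targets) <- vapply(seq_along(targets), function(i) {
      seq_id(targets[[i]], paste0("target", i))
    }, character(1))
  }
  rows <- list()
  for (tn in names(targets)) {
    tseq <- as_seq(targets[[tn]])
    for (sn in names(spacers)) {
      h <- align_local(setNames(spacers[[sn]], sn), setNames(tseq, tn),
                       "nt", params = p)
      if (nrow(h) == 0L) next
      if (h$identity < min_identity) next
      if (require_full_length && h$query_coverage < 1) next
      rows[[length(rows) + 1L]] <- tibble(
        spacer_id = sn, target = tn, identity = h$identity,
        strand = h$strand, target_start = h$target_start,
        target_end = h$target_end)
    }
  }
  if (length(rows) == 0L) {
    return(tibble(spacer_id = character(), target = character(),
                  identity = numeric(), strand = character(),
                  target_start = integer(), target_end = integer()))
  }
  bind_rows(rows)
}

# ---- TA / RM ---------------------------------------------------------------

#' Inventory toxin-antitoxin and restriction-modification systems
#'
#' A TA locus is a toxin and an antitoxin of the same family on the same
#' strand within `max_pair_gap` bp (the bicistron rule). An RM system is a
#' REase + MTase pair of the same type within `max_rm_gap` bp (complete) or
#' a lone member (incomplete, reported with its surviving component).
#'
#' @param element a [replicon()].
#' @param rules a marker rule table.
#' @param max_pair_gap maximum toxin/antitoxin separation in bp (default 500).
#' @param max_rm_gap maximum REase/MTase separation in bp (default 3000).
#' @return list with tibbles `ta` (family, toxin_id, antitoxin_id, gap) and
#'   `rm` (type, status, rease_id, mtase_id, component).
#' @export
scan_ta_rm <- function(element, rules = default_marker_rules(),
                       max_pair_gap = 500L, max_rm_gap = 3000L) {
  stopifnot(is_replicon(element))
  f <- element$features
  find_cat <- function(cat) {
    sub <- rules[rules$category == cat, ]
    out <- list()
    for (i in seq_len(nrow(sub))) {
      ids <- rule_matches(element, sub[i, ])
      if (length(ids)) {
        out[[length(out) + 1L]] <- tibble(family = sub$family[i],
                                          feature_id = ids)
      }
    }
    if (length(out)) bind_rows(out) else
      tibble(family = character(), feature_id = character())
  }
  gap_between <- function(id1, id2) {
    r1 <- f[f$feature_id == id1, ]; r2 <- f[f$feature_id == id2, ]
    max(0L, max(r1$start, r2$start) - min(r1$end, r2$end))
  }
  same_strand <- function(id1, id2) {
    f$strand[f$feature_id == id1] == f$strand[f$feature_id == id2]
  }
  pair_up <- function(first, second, max_gap, strand_rule = TRUE) {
    pairs <- list(); lone_first <- character(0)
    used <- character(0)
    for (i in seq_len(nrow(first))) {
      cand <- second[second$family == first$family[i] &
                       !second$feature_id %in% used, ]
      if (nrow(cand) > 0L) {
        gaps <- vapply(cand$feature_id, gap_between, numeric(1),
                       id1 = first$feature_id[i])
        okst <- if (strand_rule) {
          vapply(cand$feature_id, same_strand, logical(1),
                 id1 = first$feature_id[i])
        } else rep(TRUE, nrow(cand))
        ok <- gaps <= max_gap & okst
        if (any(ok)) {
          j <- which(ok)[which.min(gaps[ok])]
          pairs[[length(pairs) + 1L]] <- tibble(
            family = first$family[i], a_id = first$feature_id[i],
            b_id = cand$feature_id[j], gap = as.integer(gaps[j]))
          used <- c(used, cand$feature_id[j])
          next
        }
      }
      lone_first <- c(lone_first, first$feature_id[i])
    }
    list(pairs = if (length(pairs)) bind_rows(pairs) else
           tibble(family = character(), a_id = character(),
                  b_id = character(), gap = integer()),
         lone_first = lone_first,
         lone_second = setdiff(second$feature_id, used))
  }
  tox <- find_cat("TA_toxin"); anti <- find_cat("TA_antitoxin")
  ta <- pair_up(tox, anti, max_pair_gap)
  ta_tbl <- ta$pairs |> rename(toxin_id = a_id, antitoxin_id = b_id)
  re <- find_cat("RM_REase"); mt <- find_cat("RM_MTase")
  rm_ <- pair_up(re, mt, max_rm_gap, strand_rule = FALSE)
  rm_complete <- rm_$pairs |> rename(rease_id = a_id, mtase_id = b_id)
  rm_tbl <- bind_rows(
    if (nrow(rm_complete)) mutate(rm_complete, status = "complete",
                                  component = NA_character_) else NULL,
    if (length(rm_$lone_first)) tibble(
      family = re$family[match(rm_$lone_first, re$feature_id)],
      rease_id = rm_$lone_first, mtase_id = NA_character_, gap = NA_integer_,
      status = "incomplete", component = "REase") else NULL,
    if (length(rm_$lone_second)) tibble(
      family = mt$family[match(rm_$lone_second, mt$feature_id)],
      rease_id = NA_character_, mtase_id = rm_$lone_second, gap = NA_integer_,
      status = "incomplete", component = "MTase") else NULL)
  if (is.null(rm_tbl) || nrow(rm_tbl) == 0L) {
    rm_tbl <- tibble(family = character(), rease_id = character(),
                     mtase_id = character(), gap = integer(),
                     status = character(), component = character())
  }
  list(ta = ta_tbl, rm = rename(rm_tbl, type = family))
}

# ---- tRNA island hallmark --------------------------------------------------

#' Detect duplicated tRNA 3'-ends (single-integration hallmark)
#'
#' For each tRNA feature, searches the downstream window for an exact copy
#' of the tRNA's 3'-terminal k bases (k swept over `k_range`) and reports
#' the farthest copy; the implied island spans from the tRNA end to the end
#' of the duplicated fragment.
#'
#' @param region a [replicon()] with tRNA features.
#' @param k_range range of duplicated-fragment lengths tried (default
#'   10-30).
#' @param max_distance how far downstream to search (default 50 kb).
#' @return tibble: trna_id, k, dup_start, dup_end, island_start, island_end.
#' @export
detect_trna_duplication <- function(region, k_range = c(10L, 30L),
                                    max_distance = 50000L) {
  stopifnot(is_replicon(region))
  s <- region$seq
  L <- nchar(s)
  trnas <- region$features[region$features$type == "tRNA", ]
  rows <- list()
  for (i in seq_len(nrow(trnas))) {
    row <- trnas[i, ]
    win_end <- min(L, row$end + max_distance)
    win <- subseq0(s, row$end, win_end)
    best <- NULL
    # anchor on the 3'-terminal k_min-mer, extend each downstream copy
    # leftward as far as it still matches the tRNA end; copies within 2 bp
    # of the best extension are hallmark candidates, farthest one wins
    kmin <- k_range[1]; kmax <- k_range[2]
    if (row$end - kmin >= row$start) {
      pat <- subseq0(s, row$end - kmin, row$end)
      m <- gregexpr(pat, win, fixed = TRUE)[[1]]
      if (m[1] != -1L) {
        cand_end <- row$end + as.integer(m) - 1L + kmin  # 0-based ends
        ext <- vapply(cand_end, function(en) {
          k <- kmin
          while (k < kmax && en - k - 1L >= row$end &&
                 row$end - k - 1L >= row$start &&
                 substr(s, en - k, en - k) ==
                   substr(s, row$end - k, row$end - k)) {
            k <- k + 1L
          }
          k
        }, integer(1))
        keep <- ext >= max(kmin, max(ext) - 2L)
        far <- which(keep)[which.max(cand_end[keep])]
        best <- list(k = ext[far], dup_start = cand_end[far] - ext[far],
                     dup_end = cand_end[far])
      }
    }
    if (!is.null(best)) {
      rows[[length(rows) + 1L]] <- tibble(
        trna_id = row$feature_id, k = best$k,
        dup_start = best$dup_start, dup_end = best$dup_end,
        island_start = row$end, island_end = best$dup_end)
    }
  }
  if (length(rows) == 0L) {
    return(tibble(trna_id = character(), k = integer(), dup_start = integer(),
                  dup_end = integer(), island_start = integer(),
                  island_end = integer()))
  }
  bind_rows(rows)
}

# ---- chromid diagnosis -----------------------------------------------------

#' Diagnose a megaplasmid as a chromid
#'
#' A chromid is a very large plasmid with chromosome-like cargo: essential
#' single-copy markers and functionally redundant tRNAs (isoacceptors
#' already encoded on the chromosome). The verdict is "chromid" when at
#' least `marker_threshold` essential markers are found on the plasmid and
#' at least one redundant tRNA is present.
#'
#' @param plasmid,chromosome [replicon()]s.
#' @param rules a marker rule table (essential_single_copy rows).
#' @param marker_threshold minimum essential markers (default 3).
#' @return one-row tibble: plasmid, n_markers, markers, n_trnas,
#'   n_redundant_trnas, trna_redundant, size_ratio, verdict.
#' @export
diagnose_chromid <- function(plasmid, chromosome,
                             rules = default_marker_rules(),
                             marker_threshold = 3L) {
  stopifnot(is_replicon(plasmid), is_replicon(chromosome))
  ess <- rules[rules$category == "essential_single_copy", ]
  found <- character(0)
  for (i in seq_len(nrow(ess))) {
    if (length(rule_matches(plasmid, ess[i, ])) > 0L) {
      found <- c(found, ess$family[i])
    }
  }
  p_trna <- plasmid$features[plasmid$features$type == "tRNA", ]
  c_trna <- chromosome$features[chromosome$features$type == "tRNA", ]
  redundant <- p_trna$gene[p_trna$gene %in% c_trna$gene]
  verdict <- length(found) >= marker_threshold && length(redundant) >= 1L
  ratio <- nchar(plasmid$seq) / nchar(chromosome$seq)
  tibble(plasmid = plasmid$id, n_markers = length(found),
         markers = paste(found, collapse = ","),
         n_trnas = nrow(p_trna),
         n_redundant_trnas = length(redundant),
         trna_redundant = length(redundant) >= 1L,
         size_ratio = ratio,
         verdict = if (verdict) "chromid" else "plasmid")
}
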