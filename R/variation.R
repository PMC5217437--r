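#' Windowed SNP profile along a reference
#'
#' Assigns the SNPs of a genome alignment to consecutive non-overlapping
#' windows on the reference (query) coordinate system. Windows with no
#' aligned coverage are reported as `NA`, not zero.
#'
#' @param aln a `genome_alignment` from [align_genomes()].
#' @param window window size in bp (default 1000).
#' @return tibble: window_start, window_end, covered, n_snps (NA where not
#'   covered).
#' @export
snp_windows <- function(aln, window = 1000L) {
  stopifnot(inherits(aln, "genome_alignment"))
  L <- aln$query_len
  starts <- seq(0L, max(L - 1L, 0L), by = window)
  ends <- pmin(starts + window, L)
  n <- integer(length(starts))
  if (nrow(aln$snps) > 0L) {
    idx <- findInterval(aln$snps$query_pos, starts)
    tab <- table(idx)
    n[as.integer(names(tab))] <- as.integer(tab)
  }
  covered <- vapply(seq_along(starts), function(i) {
    any(aln$blocks$query_start < ends[i] & aln$blocks$query_end > starts[i])
  }, logical(1))
  tibble(window_start = starts, window_end = ends, covered = covered,
         n_snps = ifelse(covered, n, NA_integer_))
}

#' Detect variable regions (presence/absence differences)
#'
#' A variable region (VR) is a maximal interval of at least `min_vr` bp on
#' either sequence with no aligned block — the signature of a cargo
#' cassette, island or deletion. Unaligned intervals separated by fewer
#' than `merge_within` aligned bp are merged first.
#'
#' @param aln a `genome_alignment`.
#' @param min_vr minimum VR length in bp (default 2000).
#' @param merge_within merge unaligned intervals separated by fewer aligned
#'   bp than this (default 200).
#' @return tibble: side ("query"/"target"), start, end, length.
#' @export
detect_variable_regions <- function(aln, min_vr = 2000L, merge_within = 200L) {
  stopifnot(inherits(aln, "genome_alignment"))
  one_side <- function(un, side) {
    if (nrow(un) == 0L) {
      return(tibble(side = character(), start = integer(), end = integer(),
                    length = integer()))
    }
    un <- arrange(un, start)
    grp <- cumsum(c(1L, diff(un$start) > 0) * 0L + c(1L, (un$start[-1L] -
      un$end[-nrow(un)]) >= merge_within))
    merged <- un |>
      mutate(grp = grp) |>
      group_by(grp) |>
      summarise(start = min(start), end = max(end), .groups = "drop") |>
      mutate(length = end - start) |>
      filter(length >= min_vr)
    if (nrow(merged) == 0L) {
      return(tibble(side = character(), start = integer(), end = integer(),
                    length = integer()))
    }
    tibble(side = side, start = merged$start, end = merged$end,
           length = merged$length)
  }
  bind_rows(one_side(aln$unaligned_query, "query"),
            one_side(aln$unaligned_target, "target"))
}
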