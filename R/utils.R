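#' @importFrom rlang %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n row_number desc distinct rename pull slice
#' @importFrom stats setNames rbinom runif rgeom median sd
NULL

#' Reverse complement of a DNA string
#'
#' @param x a single DNA string.
#' @return the reverse complement, case preserved, non-ACGT characters left
#'   in place (reversed).
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  cpp_revcomp(x)
}

#' Random DNA with a target GC fraction
#'
#' @param n length in bp.
#' @param gc GC fraction.
#' @return a single DNA string.
#' @export
rand_seq <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# deterministic per-stage seed fan-out from one global seed
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Substring by 0-based half-open interval
#'
#' @param x a string.
#' @param start,end 0-based half-open interval.
#' @return the substring.
#' @export
subseq0 <- function(x, start, end) {
  if (end <= start) return("")
  substr(x, start + 1L, end)
}

#' Splice a sequence into another at a 0-based position
#'
#' @param x a string.
#' @param pos 0-based insertion point.
#' @param insert string to insert.
#' @return the spliced string.
#' @export
splice_seq <- function(x, pos, insert) {
  paste0(subseq0(x, 0L, pos), insert, subseq0(x, pos, nchar(x)))
}

# union of 0-based half-open intervals; returns tibble(start, end)
interval_union <- function(start, end) {
  if (length(start) == 0L) return(tibble(start = integer(), end = integer()))
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  tibble(start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir))
}

# complement of half-open intervals within [0, len)
interval_complement <- function(start, end, len) {
  u <- interval_union(start, end)
  if (nrow(u) == 0L) return(tibble(start = 0L, end = as.integer(len)))
  gaps_start <- c(0L, u$end)
  gaps_end <- c(u$start, as.integer(len))
  keep <- gaps_end > gaps_start
  tibble(start = gaps_start[keep], end = gaps_end[keep])
}

# intersection of two half-open interval sets
interval_intersect <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(tibble(start = integer(), end = integer()))
  }
  ia <- IRanges::IRanges(start = a$start + 1L, end = a$end)
  ib <- IRanges::IRanges(start = b$start + 1L, end = b$end)
  ix <- IRanges::intersect(ia, ib)
  tibble(start = BiocGenerics::start(ix) - 1L, end = BiocGenerics::end(ix))
}

# translate a CDS (standard code); returns "" on empty input
translate_cds <- function(s) {
  if (nchar(s) < 3L) return("")
  s <- substr(s, 1L, nchar(s) - nchar(s) %% 3L)
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     if.fuzzy.codon = "X"))
}

#' GC fraction of a sequence
#'
#' @param s a DNA string.
#' @return fraction of G+C.
#' @export
gc_content <- function(s) {
  counts <- Biostrings::letterFrequency(Biostrings::DNAString(s), c("G", "C"))
  sum(counts) / nchar(s)
}
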