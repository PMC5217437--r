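#' Recruitment parameters
#'
#' The classic stringent cutoff is 99% identity over 70% of the read
#' (near-identical populations); a relaxed 95% identity cutoff is used for
#' more divergent targets such as chromids.
#'
#' @param min_identity minimum alignment identity (default 0.99).
#' @param min_read_fraction_aligned minimum aligned fraction of the full
#'   read length (default 0.70).
#' @return list of class `recruit_params`.
#' @export
recruit_params <- function(min_identity = 0.99,
                           min_read_fraction_aligned = 0.70) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_read_fraction_aligned > 0, min_read_fraction_aligned <= 1)
  structure(list(min_identity = min_identity,
                 min_read_fraction_aligned = min_read_fraction_aligned),
            class = "recruit_params")
}

read_seqs <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot(all(c("read_id", "seq") %in% names(reads)))
    setNames(reads$seq, reads$read_id)
  } else {
    if (is.null(names(reads))) {
      names(reads) <- sprintf("read%06d", seq_along(reads))
    }
    reads
  }
}

#' Recruit metagenomic reads against a replicon
#'
#' Aligns every read on both strands (seeded banded Smith-Waterman); a read
#' is recruited when its best hit reaches `min_identity` over at least
#' `min_read_fraction_aligned` of the full read length (one best hit per
#' read). RPKG = reads recruited per Kb of replicon per Gb of metagenome.
#'
#' @param reads a tibble from [generate_metagenome()] (columns read_id,
#'   seq), or a named character vector.
#' @param rep the target [replicon()] or sequence.
#' @param params a [recruit_params()].
#' @param metagenome_bp total metagenome size in bp; defaults to the total
#'   bases in the read set.
#' @param align nucleotide [align_params()] for the read mapping.
#' @return object of class `recruitment_profile`: list with `hits` tibble
#'   (read_id, position, strand, identity, aligned_fraction),
#'   `n_recruited`, `rpkg`, `replicon`, `replicon_bp`, `metagenome_bp`,
#'   `coverage` (per-base counts).
#' @export
recruit <- function(reads, rep, params = recruit_params(),
                    metagenome_bp = NULL, align = NULL) {
  seqs <- read_seqs(reads)
  if (length(seqs) == 0L) abort("empty read set")
  p <- align %||% align_params("nt", k = 13L, min_score = 20L)
  target <- as_seq(rep)
  rid <- seq_id(rep, "replicon")
  metagenome_bp <- metagenome_bp %||% sum(nchar(seqs))
  fwd <- sw_map(unname(seqs), target, p)
  rev_ <- sw_map(vapply(unname(seqs), cpp_revcomp, character(1),
                        USE.NAMES = FALSE), target, p)
  use_rev <- rev_[, "score"] > fwd[, "score"]
  m <- fwd
  m[use_rev, ] <- rev_[use_rev, ]
  ok <- m[, "score"] > 0
  identity <- ifelse(ok, m[, "matches"] / pmax(m[, "cols"], 1), 0)
  afrac <- ifelse(ok, (m[, "qend"] - m[, "qstart"]) / nchar(seqs), 0)
  keep <- ok & identity >= params$min_identity &
    afrac >= params$min_read_fraction_aligned
  hits <- tibble(read_id = names(seqs)[keep],
                 position = as.integer(m[keep, "tstart"]),
                 end = as.integer(m[keep, "tend"]),
                 strand = ifelse(use_rev[keep], "-", "+"),
                 identity = identity[keep],
                 aligned_fraction = afrac[keep])
  n <- nrow(hits)
  rpkg <- n / ((nchar(target) / 1e3) * (metagenome_bp / 1e9))
  cov <- integer(nchar(target))
  if (n > 0L) {
    for (i in seq_len(n)) {
      cov[(hits$position[i] + 1L):hits$end[i]] <-
        cov[(hits$position[i] + 1L):hits$end[i]] + 1L
    }
  }
  structure(list(replicon = rid, hits = hits, n_recruited = n, rpkg = rpkg,
                 replicon_bp = nchar(target), metagenome_bp = metagenome_bp,
                 n_reads = length(seqs), coverage = cov,
                 params = params),
            class = "recruitment_profile")
}

#' @export
print.recruitment_profile <- function(x, ...) {
  cat(sprintf("<recruitment_profile> %s: %d/%d reads recruited, RPKG %.3f\n",
              x$replicon, x$n_recruited, x$n_reads, x$rpkg))
  invisible(x)
}

#' @rdname recruit
#' @param x a `recruitment_profile`.
#' @param ... unused.
#' @method tidy recruitment_profile
#' @export
tidy.recruitment_profile <- function(x, ...) {
  mutate(x$hits, replicon = x$replicon, .before = 1)
}

#' @rdname recruit
#' @method glance recruitment_profile
#' @export
glance.recruitment_profile <- function(x, ...) {
  tibble(replicon = x$replicon, n_reads = x$n_reads,
         n_recruited = x$n_recruited, rpkg = x$rpkg,
         replicon_bp = x$replicon_bp, metagenome_bp = x$metagenome_bp,
         mean_identity = if (x$n_recruited) mean(x$hits$identity) else NA_real_)
}

#' Recruit a read set against a panel of replicons
#'
#' Each replicon is profiled independently on a shared metagenome size (a
#' read may be recruited by several replicons).
#'
#' @param reads as in [recruit()].
#' @param replicons named list of [replicon()]s or sequences.
#' @param params a [recruit_params()].
#' @param metagenome_bp shared metagenome size (default: total read bases).
#' @param ... passed to [recruit()].
#' @return list with `profiles` (named list of `recruitment_profile`) and
#'   `summary` (one row per replicon, deterministic order).
#' @export
recruit_panel <- function(reads, replicons, params = recruit_params(),
                          metagenome_bp = NULL, ...) {
  seqs <- read_seqs(reads)
  metagenome_bp <- metagenome_bp %||% sum(nchar(seqs))
  ids <- names(replicons) %||% vapply(replicons, function(r) seq_id(r, "rep"),
                                      character(1))
  profiles <- list()
  for (i in seq_along(replicons)) {
    profiles[[ids[i]]] <- recruit(seqs, replicons[[i]], params = params,
                                  metagenome_bp = metagenome_bp, ...)
  }
  list(profiles = profiles,
       summary = bind_rows(lapply(profiles, glance)))
}
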