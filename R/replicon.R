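#' Construct a replicon
#'
#' A replicon is the universal unit of comparison: one sequence (chromosome,
#' plasmid, chromid or ICE) plus its feature table and a role tag. All
#' internal coordinates are 0-based, half-open, on the forward strand; GFF3
#' output converts to 1-based inclusive at the boundary.
#'
#' @param id replicon identifier.
#' @param seq a single DNA string (coerced to upper case).
#' @param features a tibble with columns `feature_id`, `type` (e.g. "CDS",
#'   "tRNA"), `start`, `end` (0-based half-open), `strand` ("+"/"-"),
#'   `gene`, `product`. Missing columns are filled with `NA`.
#' @param role one of "chromosome", "plasmid", "ICE", "chromid".
#' @return an object of class `replicon`.
#' @export
replicon <- function(id, seq, features = empty_features(),
                     role = c("chromosome", "plasmid", "ICE", "chromid")) {
  role <- match.arg(role)
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  features <- as_tibble(features)
  for (col in setdiff(names(empty_features()), names(features))) {
    features[[col]] <- if (col %in% c("start", "end")) integer(0) else NA_character_
  }
  features <- features[, names(empty_features())]
  if (nrow(features) > 0L) {
    features$start <- as.integer(features$start)
    features$end <- as.integer(features$end)
    bad <- features$start < 0L | features$end > nchar(seq) |
      features$end <= features$start
    if (any(bad)) {
      abort(sprintf("feature coordinates out of range for '%s': %s",
                    id, paste(features$feature_id[bad], collapse = ", ")))
    }
  }
  structure(list(id = id, seq = seq, features = features, role = role),
            class = "replicon")
}

#' @export
empty_features <- function() {
  tibble(feature_id = character(), type = character(), start = integer(),
         end = integer(), strand = character(), gene = character(),
         product = character())
}

#' @export
print.replicon <- function(x, ...) {
  cat(sprintf("<replicon> %s (%s), %s bp, %d features\n",
              x$id, x$role, format(nchar(x$seq), big.mark = ","),
              nrow(x$features)))
  invisible(x)
}

#' @export
length.replicon <- function(x) nchar(x$seq)

is_replicon <- function(x) inherits(x, "replicon")

as_seq <- function(x) {
  if (is_replicon(x)) x$seq else {
    stopifnot(is.character(x), length(x) == 1L)
    toupper(unname(x))
  }
}

seq_id <- function(x, default) {
  if (is_replicon(x)) x$id
  else names(x) %||% default
}

# nucleotide sequence of one feature row, strand-resolved
feature_seq <- function(rep, row) {
  s <- subseq0(rep$seq, row$start, row$end)
  if (identical(row$strand, "-")) cpp_revcomp(s) else s
}

#' Extract the proteome of a replicon
#'
#' Translates every CDS feature with the standard genetic code (strand
#' resolved). CDS whose length is not a multiple of 3 are flagged with a
#' warning and translated up to the last complete codon.
#'
#' @param rep a [replicon()].
#' @param trim_stop drop a trailing stop ("*") from translations.
#' @return a named character vector of amino-acid sequences, named by
#'   `feature_id`.
#' @export
proteome <- function(rep, trim_stop = TRUE) {
  stopifnot(is_replicon(rep))
  cds <- rep$features[rep$features$type == "CDS", ]
  if (nrow(cds) == 0L) return(setNames(character(0), character(0)))
  lens <- cds$end - cds$start
  if (any(lens %% 3L != 0L)) {
    warn(sprintf("%d CDS in '%s' have length not divisible by 3",
                 sum(lens %% 3L != 0L), rep$id))
  }
  out <- vapply(seq_len(nrow(cds)), function(i) {
    translate_cds(feature_seq(rep, cds[i, ]))
  }, character(1))
  if (trim_stop) out <- sub("\\*$", "", out)
  setNames(out, cds$feature_id)
}
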