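#' Read and write FASTA
#'
#' Thin wrappers over Biostrings for named character vectors.
#'
#' @param x named character vector of sequences.
#' @param path file path.
#' @return `read_fasta` returns a named character vector.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(x), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readBStringSet(path)
  setNames(as.character(s), names(s))
}

#' Write reads as FASTQ
#'
#' Constant-quality FASTQ ("I" throughout; the generators model identity
#' only, not quality).
#'
#' @param reads tibble with read_id and seq (as from
#'   [generate_metagenome()]).
#' @param path file path.
#' @export
write_fastq <- function(reads, path) {
  seqs <- read_seqs(reads)
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", names(seqs), "\n", unname(seqs), "\n+\n",
                    unname(qual)), con, sep = "\n")
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  s <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = names(s), seq = unname(as.character(s)))
}

# plain deterministic TSV ('.' for missing, '\n' endings)
write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  for (col in names(df)) {
    if (is.list(df[[col]])) {
      df[[col]] <- vapply(df[[col]], paste, character(1), collapse = ",")
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".", eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_plain <- function(path) {
  as_tibble(utils::read.delim(path, na.strings = ".",
                              stringsAsFactors = FALSE))
}

#' Write a replicon as FASTA + GFF3
#'
#' Internal 0-based half-open coordinates are converted to the 1-based
#' inclusive GFF3 convention at this boundary.
#'
#' @param rep a [replicon()].
#' @param fasta_path,gff3_path output paths.
#' @export
write_replicon <- function(rep, fasta_path, gff3_path) {
  stopifnot(is_replicon(rep))
  write_fasta(setNames(rep$seq, rep$id), fasta_path)
  f <- rep$features
  gr <- GenomicRanges::GRanges(
    seqnames = rep$id,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = ifelse(is.na(f$strand), "*", f$strand))
  S4Vectors::mcols(gr)$type <- f$type
  S4Vectors::mcols(gr)$ID <- f$feature_id
  S4Vectors::mcols(gr)$gene <- f$gene
  S4Vectors::mcols(gr)$product <- f$product
  S4Vectors::mcols(gr)$source <- "mobilomics"
  S4Vectors::mcols(gr)$phase <- ifelse(f$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, gff3_path, format = "gff3")
  invisible(rep)
}

#' Read a replicon from FASTA plus GFF3 (or a flat feature TSV)
#'
#' @param fasta_path FASTA with one record (the replicon sequence).
#' @param gff3_path optional GFF3 annotation (1-based inclusive; converted
#'   to internal 0-based half-open coordinates).
#' @param tsv_path optional flat feature table with the package's internal
#'   columns (0-based half-open), as written by [write_tsv_plain] tables.
#' @param role replicon role tag.
#' @return a [replicon()].
#' @export
read_replicon <- function(fasta_path, gff3_path = NULL, tsv_path = NULL,
                          role = "chromosome") {
  seqs <- read_fasta(fasta_path)
  if (length(seqs) == 0L) abort("empty FASTA")
  id <- sub("\\s.*$", "", names(seqs)[1])
  feats <- empty_features()
  if (!is.null(gff3_path)) {
    lines <- readLines(gff3_path, warn = FALSE)
    body <- which(!grepl("^#", lines) & nzchar(lines))
    nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    if (any(nf < 9L)) {
      abort(sprintf("malformed GFF3 line %d in %s", body[which(nf < 9L)[1]],
                    gff3_path))
    }
    gr <- rtracklayer::import(gff3_path, format = "gff3")
    md <- S4Vectors::mcols(gr)
    get_md <- function(col, default = NA_character_) {
      if (col %in% names(md)) as.character(md[[col]]) else
        rep(default, length(gr))
    }
    feats <- tibble(
      feature_id = get_md("ID") %||% paste0("f", seq_along(gr)),
      type = get_md("type"),
      start = BiocGenerics::start(gr) - 1L,
      end = BiocGenerics::end(gr),
      strand = as.character(BiocGenerics::strand(gr)),
      gene = get_md("gene"),
      product = get_md("product"))
    feats$strand[!feats$strand %in% c("+", "-")] <- NA_character_
    bad <- feats$start < 0L | feats$end > nchar(seqs[1])
    if (any(bad)) abort("feature coordinates out of range in GFF3")
    cds_len <- feats$end - feats$start
    odd <- feats$type == "CDS" & cds_len %% 3L != 0L
    if (any(odd)) {
      warn(sprintf("%d CDS with length not divisible by 3 (flagged)",
                   sum(odd)))
    }
  } else if (!is.null(tsv_path)) {
    feats <- read_tsv_plain(tsv_path)
  }
  replicon(id, unname(seqs[1]), feats, role = role)
}

#' Write a distance matrix as TSV and PHYLIP square format
#'
#' @param d symmetric matrix with dimnames.
#' @param tsv_path,phylip_path output paths (either may be NULL).
#' @export
write_distance_matrix <- function(d, tsv_path = NULL, phylip_path = NULL) {
  if (!is.null(tsv_path)) {
    df <- data.frame(id = rownames(d), d, check.names = FALSE)
    write_tsv_plain(df, tsv_path)
  }
  if (!is.null(phylip_path)) {
    con <- file(phylip_path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(d)), con)
    for (i in seq_len(nrow(d))) {
      writeLines(paste(c(sprintf("%-10s", rownames(d)[i]),
                         sprintf("%.6f", d[i, ])), collapse = " "), con)
    }
  }
  invisible(d)
}

#' Export a sharing network as edge-list TSV and GraphML
#'
#' @param net a `sharing_network`.
#' @param edges_path,graphml_path output paths (either may be NULL).
#' @export
write_network <- function(net, edges_path = NULL, graphml_path = NULL) {
  stopifnot(inherits(net, "sharing_network"))
  if (!is.null(edges_path)) write_tsv_plain(net$edges, edges_path)
  if (!is.null(graphml_path)) {
    igraph::write_graph(net$graph, graphml_path, format = "graphml")
  }
  invisible(net)
}
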