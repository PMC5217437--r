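#' Simulation configuration for the synthetic mobilome
#'
#' Collects the knobs of the synthetic-data generators. Defaults describe a
#' compact but realistic marine bacterial replicon: 85% coding density, 45%
#' GC, point-mutation divergence on the order of a few percent and cargo
#' cassettes 3% lower in GC than the host (conjugative elements run
#' AT-richer than their host chromosomes).
#'
#' @param seed integer seed driving every random draw.
#' @param genome_length replicon length in bp (>= 10 kb for ancestors).
#' @param gene_density fraction of the sequence covered by CDS, in (0, 0.98].
#' @param gc_target genome GC fraction.
#' @param snp_rate substitutions per site when deriving strains.
#' @param indel_rate indel events per site.
#' @param indel_mean_len mean indel length (geometric distribution).
#' @param cassette_library tibble with columns `cassette_id`, `length`, `gc`.
#' @param read_length metagenomic read length in bp.
#' @param read_error_rate per-base substitution error rate of reads.
#' @param abundances named numeric of relative community weights
#'   (normalised to sum to 1 when used).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_length = 50000L, gene_density = 0.85,
                       gc_target = 0.45, snp_rate = 0.01, indel_rate = 0,
                       indel_mean_len = 50, cassette_library = NULL,
                       read_length = 100L, read_error_rate = 0.005,
                       abundances = NULL) {
  if (gene_density <= 0 || gene_density > 0.98) {
    abort("gene_density must be in (0, 0.98]")
  }
  rates <- c(snp_rate = snp_rate, indel_rate = indel_rate,
             read_error_rate = read_error_rate, gc_target = gc_target)
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  cassette_library <- cassette_library %||%
    tibble(cassette_id = paste0("cas", 1:6),
           length = c(3000L, 5000L, 4000L, 6000L, 2500L, 3500L),
           gc = pmax(gc_target - 0.03, 0.05))
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 gene_density = gene_density, gc_target = gc_target,
                 snp_rate = snp_rate, indel_rate = indel_rate,
                 indel_mean_len = indel_mean_len,
                 cassette_library = as_tibble(cassette_library),
                 read_length = as.integer(read_length),
                 read_error_rate = read_error_rate,
                 abundances = abundances),
            class = "sim_config")
}

empty_truth <- function() {
  list(snps = tibble(pos = integer(), ref = character(), alt = character()),
       indels = tibble(type = character(), pos = integer(), length = integer()),
       cassettes = tibble(cassette_id = character(), start = integer(),
                          end = integer(), strand = character()),
       crispr = tibble(start = integer(), end = integer(),
                       n_repeats = integer()),
       spacers = character(),
       integration = NULL, trna_dup = NULL)
}

# sense codons weighted towards a GC target
codon_pool <- function(gc) {
  bases <- c("A", "C", "G", "T")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  keep <- !codons %in% c("TAA", "TAG", "TGA")
  w <- vapply(codons, function(cd) {
    prod(p[match(strsplit(cd, "")[[1]], bases)])
  }, numeric(1))
  list(codons = codons[keep], w = w[keep] / sum(w[keep]))
}

random_orf <- function(n_codons, pool) {
  body <- sample(pool$codons, n_codons, replace = TRUE, prob = pool$w)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

# a plausible tRNA-like gene body (fixed-structure random sequence)
random_trna <- function(gc) rand_seq(76L, gc)

#' Generate an ancestral replicon
#'
#' Builds a random replicon hitting a GC target within +-0.01 and a CDS
#' coverage close to `gene_density`: genes are sampled as valid ORFs (ATG
#' start, in-frame stop only at the end) from a GC-tilted sense-codon pool,
#' and the intergenic GC is tuned so the global GC lands on target. One tRNA
#' gene is always included, one mid-replicon CDS is named `prfC` (the
#' SXT/R391 ICE integration target) and a handful of CDS are annotated as
#' ribosomal proteins so the default CAI reference set is non-empty.
#'
#' @param config a [sim_config()]; `genome_length` must be >= 10 kb.
#' @param id replicon id.
#' @param role replicon role tag.
#' @return a list with elements `replicon` and `truth` (a TruthRecord).
#' @export
generate_ancestor <- function(config = sim_config(), id = "anc",
                              role = "chromosome") {
  L <- config$genome_length
  if (L < 10000L) abort("genome_length must be >= 10 kb")
  set.seed(config$seed)
  pool <- codon_pool(config$gc_target)
  target_coding <- round(config$gene_density * L)
  gene_lens <- integer(0)
  tot <- 0L
  while (tot < target_coding - 1500L) {
    len <- (sample(100:450, 1L) + 2L) * 3L
    gene_lens <- c(gene_lens, len)
    tot <- tot + len
  }
  if (target_coding - tot >= 150L) {
    gene_lens <- c(gene_lens, (max((target_coding - tot) %/% 3L, 52L) - 2L) %/% 1L * 3L)
  }
  n_genes <- length(gene_lens)
  orfs <- vapply(gene_lens, function(l) random_orf(l %/% 3L - 2L, pool),
                 character(1))
  strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  trna_seq <- random_trna(config$gc_target)
  coding_bp <- sum(nchar(orfs)) + nchar(trna_seq)
  intergenic_bp <- L - coding_bp
  if (intergenic_bp < n_genes + 2L) abort("gene_density infeasible at this length")
  gaps <- as.vector(stats::rmultinom(1, intergenic_bp, rep(1, n_genes + 2L)))
  coding_gc_bp <- sum(vapply(orfs, function(s) {
    sum(strsplit(s, "")[[1]] %in% c("G", "C"))
  }, numeric(1))) + sum(strsplit(trna_seq, "")[[1]] %in% c("G", "C"))
  gc_int <- (config$gc_target * L - coding_gc_bp) / intergenic_bp
  gc_int <- min(max(gc_int, 0.02), 0.98)
  # assemble: gap g1, gene1, gap g2, ..., tRNA in the middle, final gap
  trna_after <- n_genes %/% 2L
  pieces <- character(0)
  feats <- list()
  pos <- 0L
  prfc_idx <- max(1L, n_genes %/% 2L)
  ribo_idx <- if (n_genes >= 10L) {
    seq(2L, n_genes, length.out = min(8L, n_genes - 1L))
  } else seq_len(max(n_genes - 1L, 1L))
  ribo_idx <- unique(as.integer(ribo_idx))
  for (i in seq_len(n_genes)) {
    gap <- rand_seq(gaps[i], gc_int)
    pieces <- c(pieces, gap)
    pos <- pos + gaps[i]
    gseq <- if (strands[i] == "+") orfs[i] else cpp_revcomp(orfs[i])
    gene_name <- if (i == prfc_idx) "prfC" else sprintf("gene%04d", i)
    product <- if (i == prfc_idx) {
      "peptide chain release factor 3"
    } else if (i %in% ribo_idx) {
      sprintf("ribosomal protein L%d", match(i, ribo_idx))
    } else "hypothetical protein"
    feats[[length(feats) + 1L]] <- tibble(
      feature_id = sprintf("%s_g%04d", id, i), type = "CDS",
      start = pos, end = pos + nchar(gseq), strand = strands[i],
      gene = gene_name, product = product)
    pieces <- c(pieces, gseq)
    pos <- pos + nchar(gseq)
    if (i == trna_after) {
      gap2 <- rand_seq(gaps[n_genes + 1L], gc_int)
      pieces <- c(pieces, gap2)
      pos <- pos + gaps[n_genes + 1L]
      feats[[length(feats) + 1L]] <- tibble(
        feature_id = sprintf("%s_trna1", id), type = "tRNA",
        start = pos, end = pos + nchar(trna_seq), strand = "+",
        gene = "tRNA-Met", product = "tRNA-Met")
      pieces <- c(pieces, trna_seq)
      pos <- pos + nchar(trna_seq)
    }
  }
  pieces <- c(pieces, rand_seq(gaps[n_genes + 2L], gc_int))
  seq <- paste(pieces, collapse = "")
  rep <- replicon(id, seq, bind_rows(feats), role = role)
  list(replicon = rep, truth = empty_truth())
}

#' Derive a strain by point mutation and indels
#'
#' Applies indels (geometric lengths) and then substitutions to a parent
#' replicon; every implanted change is recorded in the TruthRecord with
#' coordinates on the derived sequence. Features overlapping an indel are
#' dropped; all others are coordinate-shifted.
#'
#' @param parent a [replicon()].
#' @param snp_rate substitutions per site (each site mutates independently,
#'   so the SNP count is Binomial(L, snp_rate)).
#' @param indel_rate indel events per site.
#' @param seed integer seed.
#' @param n_snps optional exact number of substitutions (overrides
#'   `snp_rate`), used to emulate near-clonal strain pairs with a known SNP
#'   count.
#' @param indel_mean_len mean indel length.
#' @param id id of the derived replicon.
#' @return list with `replicon` and `truth`.
#' @export
derive_strain <- function(parent, snp_rate = 0, indel_rate = 0, seed = 1L,
                          n_snps = NULL, indel_mean_len = 50,
                          id = paste0(parent$id, "_d")) {
  stopifnot(is_replicon(parent), snp_rate >= 0, indel_rate >= 0)
  set.seed(seed)
  chars <- strsplit(parent$seq, "")[[1]]
  feats <- parent$features
  truth <- empty_truth()
  L0 <- length(chars)
  n_ind <- rbinom(1L, L0, indel_rate)
  if (n_ind > 0L) {
    ipos <- sort(sample.int(L0, n_ind))
    itype <- sample(c("ins", "del"), n_ind, replace = TRUE)
    ilen <- rgeom(n_ind, 1 / indel_mean_len) + 1L
    # apply right to left so earlier coordinates stay valid
    for (j in rev(seq_len(n_ind))) {
      p <- ipos[j]
      if (itype[j] == "del") {
        len <- min(ilen[j], L0 - p + 1L)
        chars <- chars[-(p:(p + len - 1L))]
        ilen[j] <- len
      } else {
        ins <- strsplit(rand_seq(ilen[j], 0.5), "")[[1]]
        chars <- append(chars, ins, after = p - 1L)
      }
    }
    # derived-coordinate positions of the indels
    shift <- ifelse(itype == "ins", ilen, -ilen)
    cumshift <- c(0L, cumsum(shift))[seq_len(n_ind)]
    truth$indels <- tibble(type = itype,
                           pos = as.integer(ipos - 1L + cumshift),
                           length = as.integer(ilen))
    # feature mapping in original coordinates -> derived
    map_coord <- function(x) {
      as.integer(x + sapply(x, function(v) {
        sum(ifelse(ipos - 1L <= v, shift, 0L))
      }))
    }
    hit <- vapply(seq_len(nrow(feats)), function(i) {
      any(ipos - 1L >= feats$start[i] & ipos - 1L < feats$end[i])
    }, logical(1))
    feats <- feats[!hit, ]
    if (nrow(feats) > 0L) {
      feats$start <- map_coord(feats$start)
      feats$end <- map_coord(feats$end)
    }
  }
  L <- length(chars)
  if (!is.null(n_snps)) {
    spos <- sort(sample.int(L, n_snps))
  } else if (snp_rate > 0) {
    spos <- which(runif(L) < snp_rate)
  } else spos <- integer(0)
  if (length(spos) > 0L) {
    alts <- vapply(spos, function(p) {
      sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
    }, character(1))
    truth$snps <- tibble(pos = as.integer(spos - 1L), ref = chars[spos],
                         alt = alts)
    chars[spos] <- alts
  }
  rep <- replicon(id, paste(chars, collapse = ""), feats, role = parent$role)
  list(replicon = rep, truth = truth)
}

mpf_gene_set <- function() paste0("virB", 1:11) |> c("virD4")

#' Build a synthetic conjugative element
#'
#' Assembles a plasmid-like element whose marker-gene complement encodes a
#' chosen mobility class: `C` (conjugative) carries a relaxase plus the
#' complete 12-gene mating-pair-formation (MPF/T4SS) set, `MB` (mobilizable)
#' a relaxase plus an incomplete MPF set, and `NMB` (non-mobilizable)
#' neither. Cargo cassettes from the configured library are appended with
#' recorded coordinates.
#'
#' @param id element id.
#' @param mobility_class "C", "MB" or "NMB".
#' @param cargo character vector of cassette ids from
#'   `config$cassette_library`.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param n_mpf_drop how many MPF genes an MB element is missing.
#' @return list with `replicon` (role "plasmid") and `truth`.
#' @export
build_conjugative_element <- function(id, mobility_class = c("C", "MB", "NMB"),
                                      cargo = character(), config = sim_config(),
                                      seed = 1L, n_mpf_drop = 5L) {
  mobility_class <- match.arg(mobility_class)
  set.seed(seed)
  lib <- config$cassette_library
  unknown <- setdiff(cargo, lib$cassette_id)
  if (length(unknown) > 0L) {
    abort(paste("unknown cassette_id:", paste(unknown, collapse = ", ")))
  }
  pool <- codon_pool(config$gc_target)
  markers <- switch(mobility_class,
    C = c("mobA", mpf_gene_set()),
    MB = c("mobA", sample(mpf_gene_set(), length(mpf_gene_set()) - n_mpf_drop)),
    NMB = character(0))
  # backbone: replication gene + stability genes + markers
  genes <- c("repA", "parA", markers, sprintf("orf%02d", 1:8))
  pieces <- character(0)
  feats <- list()
  truth <- empty_truth()
  pos <- 0L
  for (i in seq_along(genes)) {
    gap <- rand_seq(120L, config$gc_target)
    pieces <- c(pieces, gap)
    pos <- pos + 120L
    orf <- random_orf(sample(220:340, 1L), pool)
    strand <- sample(c("+", "-"), 1L)
    gseq <- if (strand == "+") orf else cpp_revcomp(orf)
    feats[[length(feats) + 1L]] <- tibble(
      feature_id = sprintf("%s_g%02d", id, i), type = "CDS",
      start = pos, end = pos + nchar(gseq), strand = strand,
      gene = genes[i],
      product = if (genes[i] == "mobA") "MOB relaxase" else
        if (grepl("^vir", genes[i])) "type IV secretion system protein" else
          "hypothetical protein")
    pieces <- c(pieces, gseq)
    pos <- pos + nchar(gseq)
  }
  cassettes <- list()
  for (cid in cargo) {
    row <- lib[lib$cassette_id == cid, ]
    gap <- rand_seq(150L, config$gc_target)
    pieces <- c(pieces, gap)
    pos <- pos + 150L
    cseq <- rand_seq(row$length[1], row$gc[1])
    cassettes[[length(cassettes) + 1L]] <- tibble(
      cassette_id = cid, start = pos, end = pos + nchar(cseq), strand = "+")
    feats[[length(feats) + 1L]] <- tibble(
      feature_id = sprintf("%s_%s", id, cid), type = "cassette",
      start = pos, end = pos + nchar(cseq), strand = "+",
      gene = cid, product = "cargo cassette")
    pieces <- c(pieces, cseq)
    pos <- pos + nchar(cseq)
  }
  pieces <- c(pieces, rand_seq(200L, config$gc_target))
  if (length(cassettes)) truth$cassettes <- bind_rows(cassettes)
  rep <- replicon(id, paste(pieces, collapse = ""), bind_rows(feats),
                  role = "plasmid")
  list(replicon = rep, truth = truth)
}

#' Integrate an ICE 5' of prfC
#'
#' Inserts an ICE sequence immediately 5' of the chromosomal `prfC` gene
#' (the conserved SXT/R391 integration site) and records the integration
#' interval. Excising the recorded interval restores the original
#' chromosome byte-exactly.
#'
#' @param chromosome a [replicon()] carrying a feature with gene `prfC`.
#' @param ice a [replicon()] (role "ICE").
#' @return list with `replicon` and `truth` (integration = tibble of the
#'   inserted interval).
#' @export
implant_ice <- function(chromosome, ice) {
  stopifnot(is_replicon(chromosome), is_replicon(ice))
  f <- chromosome$features
  hit <- which(f$gene == "prfC")
  if (length(hit) == 0L) abort("chromosome has no prfC feature")
  row <- f[hit[1], ]
  pos <- if (identical(row$strand, "-")) row$end else row$start
  lice <- nchar(ice$seq)
  seq <- splice_seq(chromosome$seq, pos, ice$seq)
  chrom_f <- f
  shift <- chrom_f$start >= pos
  chrom_f$start[shift] <- chrom_f$start[shift] + lice
  chrom_f$end[chrom_f$end > pos | shift] <-
    chrom_f$end[chrom_f$end > pos | shift] + lice
  ice_f <- ice$features
  if (nrow(ice_f) > 0L) {
    ice_f$start <- ice_f$start + pos
    ice_f$end <- ice_f$end + pos
    ice_f$feature_id <- paste0(ice$id, ":", ice_f$feature_id)
  }
  truth <- empty_truth()
  truth$integration <- tibble(ice_id = ice$id, start = pos,
                              end = pos + lice)
  out <- replicon(chromosome$id, seq, bind_rows(chrom_f, ice_f),
                  role = chromosome$role)
  list(replicon = out, truth = truth)
}

#' Remove an interval from a replicon
#'
#' @param rep a [replicon()].
#' @param start,end 0-based half-open interval to excise.
#' @return a [replicon()]; features overlapping the interval are dropped,
#'   later features are shifted.
#' @export
excise_interval <- function(rep, start, end) {
  stopifnot(is_replicon(rep), start >= 0, end <= nchar(rep$seq), end > start)
  len <- end - start
  seq <- paste0(subseq0(rep$seq, 0L, start), subseq0(rep$seq, end, nchar(rep$seq)))
  f <- rep$features
  keep <- f$end <= start | f$start >= end
  f <- f[keep, ]
  shift <- f$start >= end
  f$start[shift] <- f$start[shift] - len
  f$end[shift] <- f$end[shift] - len
  replicon(rep$id, seq, f, role = rep$role)
}

#' Insert a genomic island next to a tRNA with a duplicated tRNA 3'-end
#'
#' Emulates the hallmark of a single integration event at a tRNA locus: the
#' island is inserted immediately downstream of the tRNA gene and a copy of
#' the tRNA's 3'-terminal `k` bases is placed at the island's distal end.
#'
#' @param chromosome a [replicon()] with a tRNA feature.
#' @param island a [replicon()] (the island to insert).
#' @param trna_feature feature_id of the target tRNA; default: first tRNA.
#' @param k length of the duplicated 3'-end (0 = no duplication).
#' @return list with `replicon` and `truth` (`trna_dup` interval of the
#'   duplicated fragment; `integration` the island interval).
#' @export
implant_trna_island <- function(chromosome, island, trna_feature = NULL,
                                k = 15L) {
  stopifnot(is_replicon(chromosome), is_replicon(island))
  f <- chromosome$features
  trnas <- f[f$type == "tRNA", ]
  if (nrow(trnas) == 0L) abort("chromosome has no tRNA feature")
  row <- if (is.null(trna_feature)) trnas[1, ] else {
    trnas[trnas$feature_id == trna_feature, ][1, ]
  }
  at <- row$end  # insert downstream of the tRNA (forward-strand convention)
  dup <- if (k > 0L) subseq0(chromosome$seq, row$end - k, row$end) else ""
  island_seq <- island$seq
  if (k > 0L && nchar(island_seq) > 0L && row$end - k - 1L >= row$start) {
    # keep the duplication boundary unambiguous: the island must not extend
    # the duplicated fragment by ending with the base that precedes it
    before <- substr(chromosome$seq, row$end - k, row$end - k)
    lastb <- substr(island_seq, nchar(island_seq), nchar(island_seq))
    if (identical(lastb, before)) {
      swap <- setdiff(c("A", "C", "G", "T"), before)[1]
      substr(island_seq, nchar(island_seq), nchar(island_seq)) <- swap
    }
  }
  insert <- paste0(island_seq, dup)
  lins <- nchar(insert)
  seq <- splice_seq(chromosome$seq, at, insert)
  shift <- f$start >= at
  f$start[shift] <- f$start[shift] + lins
  f$end[f$end > at | shift] <- f$end[f$end > at | shift] + lins
  isl_f <- island$features
  if (nrow(isl_f) > 0L) {
    isl_f$start <- isl_f$start + at
    isl_f$end <- isl_f$end + at
    isl_f$feature_id <- paste0(island$id, ":", isl_f$feature_id)
  }
  truth <- empty_truth()
  truth$integration <- tibble(ice_id = island$id, start = at, end = at + lins)
  truth$trna_dup <- if (k > 0L) {
    tibble(trna_id = row$feature_id, start = at + nchar(island_seq),
           end = at + lins, k = as.integer(k))
  } else NULL
  out <- replicon(chromosome$id, seq, bind_rows(f, isl_f),
                  role = chromosome$role)
  list(replicon = out, truth = truth)
}

#' Generate a CRISPR array
#'
#' `n_repeats` identical direct repeats separated by `n_repeats - 1` unique
#' random spacers.
#'
#' @param n_repeats number of repeats (>= 2).
#' @param repeat_len,spacer_len lengths in bp.
#' @param seed integer seed.
#' @param gc GC fraction of repeat and spacers.
#' @return list with `seq`, `repeat_consensus`, `spacers` (character vector)
#'   and `truth` (repeat coordinates within the array).
#' @export
generate_crispr_array <- function(n_repeats = 8L, repeat_len = 28L,
                                  spacer_len = 32L, seed = 1L, gc = 0.5) {
  stopifnot(n_repeats >= 2L)
  set.seed(seed)
  rep_seq <- rand_seq(repeat_len, gc)
  spacers <- character(0)
  while (length(spacers) < n_repeats - 1L) {
    s <- rand_seq(spacer_len, gc)
    if (!s %in% spacers && s != rep_seq) spacers <- c(spacers, s)
  }
  parts <- character(2L * n_repeats - 1L)
  parts[seq(1L, by = 2L, length.out = n_repeats)] <- rep_seq
  if (n_repeats > 1L) {
    parts[seq(2L, by = 2L, length.out = n_repeats - 1L)] <- spacers
  }
  seqv <- paste(parts, collapse = "")
  starts <- (seq_len(n_repeats) - 1L) * (repeat_len + spacer_len)
  list(seq = seqv, repeat_consensus = rep_seq, spacers = spacers,
       truth = tibble(start = starts, end = starts + repeat_len))
}

#' Draw a synthetic metagenome from a community
#'
#' Single-end fixed-length reads: the source replicon is chosen
#' proportionally to abundance, the start uniformly, the strand with
#' probability 1/2, and substitution errors are applied per base. The
#' returned tibble is its own TruthRecord (source, origin, strand and error
#' count per read).
#'
#' @param replicons named list of [replicon()]s (or plain sequences).
#' @param abundances named numeric of relative weights (normalised).
#' @param n_reads number of reads.
#' @param read_length read length in bp.
#' @param error_rate per-base substitution error rate.
#' @param seed integer seed.
#' @return tibble with columns read_id, source, start, end, strand,
#'   n_errors, seq.
#' @export
generate_metagenome <- function(replicons, abundances, n_reads,
                                read_length = 100L, error_rate = 0.005,
                                seed = 1L) {
  set.seed(seed)
  seqs <- vapply(replicons, as_seq, character(1))
  if (is.null(names(seqs))) abort("replicons must be named")
  abundances <- abundances[names(seqs)]
  if (any(is.na(abundances))) abort("abundances must cover every replicon")
  w <- abundances / sum(abundances)
  lens <- nchar(seqs)
  if (any(lens < read_length)) abort("replicon shorter than read_length")
  src <- sample(names(seqs), n_reads, replace = TRUE, prob = w)
  start <- floor(runif(n_reads) * (lens[src] - read_length + 1))
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  reads <- substring(seqs[src], start + 1L, start + read_length)
  flip <- strand == "-"
  reads[flip] <- vapply(reads[flip], cpp_revcomp, character(1), USE.NAMES = FALSE)
  n_err <- rbinom(n_reads, read_length, error_rate)
  if (any(n_err > 0L)) {
    for (i in which(n_err > 0L)) {
      rp <- sample.int(read_length, n_err[i])
      rc <- strsplit(reads[i], "")[[1]]
      rc[rp] <- vapply(rp, function(p) {
        sample(setdiff(c("A", "C", "G", "T"), rc[p]), 1L)
      }, character(1))
      reads[i] <- paste(rc, collapse = "")
    }
  }
  tibble(read_id = sprintf("read%06d", seq_len(n_reads)), source = src,
         start = as.integer(start), end = as.integer(start + read_length),
         strand = strand, n_errors = as.integer(n_err), seq = unname(reads))
}

#' Simulate a family of ICEs sharing a backbone with private hotspots
#'
#' Generates `n_elements` ICEs descending from one backbone: each element is
#' derived by point mutation at half the target pairwise divergence (so any
#' two elements differ at approximately `divergence` of backbone sites) and
#' receives a private cargo cassette at each hotspot position.
#'
#' @param n_elements number of elements.
#' @param backbone_len shared backbone length in bp.
#' @param divergence target pairwise nucleotide divergence of the backbone.
#' @param hotspot_at numeric positions (fractions of the backbone) where
#'   private cassettes are inserted.
#' @param cassette_len length of each private cassette.
#' @param seed integer seed.
#' @param gc backbone GC fraction.
#' @return list with `elements` (list of replicons), `backbone`
#'   (ancestral replicon) and `truth` (per-element SNP and cassette tables,
#'   in ancestral backbone coordinates for SNPs).
#' @export
simulate_ice_family <- function(n_elements = 5L, backbone_len = 46000L,
                                divergence = 0.035,
                                hotspot_at = c(0.15, 0.55, 0.85),
                                cassette_len = 5000L, seed = 1L, gc = 0.45) {
  anc <- generate_ancestor(sim_config(seed = seed, genome_length = backbone_len,
                                      gc_target = gc, gene_density = 0.85),
                           id = "ice_backbone", role = "ICE")
  per_branch <- divergence / 2
  elements <- list()
  truth <- list()
  hs_pos <- sort(as.integer(floor(hotspot_at * backbone_len)))
  for (i in seq_len(n_elements)) {
    d <- derive_strain(anc$replicon, snp_rate = per_branch,
                       seed = stage_seed(seed, paste0("ice", i)),
                       id = sprintf("ICE%02d", i))
    set.seed(stage_seed(seed, paste0("cassette", i)))
    seqv <- d$replicon$seq
    feats <- d$replicon$features
    cass <- list()
    for (h in rev(seq_along(hs_pos))) {
      cs <- rand_seq(cassette_len, max(gc - 0.05, 0.05))
      seqv <- splice_seq(seqv, hs_pos[h], cs)
      shift <- feats$start >= hs_pos[h]
      feats$start[shift] <- feats$start[shift] + cassette_len
      feats$end[feats$end > hs_pos[h] | shift] <-
        feats$end[feats$end > hs_pos[h] | shift] + cassette_len
      # final element coordinate: cassettes at smaller hotspots (inserted
      # later) shift this one right by cassette_len each
      fin <- hs_pos[h] + (h - 1L) * cassette_len
      cass[[length(cass) + 1L]] <- tibble(
        cassette_id = sprintf("ICE%02d_hs%d", i, h),
        start = fin, end = fin + cassette_len, strand = "+")
    }
    # features overlapping a hotspot breakpoint are now invalid; drop them
    feats <- feats[feats$end <= nchar(seqv) & feats$end > feats$start, ]
    el <- replicon(sprintf("ICE%02d", i), seqv, feats, role = "ICE")
    elements[[el$id]] <- el
    tr <- d$truth
    tr$cassettes <- bind_rows(cass)
    truth[[el$id]] <- tr
  }
  list(elements = elements, backbone = anc$replicon, truth = truth)
}
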