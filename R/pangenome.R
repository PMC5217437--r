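#' Ortholog grouping by reciprocal best hits
#'
#' All-versus-all protein comparison between genome pairs; a reciprocal
#' best-hit (RBH) edge joins two proteins that are each other's best hit at
#' `min_identity` / `min_coverage`. Groups are the connected components of
#' the RBH graph; a group is core when it has exactly one member in every
#' genome.
#'
#' @param proteomes named list (genome -> named character vector of
#'   proteins).
#' @param min_identity,min_coverage RBH thresholds (default 0.70/0.70).
#' @param params amino-acid [align_params()].
#' @return object of class `ortholog_groups`: tibble with columns `group`,
#'   `genome`, `protein_id`, `core`.
#' @export
find_orthologs <- function(proteomes, min_identity = 0.70,
                           min_coverage = 0.70, params = NULL) {
  p <- params %||% align_params("aa")
  genomes <- names(proteomes)
  stopifnot(!is.null(genomes), length(genomes) >= 2L)
  vkey <- function(g, id) paste(g, id, sep = "\r")
  edges <- list()
  for (i in seq_len(length(genomes) - 1L)) {
    for (j in (i + 1L):length(genomes)) {
      pi_ <- proteomes[[i]]; pj <- proteomes[[j]]
      if (length(pi_) == 0L || length(pj) == 0L) next
      fwd <- protein_hits(pi_, pj, p) |> best_hit_per_query() |>
        filter(identity >= min_identity, coverage >= min_coverage)
      rev_ <- protein_hits(pj, pi_, p) |> best_hit_per_query() |>
        filter(identity >= min_identity, coverage >= min_coverage)
      if (nrow(fwd) == 0L || nrow(rev_) == 0L) next
      rb <- left_join(fwd, rev_, by = c("query_id" = "target_id",
                                        "target_id" = "query_id"),
                      suffix = c("", ".rev"))
      rb <- rb[!is.na(rb$score.rev), ]
      if (nrow(rb) == 0L) next
      edges[[length(edges) + 1L]] <- tibble(
        from = vkey(genomes[i], rb$query_id),
        to = vkey(genomes[j], rb$target_id))
    }
  }
  # in-genome mutual best hits (paralog edges): a duplicated gene pulls its
  # copies into one component, which then fails the single-copy rule
  for (g in genomes) {
    pg <- proteomes[[g]]
    if (length(pg) < 2L) next
    hits <- protein_hits(pg, pg, p)
    hits <- hits[hits$query_id != hits$target_id, ]
    hits <- best_hit_per_query(hits) |>
      filter(identity >= min_identity, coverage >= min_coverage)
    if (nrow(hits) == 0L) next
    rb <- left_join(hits, hits, by = c("query_id" = "target_id",
                                       "target_id" = "query_id"),
                    suffix = c("", ".rev"))
    rb <- rb[!is.na(rb$score.rev) & rb$query_id < rb$target_id, ]
    if (nrow(rb) > 0L) {
      edges[[length(edges) + 1L]] <- tibble(from = vkey(g, rb$query_id),
                                            to = vkey(g, rb$target_id))
    }
  }
  all_prot <- bind_rows(lapply(genomes, function(g) {
    tibble(genome = g, protein_id = names(proteomes[[g]]),
           key = vkey(g, names(proteomes[[g]])))
  }))
  g <- igraph::make_empty_graph(n = nrow(all_prot), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = all_prot$key)
  if (length(edges)) {
    e <- bind_rows(edges)
    g <- igraph::add_edges(g, rbind(match(e$from, all_prot$key),
                                    match(e$to, all_prot$key)))
  }
  comp <- igraph::components(g)
  all_prot$group <- comp$membership
  grp <- all_prot |>
    group_by(group) |>
    mutate(core = length(unique(genome)) == length(genomes) &
             n() == length(genomes)) |>
    ungroup()
  # drop singleton "groups" (proteins with no ortholog) from group ids? keep;
  # relabel deterministically by smallest protein key
  key_min <- vapply(split(grp$key, grp$group), min, character(1))
  relabel <- setNames(rank(key_min, ties.method = "first"),
                      names(key_min))
  grp$group <- as.integer(relabel[as.character(grp$group)])
  out <- grp |> select(group, genome, protein_id, core) |> arrange(group)
  class(out) <- c("ortholog_groups", class(out))
  out
}

# global pairwise alignment of two sequences, returning the column path
global_path <- function(x, y, p) {
  cpp_global_align(x, y, p$syms, p$submat, p$wild, p$gap_open, p$gap_ext)
}

# center-star multiple alignment of a small set of sequences
# returns a named character vector of equal-length aligned strings
center_star_msa <- function(seqs, p) {
  n <- length(seqs)
  if (n == 1L) return(seqs)
  paths <- list()
  dist_sum <- numeric(n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      g <- global_path(seqs[[i]], seqs[[j]], p)
      qi <- g$q_idx; ti <- g$t_idx
      al <- qi >= 0L & ti >= 0L
      xi <- strsplit(seqs[[i]], "")[[1]][qi[al] + 1L]
      yi <- strsplit(seqs[[j]], "")[[1]][ti[al] + 1L]
      d <- 1 - sum(xi == yi) / length(qi)
      dist_sum[i] <- dist_sum[i] + d
      dist_sum[j] <- dist_sum[j] + d
      paths[[paste(i, j)]] <- g
    }
  }
  c_idx <- which.min(dist_sum)
  center <- seqs[[c_idx]]
  lc <- nchar(center)
  # per member: chars at center positions + insertions before each slot
  # slot i in 0..lc (insertion before center position i)
  members <- setdiff(seq_len(n), c_idx)
  at <- list(); ins <- list()
  for (m in members) {
    i <- min(c_idx, m); j <- max(c_idx, m)
    g <- paths[[paste(i, j)]]
    if (c_idx < m) { ci <- g$q_idx; mi <- g$t_idx } else {
      ci <- g$t_idx; mi <- g$q_idx
    }
    mchars <- strsplit(seqs[[m]], "")[[1]]
    atv <- rep("-", lc)
    insv <- rep("", lc + 1L)
    next_c <- 0L
    buf <- character(0)
    for (col in seq_along(ci)) {
      if (ci[col] >= 0L) {
        if (length(buf)) {
          insv[ci[col] + 1L] <- paste(buf, collapse = "")
          buf <- character(0)
        }
        if (mi[col] >= 0L) atv[ci[col] + 1L] <- mchars[mi[col] + 1L]
        next_c <- ci[col] + 1L
      } else {
        buf <- c(buf, mchars[mi[col] + 1L])
      }
    }
    if (length(buf)) insv[lc + 1L] <- paste(buf, collapse = "")
    at[[as.character(m)]] <- atv
    ins[[as.character(m)]] <- insv
  }
  ins_len <- rep(0L, lc + 1L)
  for (m in members) {
    ins_len <- pmax(ins_len, nchar(ins[[as.character(m)]]))
  }
  pad <- function(s, w) paste0(s, strrep("-", w - nchar(s)))
  build_row <- function(atv, insv) {
    out <- character(2L * lc + 1L)
    for (i in 0:lc) {
      out[2L * i + 1L] <- pad(insv[i + 1L], ins_len[i + 1L])
      if (i < lc) out[2L * i + 2L] <- atv[i + 1L]
    }
    paste(out, collapse = "")
  }
  rows <- setNames(vector("character", n), names(seqs))
  cchars <- strsplit(center, "")[[1]]
  rows[c_idx] <- build_row(cchars, rep("", lc + 1L))
  for (m in members) {
    rows[m] <- build_row(at[[as.character(m)]], ins[[as.character(m)]])
  }
  rows
}

#' Align core ortholog groups and concatenate
#'
#' Each core group is aligned by center-star multiple alignment (the center
#' is the member minimising summed pairwise distance; merging follows
#' "once a gap, always a gap") and the per-group alignments are
#' concatenated in deterministic group order.
#'
#' @param groups an `ortholog_groups` tibble from [find_orthologs()].
#' @param proteomes the named list the groups were built from.
#' @param params [align_params()] matching the sequence alphabet.
#' @param alphabet "aa" (default) or "nt".
#' @return object of class `core_alignment`: list with `aln` (named aligned
#'   strings), `length`, `n_groups`, `variable_sites`.
#' @export
align_core_and_concatenate <- function(groups, proteomes, params = NULL,
                                       alphabet = c("aa", "nt")) {
  alphabet <- match.arg(alphabet)
  p <- params %||% align_params(alphabet)
  core <- groups[groups$core, ]
  gids <- sort(unique(core$group))
  genomes <- names(proteomes)
  pieces <- setNames(rep(list(character(0)), length(genomes)), genomes)
  for (gid in gids) {
    sub <- core[core$group == gid, ]
    seqs <- setNames(vapply(seq_len(nrow(sub)), function(i) {
      unname(proteomes[[sub$genome[i]]][[sub$protein_id[i]]])
    }, character(1)), sub$genome)
    seqs <- seqs[genomes]
    msa <- center_star_msa(seqs, p)
    for (g in genomes) pieces[[g]] <- c(pieces[[g]], msa[[g]])
  }
  aln <- vapply(pieces, paste, character(1), collapse = "")
  structure(list(aln = aln, length = unname(nchar(aln[1])),
                 n_groups = length(gids),
                 variable_sites = count_variable_sites(aln),
                 alphabet = alphabet),
            class = "core_alignment")
}

# variable site = column with >= 2 distinct non-gap characters
count_variable_sites <- function(aln) {
  if (length(aln) == 0L || nchar(aln[1]) == 0L) return(0L)
  m <- do.call(rbind, lapply(aln, function(s) charToRaw(s)))
  gap <- charToRaw("-")
  var <- vapply(seq_len(ncol(m)), function(j) {
    u <- unique(m[m[, j] != gap, j])
    length(u) >= 2L
  }, logical(1))
  sum(var)
}

#' @export
print.core_alignment <- function(x, ...) {
  cat(sprintf("<core_alignment> %d rows x %d columns, %d groups, %d variable sites\n",
              length(x$aln), x$length, x$n_groups, x$variable_sites))
  invisible(x)
}

#' Pairwise distances from a multiple alignment
#'
#' `K2P`: Kimura two-parameter distance
#' d = -1/2 ln((1-2P-Q)) - 1/4 ln(1-2Q) with P and Q the transition and
#' transversion proportions over columns ungapped in both rows.
#' `Poisson`: d = -ln(1 - p) on amino-acid p-distance. `p`: raw p-distance.
#' Saturated pairs (log argument <= 0) are reported as `Inf` with a warning.
#'
#' @param aln a `core_alignment` or named character vector of equal-length
#'   aligned strings.
#' @param model "K2P", "Poisson" or "p".
#' @return a symmetric numeric matrix (substitutions per site).
#' @export
distance_matrix <- function(aln, model = c("K2P", "Poisson", "p")) {
  model <- match.arg(model)
  if (inherits(aln, "core_alignment")) aln <- aln$aln
  n <- length(aln)
  ids <- names(aln) %||% paste0("t", seq_len(n))
  m <- do.call(rbind, lapply(aln, charToRaw))
  gap <- charToRaw("-")
  purine <- charToRaw(c("AG"))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  saturated <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- m[i, ] != gap & m[j, ] != gap
      xi <- m[i, ok]; xj <- m[j, ok]
      nc <- length(xi)
      if (nc == 0L) { d[i, j] <- d[j, i] <- NA_real_; next }
      if (model == "K2P") {
        diffv <- xi != xj
        ts <- diffv & ((xi %in% purine) == (xj %in% purine))
        P <- sum(ts) / nc
        Q <- sum(diffv & !ts) / nc
        a1 <- 1 - 2 * P - Q
        a2 <- 1 - 2 * Q
        if (a1 <= 0 || a2 <= 0) { d[i, j] <- d[j, i] <- Inf; saturated <- TRUE }
        else d[i, j] <- d[j, i] <- -0.5 * log(a1) - 0.25 * log(a2)
      } else {
        pd <- sum(xi != xj) / nc
        if (model == "p") d[i, j] <- d[j, i] <- pd
        else {
          if (pd >= 1) { d[i, j] <- d[j, i] <- Inf; saturated <- TRUE }
          else d[i, j] <- d[j, i] <- -log(1 - pd)
        }
      }
    }
  }
  if (saturated) warn("saturated distances reported as Inf")
  d
}

#' Neighbour-joining tree
#'
#' Canonical Saitou-Nei neighbour joining on a distance matrix (via
#' `ape::nj`); negative branch lengths are clamped to zero with the deficit
#' moved to the sister branch so path lengths are preserved.
#'
#' @param dist symmetric numeric matrix with dimnames.
#' @return an `ape::phylo` tree (unrooted).
#' @export
neighbor_joining <- function(dist) {
  tr <- ape::nj(as.matrix(dist))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sibs <- which(tr$edge[, 1] == parent)
    sibs <- setdiff(sibs, e)
    deficit <- -tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sibs) > 0L) {
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + deficit
    }
  }
  tr
}

#' Extract the shared core of a set of conjugative elements
#'
#' Aligns every element to a reference (the longest element), intersects
#' the aligned reference intervals across all elements, and keeps
#' intersections of at least `min_block` bp — the backbone shared by the
#' whole family. Variable-site counts and the length-weighted mean pairwise
#' identity are computed over reference-anchored columns of the core
#' blocks; the gene count reports reference CDS fully inside core blocks.
#'
#' @param elements named list of [replicon()]s (>= 2).
#' @param min_block minimum core block length in bp (default 500).
#' @param ... passed to [align_genomes()].
#' @return object of class `ice_core`: list with `core_blocks` (reference
#'   intervals), `core_length`, `n_blocks`, `variable_sites`,
#'   `average_identity` (fraction), `n_genes_in_core`, `reference`.
#' @export
extract_ice_core <- function(elements, min_block = 500L, ...) {
  stopifnot(length(elements) >= 2L)
  ids <- names(elements) %||% vapply(elements, function(e) seq_id(e, "el"),
                                     character(1))
  lens <- vapply(elements, function(e) nchar(as_seq(e)), numeric(1))
  ref_i <- which.max(lens)
  ref <- elements[[ref_i]]
  ref_seq <- as_seq(ref)
  Lr <- nchar(ref_seq)
  others <- setdiff(seq_along(elements), ref_i)
  alns <- list()
  core <- tibble(start = 0L, end = as.integer(Lr))
  for (i in others) {
    g <- align_genomes(ref, elements[[i]], ...)
    alns[[ids[i]]] <- g
    cov <- interval_union(g$blocks$query_start, g$blocks$query_end)
    core <- interval_intersect(core, cov)
  }
  core <- core[core$end - core$start >= min_block, ]
  core_len <- sum(core$end - core$start)
  # reference-anchored character matrix over core positions
  core_pos <- unlist(lapply(seq_len(nrow(core)), function(i) {
    (core$start[i] + 1L):core$end[i]   # 1-based reference positions
  }))
  refchars <- charToRaw(ref_seq)[core_pos]
  mat <- matrix(rep(refchars, length(elements)), nrow = length(elements),
                byrow = TRUE)
  row_ids <- c(ids[ref_i], ids[others])
  gapr <- charToRaw("-")
  pos_index <- integer(Lr)
  pos_index[core_pos] <- seq_along(core_pos)
  for (w in seq_along(others)) {
    g <- alns[[ids[others[w]]]]
    row <- w + 1L
    if (nrow(g$snps) > 0L) {
      sp <- g$snps$query_pos + 1L
      inside <- pos_index[sp] > 0L
      mat[row, pos_index[sp[inside]]] <-
        charToRaw(paste(g$snps$target_base[inside], collapse = ""))
    }
    gaps <- g$indels[g$indels$side == "target", ]
    for (k in seq_len(nrow(gaps))) {
      rng <- (gaps$query_pos[k] + 1L):(gaps$query_pos[k] + gaps$length[k])
      rng <- rng[rng >= 1L & rng <= Lr]
      inside <- pos_index[rng] > 0L
      if (any(inside)) mat[row, pos_index[rng[inside]]] <- gapr
    }
  }
  nel <- nrow(mat)
  var_col <- vapply(seq_len(ncol(mat)), function(j) {
    u <- unique(mat[mat[, j] != gapr, j])
    length(u) >= 2L
  }, logical(1))
  # length-weighted mean pairwise identity over element pairs
  tot_id <- 0; tot_cols <- 0
  for (i in seq_len(nel - 1L)) {
    for (j in (i + 1L):nel) {
      ok <- mat[i, ] != gapr & mat[j, ] != gapr
      tot_id <- tot_id + sum(mat[i, ok] == mat[j, ok])
      tot_cols <- tot_cols + sum(ok)
    }
  }
  feats <- if (is_replicon(ref)) ref$features[ref$features$type == "CDS", ] else
    empty_features()
  in_core <- vapply(seq_len(nrow(feats)), function(i) {
    any(feats$start[i] >= core$start & feats$end[i] <= core$end)
  }, logical(1))
  structure(list(core_blocks = core, core_length = core_len,
                 n_blocks = nrow(core),
                 variable_sites = sum(var_col),
                 average_identity = if (tot_cols > 0) tot_id / tot_cols else NA_real_,
                 n_genes_in_core = sum(in_core),
                 reference = ids[ref_i], element_ids = row_ids,
                 matrix = mat),
            class = "ice_core")
}

#' @export
print.ice_core <- function(x, ...) {
  cat(sprintf(
    "<ice_core> %d blocks, %s bp core, %d variable sites, %.1f%% identity, %d genes\n",
    x$n_blocks, format(x$core_length, big.mark = ","), x$variable_sites,
    100 * x$average_identity, x$n_genes_in_core))
  invisible(x)
}

#' @rdname extract_ice_core
#' @param x an `ice_core`.
#' @param ... unused.
#' @method glance ice_core
#' @export
glance.ice_core <- function(x, ...) {
  tibble(reference = x$reference, n_blocks = x$n_blocks,
         core_length = x$core_length, variable_sites = x$variable_sites,
         average_identity = x$average_identity,
         n_genes_in_core = x$n_genes_in_core)
}

#' Classify SNPs as synonymous, nonsynonymous or intergenic
#'
#' Codon-aware: each SNP inside a CDS is evaluated with the feature's frame
#' and strand under the standard genetic code; SNPs covered by several CDS
#' get the most severe call with every effect recorded.
#'
#' @param snps tibble with a reference position column and an alternate
#'   base column (defaults: `query_pos`, `target_base`, as produced by
#'   [align_genomes()]).
#' @param rep the reference [replicon()].
#' @param pos_col,alt_col column names in `snps`.
#' @return `snps` with added columns `effect` and `effects` (comma list
#'   when several CDS overlap).
#' @export
classify_snps <- function(snps, rep, pos_col = "query_pos",
                          alt_col = "target_base") {
  stopifnot(is_replicon(rep))
  cds <- rep$features[rep$features$type == "CDS", ]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  eff_one <- function(pos, alt, row) {
    if (identical(row$strand, "-")) {
      off <- row$end - 1L - pos
      alt <- comp[[alt]] %||% "N"
      orf <- cpp_revcomp(subseq0(rep$seq, row$start, row$end))
    } else {
      off <- pos - row$start
      orf <- subseq0(rep$seq, row$start, row$end)
    }
    ci <- off %/% 3L
    cp <- off %% 3L
    codon <- substr(orf, ci * 3L + 1L, ci * 3L + 3L)
    if (nchar(codon) < 3L) return(NA_character_)
    mut <- codon
    substr(mut, cp + 1L, cp + 1L) <- alt
    code <- Biostrings::GENETIC_CODE
    aa1 <- unname(code[codon])
    aa2 <- unname(code[mut])
    if (is.na(aa1) || is.na(aa2)) return(NA_character_)
    if (identical(aa1, aa2)) "synonymous" else "nonsynonymous"
  }
  effect <- character(nrow(snps))
  effects <- character(nrow(snps))
  for (i in seq_len(nrow(snps))) {
    pos <- snps[[pos_col]][i]
    alt <- snps[[alt_col]][i]
    hit <- cds[cds$start <= pos & cds$end > pos, ]
    if (nrow(hit) == 0L) {
      effect[i] <- "intergenic"
      effects[i] <- "intergenic"
      next
    }
    es <- vapply(seq_len(nrow(hit)), function(k) {
      eff_one(pos, alt, hit[k, ]) %||% NA_character_
    }, character(1))
    es <- es[!is.na(es)]
    if (length(es) == 0L) {
      effect[i] <- "intergenic"; effects[i] <- "intergenic"; next
    }
    effect[i] <- if (any(es == "nonsynonymous")) "nonsynonymous" else "synonymous"
    effects[i] <- paste(es, collapse = ",")
  }
  snps$effect <- effect
  snps$effects <- effects
  snps
}
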