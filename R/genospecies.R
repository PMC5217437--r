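#' Fragment-based average nucleotide identity (ANI)
#'
#' Cuts genome `a` into consecutive non-overlapping fragments (the classic
#' 1020-bp convention), aligns each fragment to genome `b` on both strands,
#' keeps fragments aligning at >= 30% identity over >= 70% of their length,
#' and averages the identity of the kept fragments. The reported ANI is the
#' mean of the two directed values.
#'
#' @param a,b [replicon()]s or sequences.
#' @param fragment_len fragment size in bp (default 1020).
#' @param params nucleotide [align_params()].
#' @return a one-row tibble: genome_a, genome_b, ani (percent),
#'   n_fragments_used, fraction_aligned.
#' @export
compute_ani <- function(a, b, fragment_len = 1020L, params = NULL) {
  p <- params %||% align_params("nt")
  ida <- seq_id(a, "a"); idb <- seq_id(b, "b")
  sa <- as_seq(a); sb <- as_seq(b)
  if (nchar(sa) < fragment_len || nchar(sb) < fragment_len) {
    abort("genome shorter than one ANI fragment")
  }
  directed <- function(x, y) {
    n <- nchar(x)
    starts <- seq(0L, n - fragment_len, by = fragment_len)
    frags <- substring(x, starts + 1L, starts + fragment_len)
    fwd <- sw_map(frags, y, p)
    rev_ <- sw_map(vapply(frags, cpp_revcomp, character(1), USE.NAMES = FALSE),
                   y, p)
    use_rev <- rev_[, "score"] > fwd[, "score"]
    m <- fwd
    m[use_rev, ] <- rev_[use_rev, ]
    ok <- m[, "score"] >= 0
    identity <- ifelse(ok, m[, "matches"] / pmax(m[, "cols"], 1), 0)
    coverage <- ifelse(ok, (m[, "qend"] - m[, "qstart"]) / fragment_len, 0)
    keep <- ok & identity >= 0.30 & coverage >= 0.70
    list(ani = if (any(keep)) mean(identity[keep]) * 100 else NA_real_,
         n_used = sum(keep), frac = sum(keep) / length(frags))
  }
  d1 <- directed(sa, sb)
  d2 <- directed(sb, sa)
  tibble(genome_a = ida, genome_b = idb,
         ani = mean(c(d1$ani, d2$ani)),
         n_fragments_used = d1$n_used + d2$n_used,
         fraction_aligned = mean(c(d1$frac, d2$frac)))
}

#' All-pairs ANI table for a set of genomes
#'
#' @param replicons named list of [replicon()]s or sequences.
#' @param ... passed to [compute_ani()].
#' @return tibble of pairwise ANI rows (unordered pairs).
#' @export
ani_matrix <- function(replicons, ...) {
  ids <- names(replicons) %||% vapply(replicons, seq_id, character(1), "x")
  n <- length(replicons)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      r <- compute_ani(replicons[[i]], replicons[[j]], ...)
      r$genome_a <- ids[i]
      r$genome_b <- ids[j]
      rows[[length(rows) + 1L]] <- r
    }
  }
  bind_rows(rows)
}

#' Cluster genomes into genospecies at an ANI threshold
#'
#' Single-linkage: genomes joined whenever their symmetrised ANI reaches the
#' threshold; genospecies are the connected components, labelled `GS1`,
#' `GS2`, ... in order of their smallest member id.
#'
#' @param ani a tibble of pairwise rows (genome_a, genome_b, ani) as
#'   produced by [ani_matrix()], or a symmetric numeric matrix with
#'   dimnames.
#' @param threshold ANI percent threshold (default 95, the conventional
#'   species boundary).
#' @return tibble with columns `genome` and `genospecies`.
#' @export
cluster_genospecies <- function(ani, threshold = 95) {
  if (is.matrix(ani)) {
    ids <- rownames(ani)
    idx <- which(upper.tri(ani), arr.ind = TRUE)
    ani <- tibble(genome_a = ids[idx[, 1]], genome_b = ids[idx[, 2]],
                  ani = ani[idx])
  }
  ids <- sort(unique(c(ani$genome_a, ani$genome_b)))
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  keep <- !is.na(ani$ani) & ani$ani >= threshold
  if (any(keep)) {
    g <- igraph::add_edges(g, rbind(match(ani$genome_a[keep], ids),
                                    match(ani$genome_b[keep], ids)))
  }
  comp <- igraph::components(g)
  member <- split(ids, comp$membership)
  ord <- order(vapply(member, min, character(1)))
  labels <- character(length(ids))
  for (k in seq_along(ord)) {
    labels[ids %in% member[[ord[k]]]] <- paste0("GS", k)
  }
  tibble(genome = ids, genospecies = labels)
}

# per-query best hits of query proteins against one proteome
# returns tibble(query_id, target_id, score, identity, coverage)
protein_hits <- function(queries, targets, p) {
  stopifnot(length(names(queries)) == length(queries),
            length(names(targets)) == length(targets))
  rows <- list()
  for (j in seq_along(targets)) {
    m <- sw_map(queries, targets[[j]], p)
    ok <- m[, "score"] >= p$min_score
    if (!any(ok)) next
    rows[[length(rows) + 1L]] <- tibble(
      query_id = names(queries)[ok], target_id = names(targets)[j],
      score = m[ok, "score"],
      identity = m[ok, "matches"] / pmax(m[ok, "cols"], 1),
      coverage = (m[ok, "qend"] - m[ok, "qstart"]) / nchar(queries)[ok])
  }
  if (length(rows) == 0L) {
    return(tibble(query_id = character(), target_id = character(),
                  score = numeric(), identity = numeric(),
                  coverage = numeric()))
  }
  bind_rows(rows)
}

best_hit_per_query <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  hits |>
    arrange(desc(score), target_id) |>
    group_by(query_id) |>
    slice(1L) |>
    ungroup()
}

#' Protein-sharing similarity network among elements
#'
#' All-versus-all protein comparison across elements: a protein pair is a
#' shared protein when the best hit between the two elements reaches
#' `min_identity` over at least `min_coverage` of the query. Edge weight is
#' the number of distinct shared protein pairs; nodes without edges are
#' retained as singletons.
#'
#' @param proteomes named list of named character vectors (element ->
#'   proteins).
#' @param min_identity amino-acid identity threshold (default 0.90).
#' @param min_coverage query coverage threshold (default 0.70).
#' @param params amino-acid [align_params()].
#' @return object of class `sharing_network`: list with `nodes`, `edges`
#'   (a, b, weight), `components` tibble and the igraph object.
#' @export
build_sharing_network <- function(proteomes, min_identity = 0.90,
                                  min_coverage = 0.70, params = NULL) {
  p <- params %||% align_params("aa")
  ids <- names(proteomes)
  stopifnot(!is.null(ids))
  edges <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i == j) next
      if (length(proteomes[[i]]) == 0L || length(proteomes[[j]]) == 0L) next
      hits <- protein_hits(proteomes[[i]], proteomes[[j]], p) |>
        best_hit_per_query() |>
        filter(identity >= min_identity, coverage >= min_coverage)
      if (nrow(hits) == 0L) next
      a <- min(ids[i], ids[j]); b <- max(ids[i], ids[j])
      # unordered protein pair keys so reciprocal hits are not double-counted
      pair_key <- if (ids[i] < ids[j]) {
        paste(hits$query_id, hits$target_id, sep = "\r")
      } else {
        paste(hits$target_id, hits$query_id, sep = "\r")
      }
      edges[[paste(a, b, sep = "\r")]] <-
        union(edges[[paste(a, b, sep = "\r")]], pair_key)
    }
  }
  edge_tbl <- if (length(edges)) {
    tibble(key = names(edges), weight = unname(lengths(edges))) |>
      tidyr::separate(key, c("a", "b"), sep = "\r")
  } else tibble(a = character(), b = character(), weight = integer())
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(edge_tbl) > 0L) {
    g <- igraph::add_edges(g, rbind(match(edge_tbl$a, ids),
                                    match(edge_tbl$b, ids)))
    g <- igraph::set_edge_attr(g, "weight", value = edge_tbl$weight)
  }
  comp <- igraph::components(g)
  member <- split(ids, comp$membership)
  ord <- order(vapply(member, min, character(1)))
  comp_tbl <- bind_rows(lapply(seq_along(ord), function(k) {
    tibble(element = sort(member[[ord[k]]]), component = k)
  }))
  structure(list(nodes = tibble(element = ids), edges = edge_tbl,
                 components = comp_tbl, graph = g),
            class = "sharing_network")
}

#' @export
print.sharing_network <- function(x, ...) {
  cat(sprintf("<sharing_network> %d nodes, %d edges, %d components\n",
              nrow(x$nodes), nrow(x$edges),
              max(c(0L, x$components$component))))
  invisible(x)
}

#' @rdname build_sharing_network
#' @param x a `sharing_network`.
#' @param ... unused.
#' @method tidy sharing_network
#' @export
tidy.sharing_network <- function(x, ...) x$edges

#' @rdname build_sharing_network
#' @method glance sharing_network
#' @export
glance.sharing_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_components = max(c(0L, x$components$component)),
         total_weight = sum(x$edges$weight))
}

#' Scan target proteomes for homologs of a query protein set
#'
#' Each query protein is counted at most once per target proteome (best hit
#' only), emulating protein-level homolog counting between plasmids and
#' chromosomes.
#'
#' @param query_proteins named character vector of protein sequences.
#' @param target_proteomes named list of named character vectors.
#' @param min_identity identity threshold (0.70 for the plasmid/chromosome
#'   scan, 0.50 for the chromid/chromosome scan).
#' @param min_coverage query coverage threshold (default 0.70).
#' @param params amino-acid [align_params()].
#' @return list with `counts` (tibble target, n_homologs) and `hits` (full
#'   best-hit table).
#' @export
homolog_scan <- function(query_proteins, target_proteomes, min_identity = 0.70,
                         min_coverage = 0.70, params = NULL) {
  p <- params %||% align_params("aa")
  rows <- list()
  for (tname in names(target_proteomes)) {
    tp <- target_proteomes[[tname]]
    if (length(tp) == 0L || length(query_proteins) == 0L) {
      rows[[tname]] <- tibble(query_id = character(), target_id = character(),
                              score = numeric(), identity = numeric(),
                              coverage = numeric())
      next
    }
    hits <- protein_hits(query_proteins, tp, p) |>
      best_hit_per_query() |>
      filter(identity >= min_identity, coverage >= min_coverage)
    hits$target <- rep(tname, nrow(hits))
    rows[[tname]] <- hits
  }
  hits <- bind_rows(rows)
  counts <- tibble(target = names(target_proteomes),
                   n_homologs = vapply(names(target_proteomes), function(tn) {
                     if (nrow(hits) == 0L) 0L else
                       sum(hits$target == tn, na.rm = TRUE)
                   }, integer(1)))
  list(counts = counts, hits = hits)
}
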