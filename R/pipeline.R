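#' Pipeline configuration
#'
#' Collects inputs and stage thresholds for [run_pipeline()]. The defaults
#' are the analysis' standard operating points: genospecies at ANI 95,
#' protein network at 90% identity / 70% coverage, homolog scans at 70%
#' (plasmid vs chromosome) and 50% (chromid vs chromosome), recruitment at
#' 99%/70% with the relaxed 95% chromid cutoff, 1000-bp SNP windows and
#' 500-bp minimum core blocks.
#'
#' @param replicons named list of [replicon()]s.
#' @param reads optional read tibble (see [generate_metagenome()]).
#' @param rules marker rule table.
#' @param out_dir output directory (created if needed).
#' @param seed global seed; per-stage seeds are derived by stable hashing
#'   of stage names.
#' @param ani_threshold,network_min_identity,network_min_coverage,
#'   homolog_min_identity,chromid_min_identity,recruit_min_identity,
#'   recruit_min_fraction,chromid_recruit_identity,snp_window,min_core_block
#'   stage thresholds.
#' @param skip character vector of stage names to skip (any of "ani",
#'   "network", "mobility", "defense", "core_phylogeny", "ice_core",
#'   "composition", "recruitment").
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(replicons, reads = NULL,
                            rules = default_marker_rules(),
                            out_dir = tempfile("mobilomics_"), seed = 1L,
                            ani_threshold = 95,
                            network_min_identity = 0.90,
                            network_min_coverage = 0.70,
                            homolog_min_identity = 0.70,
                            chromid_min_identity = 0.50,
                            recruit_min_identity = 0.99,
                            recruit_min_fraction = 0.70,
                            chromid_recruit_identity = 0.95,
                            snp_window = 1000L,
                            min_core_block = 500L,
                            skip = character()) {
  stopifnot(length(replicons) >= 1L, !is.null(names(replicons)))
  thr <- c(ani_threshold, 100 * network_min_identity,
           100 * network_min_coverage, 100 * homolog_min_identity,
           100 * chromid_min_identity, 100 * recruit_min_identity,
           100 * recruit_min_fraction, 100 * chromid_recruit_identity)
  stopifnot(all(thr > 0 & thr <= 100))
  structure(list(replicons = replicons, reads = reads, rules = rules,
                 out_dir = out_dir, seed = as.integer(seed),
                 ani_threshold = ani_threshold,
                 network_min_identity = network_min_identity,
                 network_min_coverage = network_min_coverage,
                 homolog_min_identity = homolog_min_identity,
                 chromid_min_identity = chromid_min_identity,
                 recruit_min_identity = recruit_min_identity,
                 recruit_min_fraction = recruit_min_fraction,
                 chromid_recruit_identity = chromid_recruit_identity,
                 snp_window = as.integer(snp_window),
                 min_core_block = as.integer(min_core_block),
                 skip = skip),
            class = "pipeline_config")
}

config_echo <- function(config) {
  keep <- setdiff(names(config), c("replicons", "reads", "rules"))
  c(config[keep],
    list(replicons = names(config$replicons),
         n_reads = if (is.null(config$reads)) 0L else
           length(read_seqs(config$reads))))
}

#' Run the full comparative mobilome pipeline
#'
#' Chains the analysis stages on a set of replicons: ANI + genospecies,
#' protein-sharing network, mobility classification, defense scans
#' (TA/RM, CRISPR, tRNA-island hallmarks), core phylogeny, ICE core /
#' variable regions / SNP windows, composition + chromid diagnosis, and
#' (when reads are supplied) fragment recruitment. Every stage writes its
#' tables under `config$out_dir` and is listed in the returned manifest; a
#' stage failure aborts with the stage name, earlier outputs preserved.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with per-stage results, `manifest` tibble and the
#'   echoed config.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  reps <- config$replicons
  roles <- vapply(reps, function(r) r$role, character(1))
  manifest <- list()
  results <- list()
  emit <- function(stage, name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    manifest[[length(manifest) + 1L]] <<- tibble(stage = stage, file = name)
  }
  stage <- function(name, fn) {
    if (name %in% config$skip) return(invisible())
    res <- tryCatch(fn(), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    results[[name]] <<- res
    invisible()
  }
  chromosomes <- reps[roles %in% c("chromosome")]
  elements <- reps[roles %in% c("plasmid", "ICE", "chromid")]
  ices <- reps[roles == "ICE"]

  stage("ani", function() {
    if (length(chromosomes) < 2L) return(NULL)
    am <- ani_matrix(chromosomes)
    cl <- cluster_genospecies(am, config$ani_threshold)
    emit("ani", "ani.tsv", function(p) write_tsv_plain(am, p))
    emit("ani", "genospecies.tsv", function(p) write_tsv_plain(cl, p))
    list(ani = am, genospecies = cl)
  })
  stage("network", function() {
    if (length(elements) < 2L) return(NULL)
    prots <- lapply(elements, proteome)
    net <- build_sharing_network(prots, config$network_min_identity,
                                 config$network_min_coverage)
    emit("network", "network_edges.tsv", function(p) {
      write_network(net, edges_path = p)
    })
    emit("network", "network.graphml", function(p) {
      write_network(net, graphml_path = p)
    })
    emit("network", "network_components.tsv", function(p) {
      write_tsv_plain(net$components, p)
    })
    net
  })
  stage("mobility", function() {
    if (length(elements) == 0L) return(NULL)
    calls <- bind_rows(lapply(elements, classify_mobility,
                              rules = config$rules))
    emit("mobility", "mobility.tsv", function(p) write_tsv_plain(calls, p))
    calls
  })
  stage("defense", function() {
    inv <- lapply(reps, scan_ta_rm, rules = config$rules)
    ta <- bind_rows(lapply(names(inv), function(n) {
      if (nrow(inv[[n]]$ta)) mutate(inv[[n]]$ta, replicon = n, .before = 1)
      else NULL
    }))
    rm_ <- bind_rows(lapply(names(inv), function(n) {
      if (nrow(inv[[n]]$rm)) mutate(inv[[n]]$rm, replicon = n, .before = 1)
      else NULL
    }))
    cr <- bind_rows(lapply(names(reps), function(n) {
      d <- detect_crispr(reps[[n]])
      if (nrow(d)) mutate(d, replicon = n, .before = 1) else NULL
    }))
    td <- bind_rows(lapply(names(reps), function(n) {
      d <- detect_trna_duplication(reps[[n]])
      if (nrow(d)) mutate(d, replicon = n, .before = 1) else NULL
    }))
    emit("defense", "ta_loci.tsv", function(p) write_tsv_plain(ta, p))
    emit("defense", "rm_systems.tsv", function(p) write_tsv_plain(rm_, p))
    emit("defense", "crispr_arrays.tsv", function(p) write_tsv_plain(cr, p))
    emit("defense", "trna_islands.tsv", function(p) write_tsv_plain(td, p))
    list(ta = ta, rm = rm_, crispr = cr, trna_islands = td)
  })
  stage("core_phylogeny", function() {
    if (length(chromosomes) < 3L) return(NULL)
    prots <- lapply(chromosomes, proteome)
    og <- find_orthologs(prots)
    ca <- align_core_and_concatenate(og, prots)
    D <- distance_matrix(ca, "Poisson")
    tr <- neighbor_joining(D)
    emit("core_phylogeny", "core_distances.tsv", function(p) {
      write_distance_matrix(D, tsv_path = p)
    })
    emit("core_phylogeny", "core_distances.phy", function(p) {
      write_distance_matrix(D, phylip_path = p)
    })
    emit("core_phylogeny", "core_tree.nwk", function(p) {
      ape::write.tree(tr, p)
    })
    emit("core_phylogeny", "core_alignment.fasta", function(p) {
      write_fasta(ca$aln, p)
    })
    list(groups = og, alignment = ca, distances = D, tree = tr)
  })
  stage("ice_core", function() {
    if (length(ices) < 2L) return(NULL)
    core <- extract_ice_core(ices, min_block = config$min_core_block)
    emit("ice_core", "ice_core_blocks.tsv", function(p) {
      write_tsv_plain(core$core_blocks, p)
    })
    emit("ice_core", "ice_core_summary.tsv", function(p) {
      write_tsv_plain(glance(core), p)
    })
    pairs <- utils::combn(names(ices), 2)
    prof <- list()
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      g <- align_genomes(ices[[a]], ices[[b]])
      sw <- snp_windows(g, config$snp_window)
      prof[[paste(a, b, sep = "|")]] <- mutate(sw, pair = paste(a, b, sep = "|"),
                                               .before = 1)
    }
    emit("ice_core", "ice_snp_windows.tsv", function(p) {
      write_tsv_plain(bind_rows(prof), p)
    })
    list(core = core, snp_windows = bind_rows(prof))
  })
  stage("composition", function() {
    if (length(elements) == 0L) return(NULL)
    comps <- lapply(elements, composition)
    emit("composition", "composition.tsv", function(p) {
      write_tsv_plain(bind_rows(lapply(comps, glance)), p)
    })
    chromid <- NULL
    if (length(chromosomes) >= 1L && length(elements) >= 1L) {
      big_el <- elements[[which.max(vapply(elements, length, numeric(1)))]]
      big_ch <- chromosomes[[which.max(vapply(chromosomes, length,
                                              numeric(1)))]]
      chromid <- diagnose_chromid(big_el, big_ch, config$rules)
      emit("composition", "chromid_check.tsv", function(p) {
        write_tsv_plain(chromid, p)
      })
    }
    list(composition = comps, chromid = chromid)
  })
  stage("recruitment", function() {
    if (is.null(config$reads)) return(NULL)
    pars <- recruit_params(config$recruit_min_identity,
                           config$recruit_min_fraction)
    panel <- recruit_panel(config$reads, reps, params = pars)
    emit("recruitment", "recruitment.tsv", function(p) {
      write_tsv_plain(panel$summary, p)
    })
    panel
  })
  manifest_tbl <- if (length(manifest)) bind_rows(manifest) else
    tibble(stage = character(), file = character())
  echo <- config_echo(config)
  jsonlite::write_json(list(config = echo,
                            outputs = manifest_tbl$file,
                            stages = unique(manifest_tbl$stage)),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest_tbl <- bind_rows(manifest_tbl,
                            tibble(stage = "manifest", file = "manifest.json"))
  results$manifest <- manifest_tbl
  results$config <- echo
  invisible(results)
}
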