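#' Pipeline configuration
#'
#' Bundles per-stage parameter blocks, the global seed and the output
#' directory for [run_pipeline()].  Unknown keys in any block are rejected
#' up front, and the validated config is serialized into the output
#' directory for provenance.
#'
#' @param synth A [sixvp_sim_config()] describing the synthetic inputs.
#' @param cluster List: `targets` (tree-growth levels), `min_size`.
#' @param enrich List: `alpha`, `simrel_threshold`.
#' @param control List: `size`, `reps` for the random-control profile.
#' @param phenogram List: `metric`, `min_genes`, `max_genes`.
#' @param seed Global seed; per-stage child seeds are derived from it by a
#'   stable hash of the stage name.
#' @param out_dir Output directory.
#' @return A validated list of class `sixvp_pipeline_config`.
#' @export
sixvp_pipeline_config <- function(synth = sixvp_sim_config(),
                                  cluster = list(),
                                  enrich = list(),
                                  control = list(),
                                  phenogram = list(),
                                  seed = 7L,
                                  out_dir = tempfile("sixvp_run_")) {
  defaults <- list(
    cluster = list(targets = c(10L, 15L, 20L), min_size = 5L),
    enrich = list(alpha = 0.001, simrel_threshold = 0.7),
    control = list(size = 50L, reps = 1000L),
    phenogram = list(metric = "euclidean", min_genes = 5L, max_genes = 275L)
  )
  merge_block <- function(name, user) {
    base <- defaults[[name]]
    unknown <- setdiff(names(user), names(base))
    if (length(unknown)) {
      stop(sprintf("unknown key(s) in '%s' block: %s", name,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    utils::modifyList(base, user)
  }
  stopifnot(inherits(synth, "sixvp_sim_config"))
  structure(
    list(synth = synth,
         cluster = merge_block("cluster", cluster),
         enrich = merge_block("enrich", enrich),
         control = merge_block("control", control),
         phenogram = merge_block("phenogram", phenogram),
         seed = as.integer(seed),
         out_dir = out_dir),
    class = "sixvp_pipeline_config"
  )
}

## stable, platform-independent child seed from the global seed + stage name
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.double(seed) * 7919 + h) %% 2147483647)
}

#' Run the full analysis pipeline on synthetic fixtures
#'
#' Chains every stage end to end: synthetic clade generation, per-variable
#' harmonization, rank profiles with a random control band, SOTA clustering
#' at several levels, GO enrichment with FDR and semantic de-duplication,
#' complex-vs-GO pair-distance statistics, Bayesian model averaging of PA on
#' the other variables, and NJ/UPGMA phenograms from GO-term-level profiles.
#' All artifacts are written under `config$out_dir` together with a
#' manifest (stage, parameters, output files with MD5 hashes, wall time).
#' Reruns with the same config and seed reproduce identical output hashes.
#'
#' @param config A [sixvp_pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest; side effect: files under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "sixvp_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  results <- list()
  log_stage <- function(name, params, files) {
    manifest[[length(manifest) + 1L]] <<- list(
      stage = name, parameters = params,
      outputs = lapply(files, function(f) {
        list(path = basename(f), md5 = unname(tools::md5sum(f)))
      }),
      elapsed_s = round(as.numeric(proc.time()["elapsed"]) - t0, 3)
    )
  }
  cfg_path <- file.path(config$out_dir, "pipeline_config.json")
  jsonlite::write_json(serialize_config(config), cfg_path, auto_unbox = TRUE,
                       pretty = TRUE)

  ## 1. synth ---------------------------------------------------------------
  t0 <- as.numeric(proc.time()["elapsed"])
  synth_cfg <- config$synth
  synth_cfg$seed <- stage_seed(config$seed, "synth")
  clade <- generate_clade(synth_cfg)
  results$clade <- clade
  synth_files <- character(0)
  for (o in names(clade$organisms)) {
    for (v in SIXVP_VARIABLES) {
      for (t in clade$organisms[[o]]$tables[[v]]) {
        f <- file.path(config$out_dir, paste0(t$source_id, ".tsv"))
        write_expression_table(t, f)
        synth_files <- c(synth_files, f)
      }
    }
  }
  obo_path <- file.path(config$out_dir, "toy_go.obo")
  write_obo(clade$graph, obo_path)
  ann_path <- file.path(config$out_dir, "annotations.tsv")
  write_annotations(clade$annotations, ann_path)
  log_stage("synth", list(seed = synth_cfg$seed,
                          n_genes = synth_cfg$n_genes),
            c(synth_files[1L], obo_path, ann_path))

  ## 2. harmonize ------------------------------------------------------------
  t0 <- as.numeric(proc.time()["elapsed"])
  matrices <- list()
  harm_files <- character(0)
  for (o in names(clade$organisms)) {
    merged <- lapply(SIXVP_VARIABLES, function(v) {
      harmonize_variable(clade$organisms[[o]]$tables[[v]])$table
    })
    matrices[[o]] <- six_variable_matrix(merged, organism = o)
    f <- file.path(config$out_dir, paste0("matrix_", o, ".tsv"))
    write_sixvp_matrix(matrices[[o]], f)
    harm_files <- c(harm_files, f)
  }
  results$matrices <- matrices
  log_stage("harmonize", list(), harm_files)

  ## 3. profile --------------------------------------------------------------
  t0 <- as.numeric(proc.time()["elapsed"])
  ranks <- list()
  for (o in names(matrices)) {
    keep <- filter_genes(matrices[[o]])
    ranks[[o]] <- rank_matrix(matrices[[o]][keep, , drop = FALSE])
  }
  results$ranks <- ranks
  ref <- clade$reference
  ctrl <- random_control(ranks[[ref]], size = config$control$size,
                         reps = config$control$reps,
                         seed = stage_seed(config$seed, "control"))
  results$control <- ctrl
  ctrl_path <- file.path(config$out_dir, "random_control.json")
  jsonlite::write_json(ctrl, ctrl_path, auto_unbox = TRUE, digits = 10)
  log_stage("profile", config$control, ctrl_path)

  ## 4. cluster --------------------------------------------------------------
  t0 <- as.numeric(proc.time()["elapsed"])
  complete <- impute_knn(unclass(ranks[[ref]]))
  cluster_sets <- lapply(config$cluster$targets, function(k) {
    sota_cluster(complete, target_clusters = k,
                 min_size = config$cluster$min_size,
                 seed = stage_seed(config$seed, paste0("cluster", k)))
  })
  results$cluster_sets <- cluster_sets
  clus_path <- file.path(config$out_dir, "clusters.json")
  jsonlite::write_json(lapply(cluster_sets, function(cs) {
    list(level = cs$level, clusters = cs$clusters)
  }), clus_path, auto_unbox = TRUE)
  log_stage("cluster", config$cluster, clus_path)

  ## 5. enrich ---------------------------------------------------------------
  t0 <- as.numeric(proc.time()["elapsed"])
  graph <- clade$graph
  anns <- clade$annotations
  enr <- lapply(cluster_sets, function(cs) {
    e <- enrich_clusters(cs$clusters, anns, graph)
    e$level <- cs$level
    e
  })
  enr <- do.call(rbind, enr)
  sig <- significant_terms(enr, alpha = config$enrich$alpha)
  ic <- information_content(graph, anns)
  deduped <- sig
  if (nrow(sig) > 0L) {
    by_cluster <- split(sig, paste(sig$level, sig$cluster_id))
    deduped <- do.call(rbind, lapply(by_cluster, function(recs) {
      out <- recs[0L, ]
      for (nsx in unique(recs$namespace)) {
        sub <- recs[recs$namespace == nsx, , drop = FALSE]
        sm <- simrel_matrix(unique(sub$term_id), ic, graph)
        out <- rbind(out, dedupe_by_similarity(
          sub, sm, threshold = config$enrich$simrel_threshold))
      }
      out
    }))
    rownames(deduped) <- NULL
  }
  results$enrichment <- enr
  results$significant <- deduped
  enr_path <- file.path(config$out_dir, "enrichment.tsv")
  utils::write.table(enr, enr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("enrich", config$enrich, enr_path)

  ## 6. pairdist -------------------------------------------------------------
  t0 <- as.numeric(proc.time()["elapsed"])
  ref_org <- generate_organism(synth_cfg, organism = ref)
  go_groups <- anns$direct[grep("^GO:G", names(anns$direct))]
  complexes <- filter_complexes(ref_org$complexes, genes = rownames(complete))
  cls <- classify_pairs(rownames(complete), complexes,
                        lapply(go_groups, intersect, rownames(complete)))
  pstats <- pair_distance_stats(complete, cls)
  results$pair_stats <- pstats
  pair_path <- file.path(config$out_dir, "pair_stats.json")
  jsonlite::write_json(list(summary = pstats$summary, anova = pstats$anova),
                       pair_path, auto_unbox = TRUE, digits = 10)
  log_stage("pairdist", list(), pair_path)

  ## 7. associate ------------------------------------------------------------
  t0 <- as.numeric(proc.time()["elapsed"])
  m <- matrices[[ref]]
  cc <- m[stats::complete.cases(m), , drop = FALSE]
  z <- zscore_matrix(unclass(rank_matrix(cc)))   # rank scale, as elsewhere
  bma <- bma_regression(z[, "PA"],
                        z[, setdiff(SIXVP_VARIABLES, "PA"), drop = FALSE],
                        seed = stage_seed(config$seed, "associate"))
  grid <- pairwise_correlations(m)
  results$bma <- bma
  results$correlations <- grid
  bma_path <- file.path(config$out_dir, "bma.json")
  jsonlite::write_json(list(posterior_mean = as.list(bma$posterior_mean),
                            inclusion_prob = as.list(bma$inclusion_prob)),
                       bma_path, auto_unbox = TRUE, digits = 10)
  log_stage("associate", list(), bma_path)

  ## 8. phenogram ------------------------------------------------------------
  t0 <- as.numeric(proc.time()["elapsed"])
  term_genes <- anns$propagated[grep("^GO:G", names(anns$propagated))]
  profiles <- build_go_profiles(ranks, term_genes,
                                ortholog_maps = clade$ortholog_maps,
                                min_genes = config$phenogram$min_genes,
                                max_genes = config$phenogram$max_genes)
  d <- organism_distance(profiles, metric = config$phenogram$metric)
  trees <- list(upgma = upgma_tree(d),
                nj = if (nrow(d) >= 3L) nj_tree(d) else NULL)
  results$profiles <- profiles
  results$trees <- trees
  tree_files <- character(0)
  for (meth in names(trees)) {
    if (is.null(trees[[meth]])) next
    f <- file.path(config$out_dir, paste0("phenogram_", meth, ".nwk"))
    write_newick(trees[[meth]], f)
    tree_files <- c(tree_files, f)
  }
  log_stage("phenogram", config$phenogram, tree_files)

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

serialize_config <- function(config) {
  out <- unclass(config)
  out$synth <- unclass(out$synth)
  out$synth$group_profile_archetypes <-
    apply(out$synth$group_profile_archetypes, 1L, as.list)
  out
}
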