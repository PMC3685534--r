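#' Default end-to-end run configuration
#'
#' @param seed integer seed driving every stochastic step of the run.
#' @return nested list understood by [run_all()]: `simulate` (generate the
#'   coupled synthetic dataset), `synthetic` (overrides for
#'   [synthetic_spec()]), `inputs` (paths to `genes`, `volatiles`, `design`
#'   TSVs when `simulate` is FALSE), `analysis` ([analysis_config()]) and
#'   `stages`.
#' @export
default_run_config <- function(seed = 1L) {
  list(simulate = TRUE,
       seed = as.integer(seed),
       synthetic = list(),
       inputs = list(genes = NULL, volatiles = NULL, design = NULL),
       analysis = analysis_config(rng_seed = seed),
       stages = c("correlate", "cluster", "differential", "pca",
                  "network", "candidates"))
}

.known_config_keys <- c("simulate", "seed", "synthetic", "inputs",
                        "analysis", "stages")
.known_stages <- c("correlate", "cluster", "differential", "pca",
                   "network", "candidates")

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

.write_named_matrix <- function(mat, path, id_col = "feature_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  .write_tsv(df, path)
}

#' Run the full integrative analysis
#'
#' Orchestrates the pipeline on either a simulated or a user-supplied
#' dataset: all-pairs correlation, joint hierarchical clustering, SAM and
#' volatile t-tests for the shelf-life contrast in each genotype with a
#' Venn partition, PCA, volatile and merged correlation networks (primary
#' cutoff plus a secondary, lower cutoff restricted to volatiles left
#' unconnected by the primary one), and multi-evidence candidate selection
#' with annotation-based exclusions. Writes TSV/Newick/SIF/GraphML/JSON
#' outputs plus a reproducibility manifest (config snapshot, seed, output
#' checksums, stage timings). Identical config and seed reproduce every
#' output byte-for-byte; the manifest itself carries wall-clock timings and
#' is excluded from that contract.
#'
#' @param config list from [default_run_config()] (possibly modified), or a
#'   path to a JSON file with the same structure. Unknown keys are errors.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the main in-memory results and the output
#'   inventory.
#' @export
run_all <- function(config, out_dir) {
  if (is.character(config))
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  base <- default_run_config(if (is.null(config$seed)) 1L else config$seed)
  unknown <- setdiff(names(config), .known_config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(base, config)
  if (!inherits(cfg$analysis, "analysis_config"))
    cfg$analysis <- do.call(analysis_config, as.list(cfg$analysis))
  bad_stage <- setdiff(cfg$stages, .known_stages)
  if (length(bad_stage))
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "))
  ac <- cfg$analysis
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  outputs <- character(0)
  tick <- function(stage) {
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    t0 <<- proc.time()[["elapsed"]]
  }
  emit <- function(name) outputs <<- c(outputs, name)

  # ---- inputs -------------------------------------------------------------
  if (isTRUE(cfg$simulate)) {
    syn <- cfg$synthetic
    syn$rng_seed <- cfg$seed
    spec <- do.call(synthetic_spec, syn)
    ds <- generate_dataset(spec)
    genes <- ds$genes; volatiles <- ds$volatiles
    write_matrix(genes, file.path(out_dir, "genes.tsv")); emit("genes.tsv")
    write_matrix(volatiles, file.path(out_dir, "volatiles.tsv"))
    emit("volatiles.tsv")
    .write_tsv(genes$samples, file.path(out_dir, "design.tsv"))
    emit("design.tsv")
    jsonlite::write_json(
      list(volatile_archetype = as.list(ds$truth$volatile_archetype),
           planted = ds$truth$planted,
           responder_ids = ds$truth$responder_ids),
      file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE,
      digits = NA)
    emit("ground_truth.json")
  } else {
    for (field in c("genes", "volatiles", "design"))
      if (is.null(cfg$inputs[[field]]))
        stop("config inputs$", field, " is required when simulate is false")
    design <- read_design(cfg$inputs$design)
    genes <- read_matrix(cfg$inputs$genes, design)
    volatiles <- read_matrix(cfg$inputs$volatiles, design)
    volatiles$features$kind <- "volatile"
  }
  tick("inputs")

  res <- list(config = cfg)
  vol_ids <- rownames(volatiles$values)
  design <- genes$samples

  # ---- correlation --------------------------------------------------------
  cs <- pearson_all_pairs(genes, volatiles)
  topk <- lapply(vol_ids, function(v)
    top_k_correlated(cs, v, k = ac$top_k))
  names(topk) <- vol_ids
  if ("correlate" %in% cfg$stages) {
    .write_named_matrix(round(cs$gene_vol, 10),
                        file.path(out_dir, "correlations.tsv"), "gene_id")
    emit("correlations.tsv")
    long <- do.call(rbind, lapply(vol_ids, function(v)
      cbind(volatile_id = v, topk[[v]])))
    .write_tsv(long, file.path(out_dir, "top_correlated.tsv"))
    emit("top_correlated.tsv")
  }
  res$correlations <- cs
  tick("correlate")

  # ---- clustering ---------------------------------------------------------
  vol_tree <- hca_complete(correlation_distance(volatiles,
                                                missing = "impute"))
  vol_cl_int <- cut_by_similarity(vol_tree, ac$hca_cluster_sim)
  volatile_clusters <- stats::setNames(sprintf("C%d", vol_cl_int),
                                       names(vol_cl_int))
  joint_vals <- rbind(genes$values, volatiles$values)
  joint_tree <- hca_complete(correlation_distance(joint_vals,
                                                  missing = "impute"))
  hca_ev <- co_clustered_genes(joint_tree, vol_ids, ac$hca_cluster_sim)
  if ("cluster" %in% cfg$stages) {
    export_newick(joint_tree, file.path(out_dir, "joint_tree.nwk"))
    emit("joint_tree.nwk")
    .write_tsv(data.frame(volatile_id = names(volatile_clusters),
                          cluster = unname(volatile_clusters)),
               file.path(out_dir, "volatile_clusters.tsv"))
    emit("volatile_clusters.tsv")
    assign_df <- do.call(rbind, lapply(names(hca_ev), function(k)
      data.frame(group = k,
                 volatiles = paste(hca_ev[[k]]$volatiles, collapse = ";"),
                 genes = paste(hca_ev[[k]]$genes, collapse = ";"),
                 stringsAsFactors = FALSE)))
    .write_tsv(assign_df, file.path(out_dir, "co_clustered_genes.tsv"))
    emit("co_clustered_genes.tsv")
  }
  res$joint_tree <- joint_tree
  res$volatile_clusters <- volatile_clusters
  tick("cluster")

  # ---- differential -------------------------------------------------------
  if ("differential" %in% cfg$stages) {
    stages_all <- unique(design$stage)
    last2 <- utils::tail(stages_all, 2L)   # harvest-ripe vs shelf-life
    sams <- list()
    for (g in unique(design$genotype)) {
      sel <- design$genotype == g & design$stage %in% last2
      sub <- genes$values[, design$sample_id[sel], drop = FALSE]
      grp <- factor(design$stage[sel], levels = last2)
      sams[[g]] <- sam_two_class(sub, grp, fdr_target = ac$sam_fdr,
                                 seed = ac$rng_seed)
      .write_tsv(sams[[g]],
                 file.path(out_dir, sprintf("sam_%s.tsv", g)))
      emit(sprintf("sam_%s.tsv", g))
      vsub <- volatiles$values[, design$sample_id[sel], drop = FALSE]
      tt <- ttest_volatiles(vsub, grp, alpha = ac$ttest_alpha)
      .write_tsv(tt, file.path(out_dir, sprintf("ttest_volatiles_%s.tsv", g)))
      emit(sprintf("ttest_volatiles_%s.tsv", g))
    }
    if (length(sams) == 2L) {
      vp <- venn_partition(sams[[1L]], sams[[2L]])
      jsonlite::write_json(vp, file.path(out_dir, "venn.json"),
                           auto_unbox = TRUE, digits = NA)
      emit("venn.json")
      res$venn <- vp
    }
    res$sam <- sams
  }
  tick("differential")

  # ---- pca ----------------------------------------------------------------
  if ("pca" %in% cfg$stages) {
    for (what in c("volatiles", "genes")) {
      mm <- if (what == "volatiles") volatiles else genes
      vals <- mm$values
      if (anyNA(vals)) {
        rm_ <- rowMeans(vals, na.rm = TRUE)
        idx <- which(is.na(vals), arr.ind = TRUE)
        vals[idx] <- rm_[idx[, 1L]]
      }
      pr <- pca_samples(vals, n_components = min(5L, min(dim(vals))))
      .write_named_matrix(round(pr$scores, 10),
                          file.path(out_dir,
                                    sprintf("pca_scores_%s.tsv", what)),
                          "sample_id")
      emit(sprintf("pca_scores_%s.tsv", what))
      .write_tsv(data.frame(component = seq_along(pr$var_explained),
                            var_explained = round(pr$var_explained, 10)),
                 file.path(out_dir, sprintf("pca_scree_%s.tsv", what)))
      emit(sprintf("pca_scree_%s.tsv", what))
      res$pca[[what]] <- pr
    }
  }
  tick("pca")

  # ---- network ------------------------------------------------------------
  preselected <- preselect_genes(cs, ac$cna_cutoff_primary)
  merged <- build_merged_network(cs, genes, cutoff = ac$cna_cutoff_primary,
                                 preselected = preselected,
                                 floor = ac$voc_edge_floor,
                                 strong = ac$edge_strong,
                                 moderate = ac$edge_moderate)
  if ("network" %in% cfg$stages) {
    voc_net <- build_voc_network(cs, floor = ac$voc_edge_floor,
                                 strong = ac$edge_strong,
                                 moderate = ac$edge_moderate)
    export_sif(voc_net, file.path(out_dir, "voc_network.sif"))
    emit("voc_network.sif")
    export_sif(merged, file.path(out_dir, "merged_network.sif"))
    emit("merged_network.sif")
    export_graphml(merged, file.path(out_dir, "merged_network.graphml"))
    emit("merged_network.graphml")
    topo <- topology(merged, ac$hub_percentile)
    sc <- subclusters(merged, ac$subcluster_sim)
    topo$subcluster <- unname(sc[topo$node])
    .write_tsv(topo, file.path(out_dir, "network_topology.tsv"))
    emit("network_topology.tsv")
    # secondary, lower-cutoff network for volatiles the primary one missed
    e <- merged$edges
    gene_nodes <- merged$nodes$name[merged$nodes$kind == "gene"]
    connected_voc <- unique(c(e$v[e$u %in% gene_nodes],
                              e$u[e$v %in% gene_nodes]))
    orphan_voc <- setdiff(vol_ids, connected_voc)
    if (length(orphan_voc)) {
      pre2 <- preselect_genes(cs, ac$cna_cutoff_secondary, orphan_voc)
      cs2 <- cs
      cs2$gene_vol <- cs$gene_vol[, orphan_voc, drop = FALSE]
      cs2$vol_vol <- cs$vol_vol[orphan_voc, orphan_voc, drop = FALSE]
      net2 <- build_merged_network(cs2, genes,
                                   cutoff = ac$cna_cutoff_secondary,
                                   preselected = pre2,
                                   floor = ac$voc_edge_floor,
                                   strong = ac$edge_strong,
                                   moderate = ac$edge_moderate)
      export_sif(net2, file.path(out_dir, "secondary_network.sif"))
      emit("secondary_network.sif")
      res$secondary_network <- net2
    }
    res$voc_network <- voc_net
    res$topology <- topo
  }
  res$merged_network <- merged
  res$preselected <- preselected
  tick("network")

  # ---- candidates ---------------------------------------------------------
  if ("candidates" %in% cfg$stages) {
    cand <- collect_evidence(hca_ev, topk, merged, volatile_clusters,
                             gene_universe = rownames(genes$values),
                             annotations = genes$features)
    cand <- exclusion_filter(cand, genes$features)
    .write_tsv(cand, file.path(out_dir, "candidates.tsv"))
    emit("candidates.tsv")
    candidate_markdown(cand, file.path(out_dir, "candidates.md"))
    emit("candidates.md")
    res$candidates <- cand
  }
  tick("candidates")

  # ---- manifest -----------------------------------------------------------
  files <- file.path(out_dir, outputs)
  manifest <- list(
    package_version = as.character(utils::packageVersion("volnet")),
    seed = cfg$seed,
    config = list(simulate = cfg$simulate, stages = cfg$stages,
                  analysis = unclass(ac), synthetic = cfg$synthetic),
    outputs = as.list(stats::setNames(unname(tools::md5sum(files)),
                                      outputs)),
    timings_sec = lapply(timings, function(x) round(x, 3)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$outputs <- c(outputs, "manifest.json")
  invisible(res)
}
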