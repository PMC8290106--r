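# One-command orchestration: simulate/read -> coiled-coil annotation ->
# orthology -> orthogroup MSAs and profiles (masked and unmasked) ->
# all-vs-all comparisons -> three-seed cladograms with consensus ->
# similarity networks with modularity clustering and sub-clustering.

.stage <- function(name, log_con, expr) {
  .log_line(log_con, "stage ", name, " start")
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' Executes every stage on a synthetic or user-supplied dataset and
#' writes all artifacts under `out_dir`. Identical configuration and
#' seed produce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with the main in-memory results
#'   (`dataset`, `orthology`, `cladograms`, `consensus`,
#'   `cluster_consensus`, `graph_masked`, `partition_masked`,
#'   `subpartition`, `partition_unmasked`, paths).
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(log_con))
  seed <- config$seed
  al <- config$align
  # --- data ---------------------------------------------------------------
  dataset <- .stage("data", log_con, {
    if (config$mode == "simulate") {
      sc <- do.call(sim_config, utils::modifyList(config$sim,
                                                  list(seed = seed)))
      ds <- simulate_dataset(sc)
      write_dataset(ds, file.path(out_dir, "data"))
      ds
    } else {
      read_dataset(config$paths$proteome_dir)
    }
  })
  proteomes <- dataset$proteomes
  seeds <- .stage("seeds", log_con, {
    if (config$mode == "simulate") {
      tr <- dataset$truth[dataset$truth$events == "" &
                            dataset$truth$taxon %in% config$seed_taxa, ]
      data.frame(family = tr$family, seed_taxon = tr$taxon,
                 seed_id = tr$protein_id, stringsAsFactors = FALSE)
    } else {
      read.delim(config$paths$seed_file, sep = "\t",
                 stringsAsFactors = FALSE)
    }
  })
  .log_line(log_con, "data: ", sum(lengths(proteomes)), " proteins in ",
            length(proteomes), " taxa; ", nrow(seeds), " seed records")
  # --- coiled-coil annotation ----------------------------------------------
  cc_masks <- .stage("coiled_coil", log_con, {
    anns <- list()
    for (tx in names(proteomes)) {
      for (pid in names(proteomes[[tx]])) {
        anns[[pid]] <- cc_mask(list(id = pid, seq = proteomes[[tx]][[pid]]),
                               threshold = config$cc$threshold,
                               window = config$cc$window)
      }
    }
    write_cc_table(anns, file.path(out_dir, "cc.tsv"))
    anns
  })
  # --- orthology ------------------------------------------------------------
  ortho <- .stage("orthology", log_con, {
    res <- run_orthology(proteomes, seeds,
                         params = c(config$orthology,
                                    al[c("gap_open", "gap_extend",
                                         "band")],
                                    list(pseudocount =
                                           config$msa$pseudocount,
                                         merge_pseudocount =
                                           config$msa$merge_pseudocount)),
                         seed = child_seed(seed, "orthology"),
                         log_con = log_con)
    write.table(res$per_seed, file.path(out_dir, "orthologs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$combined, file.path(out_dir, "orthologs_combined.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$table, file.path(out_dir, "ortholog_matrix.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    res
  })
  # --- identity / similarity distributions ---------------------------------
  .stage("pairwise_stats", log_con, {
    db <- unlist(unname(proteomes))
    rows <- list()
    ok <- ortho$combined[ortho$combined$status %in%
                           c("reciprocal_ok", "conflict"), ]
    for (i in seq_len(nrow(ok))) {
      fam <- ok$family[i]
      sid <- seeds$seed_id[seeds$family == fam][1L]
      if (is.na(ok$target_id[i]) || ok$target_id[i] == sid) next
      st <- pairwise_stats(pairwise_global_align(
        db[[sid]], db[[ok$target_id[i]]],
        gap_open = al$stats_gap_open, gap_extend = al$stats_gap_extend))
      rows <- c(rows, list(data.frame(
        family = fam, seed_id = sid, target_id = ok$target_id[i],
        identity = st[["identity"]], similarity = st[["similarity"]])))
    }
    idsim <- do.call(rbind, rows)
    write.table(idsim, file.path(out_dir, "identity_similarity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    idsim
  })
  # --- orthogroup MSAs and profiles ----------------------------------------
  fam_profiles <- .stage("profiles", log_con, {
    db <- unlist(unname(proteomes))
    dir.create(file.path(out_dir, "msa"), showWarnings = FALSE)
    dir.create(file.path(out_dir, "profiles"), showWarnings = FALSE)
    masked <- list()
    unmasked <- list()
    msas <- list()
    for (fam in sort(unique(seeds$family))) {
      mem <- unique(c(
        seeds$seed_id[seeds$family == fam],
        ortho$combined$target_id[ortho$combined$family == fam &
                                   ortho$combined$status %in%
                                     c("reciprocal_ok", "conflict")]))
      mem <- mem[!is.na(mem)]
      msa <- progressive_msa(setNames(db[mem], mem),
                             gap_open = al$gap_open,
                             gap_extend = al$gap_extend,
                             pseudocount_weight =
                               config$msa$merge_pseudocount)
      msa <- trim_gappy_columns(msa, config$msa$max_gap_frac)
      msas[[fam]] <- msa
      write_msa(msa, file.path(out_dir, "msa", paste0(fam, ".fasta")))
      unmasked[[fam]] <- build_profile(
        msa, pseudocount_weight = config$msa$pseudocount,
        source_id = fam)
      mk <- lapply(setNames(mem, mem), function(pid) cc_masks[[pid]]$mask)
      masked[[fam]] <- build_profile(
        msa, pseudocount_weight = config$msa$pseudocount, cc_mask = mk,
        source_id = fam)
      write_profile(unmasked[[fam]],
                    file.path(out_dir, "profiles", paste0(fam, ".prof")))
      write_profile(masked[[fam]],
                    file.path(out_dir, "profiles",
                              paste0(fam, "_masked.prof")))
    }
    .log_line(log_con, "profiles: ", length(masked), " orthogroups")
    list(masked = masked, unmasked = unmasked, msas = msas)
  })
  # --- three-seed cladograms and consensus ---------------------------------
  # each analysis compares one profile per family, built from the shared
  # orthogroup alignment restricted to that seed taxon's own validated
  # assignments; distances come from the calibrated comparison weights
  # (min(-log10 P, cap)), the quantity the published matrices cluster
  clado <- .stage("cladograms", log_con, {
    trees <- list()
    common <- NULL
    for (stx in config$seed_taxa) {
      fams <- seeds$family[seeds$seed_taxon == stx]
      common <- if (is.null(common)) fams else intersect(common, fams)
    }
    common <- sort(common)
    hits1 <- NULL
    d_sum <- NULL
    for (a in seq_along(config$seed_taxa)) {
      stx <- config$seed_taxa[a]
      ps <- ortho$per_seed[ortho$per_seed$seed_taxon == stx, ]
      profs <- list()
      for (fam in common) {
        sid <- seeds$seed_id[seeds$seed_taxon == stx &
                               seeds$family == fam]
        mem <- unique(c(sid, ps$target_id[ps$family == fam &
                                            ps$status == "reciprocal_ok" &
                                            !is.na(ps$target_id)]))
        msa <- fam_profiles$msas[[fam]]
        keep <- msa$ids %in% mem
        m <- .msa_char_matrix(new_msa(msa$ids[keep], msa$seqs[keep]))
        nz <- colSums(m != "-") > 0
        sub <- new_msa(msa$ids[keep],
                       apply(m[, nz, drop = FALSE], 1L, paste,
                             collapse = ""))
        profs[[fam]] <- build_profile(
          sub, pseudocount_weight = config$msa$pseudocount,
          source_id = fam)
      }
      hv <- all_vs_all(profs,
                       n_shuffles = min(100L,
                                        config$clustering$n_shuffles),
                       seed = child_seed(seed, paste0("clado", a)),
                       gap_open = al$gap_open, gap_extend = al$gap_extend,
                       band = al$band)
      if (a == 1L) {
        hits1 <- hv
        write_heatmap_matrices(hv, out_dir)
      }
      sm <- score_matrix(hv, value = "weight",
                         weight_cap = config$clustering$weight_cap)
      trees[[stx]] <- hclust_tree(sm$D)
      d_sum <- if (a == 1L) sm$D[order(rownames(sm$D)),
                                 order(rownames(sm$D))]
        else d_sum + sm$D[rownames(d_sum), rownames(d_sum)]
      ape::write.tree(trees[[stx]]$phylo,
                      file.path(out_dir, paste0("tree_", stx, ".nwk")))
    }
    cons <- consensus_cladogram(trees, config$clustering$min_frac)
    ape::write.tree(cons, file.path(out_dir, "consensus.nwk"))
    cc <- consensus_clusters(trees, config$clustering$min_frac,
                             D = d_sum / length(config$seed_taxa))
    write.table(data.frame(family = names(cc$clusters),
                           cluster = cc$clusters),
                file.path(out_dir, "clusters_cladogram.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    .log_line(log_con, "cladograms: ", length(common),
              " common families, ", cc$k, " replicated clusters")
    list(trees = trees, consensus = cons, clusters = cc, hits1 = hits1)
  })
  # --- similarity networks --------------------------------------------------
  nets <- .stage("networks", log_con, {
    cl <- config$clustering
    res <- list()
    for (variant in cl$variants) {
      profs <- fam_profiles[[variant]]
      hv <- all_vs_all(profs, n_shuffles = cl$n_shuffles,
                       seed = child_seed(seed, paste0("net_", variant)),
                       gap_open = al$gap_open, gap_extend = al$gap_extend,
                       band = al$band)
      write.table(hv, file.path(out_dir,
                                paste0("hits_", variant, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      g <- build_graph(hv, p_max = cl$p_max, weight_cap = cl$weight_cap)
      write_edge_list(g, file.path(out_dir,
                                   paste0("edges_", variant, ".tsv")))
      part <- modularity_partition(g, seed = child_seed(seed, variant))
      write_clusters(part, file.path(out_dir,
                                     if (variant == "masked")
                                       "clusters.tsv"
                                     else "clusters_unmasked.tsv"))
      res[[paste0("hits_", variant)]] <- hv
      res[[paste0("graph_", variant)]] <- g
      res[[paste0("partition_", variant)]] <- part
      .log_line(log_con, "network ", variant, ": ",
                igraph::ecount(g), " edges, ", part$n_clusters,
                " clusters, Q = ", format(part$modularity_q, digits = 3))
    }
    # sub-clustering of the largest masked cluster (the merged twin
    # classes in the default model)
    pm <- res$partition_masked
    sizes <- table(pm$membership)
    big <- names(pm$membership)[pm$membership ==
                                  as.integer(names(which.max(sizes)))]
    subp <- subcluster(res$graph_masked, big,
                       seed = child_seed(seed, "subnet"))
    write_clusters(subp, file.path(out_dir, "subclusters.tsv"))
    .log_line(log_con, "subnetwork: ", length(big), " nodes -> ",
              subp$n_clusters, " clusters")
    # top-k / long-alignment variant (complex-level relationships)
    hv4 <- if (!is.null(res$hits_unmasked)) res$hits_unmasked
      else res$hits_masked
    g4 <- build_graph(hv4, p_max = cl$p_max,
                      min_aln_len = cl$min_aln_len, top_k = cl$top_k,
                      weight_cap = cl$weight_cap)
    write_edge_list(g4, file.path(out_dir, "edges_top4.tsv"))
    c(res, list(subpartition = subp, graph_top4 = g4))
  })
  # --- manifest -------------------------------------------------------------
  .stage("manifest", log_con, {
    cfg_path <- file.path(out_dir, "config.yaml")
    save_config(config, cfg_path)
    manifest <- list(
      package = "profhom",
      version = as.character(utils::packageVersion("profhom")),
      seed = seed,
      config_md5 = unname(tools::md5sum(cfg_path)))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  })
  .log_line(log_con, "pipeline complete")
  invisible(list(dataset = dataset, seeds = seeds, orthology = ortho,
                 cladograms = clado$trees, consensus = clado$consensus,
                 cluster_consensus = clado$clusters,
                 graph_masked = nets$graph_masked,
                 partition_masked = nets$partition_masked,
                 subpartition = nets$subpartition,
                 partition_unmasked = nets$partition_unmasked,
                 graph_top4 = nets$graph_top4,
                 out_dir = out_dir))
}

#' Summarise a completed run
#'
#' Reads the artifacts of a [run_pipeline()] output directory and builds
#' the summary tables: ortholog count matrix, identity/similarity
#' distribution, coiled-coil counts, and cluster membership with the
#' per-complex composition check (does each cladogram cluster contain
#' exactly one protein of each full tetramer, and the half-complex
#' members only two clusters).
#'
#' @param out_dir A completed run directory.
#' @return List of data frames: `ortholog_matrix`, `identity_similarity`,
#'   `cc_counts`, `clusters`, `composition` (per complex: clusters hit,
#'   `one_per_cluster` flag).
#' @export
export_report <- function(out_dir) {
  need <- c("ortholog_matrix.tsv", "identity_similarity.tsv", "cc.tsv",
            "clusters.tsv", "clusters_cladogram.tsv")
  missing <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing))
    stop("missing artifacts in ", out_dir, ": ",
         paste(missing, collapse = ", "))
  om <- read.delim(file.path(out_dir, "ortholog_matrix.tsv"),
                   row.names = 1L, check.names = FALSE)
  idsim <- read.delim(file.path(out_dir, "identity_similarity.tsv"))
  ccc <- read.delim(file.path(out_dir, "cc.tsv"))
  cl <- read.delim(file.path(out_dir, "clusters.tsv"), comment.char = "#")
  clc <- read.delim(file.path(out_dir, "clusters_cladogram.tsv"))
  # composition: family ids are complex_class
  fam <- clc$family
  cpx <- sub("_g5[0-9]+$", "", fam)
  comp <- list()
  for (cp in sort(unique(cpx))) {
    cls <- clc$cluster[cpx == cp]
    comp <- c(comp, list(data.frame(
      complex = cp, n_subunits = length(cls),
      n_clusters = length(unique(cls)),
      one_per_cluster = length(cls) == length(unique(cls)),
      stringsAsFactors = FALSE)))
  }
  list(ortholog_matrix = om, identity_similarity = idsim,
       cc_counts = ccc, clusters = cl, cladogram_clusters = clc,
       composition = do.call(rbind, comp))
}
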