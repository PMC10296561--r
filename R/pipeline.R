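# Orchestration: simulate -> subtype -> enrich -> compartments -> lr ->
# ligand activity -> TF network -> causal, from one config and one seed,
# with a manifest (checksums, seeds, stage outputs) and a markdown report.

#' Run the full pipeline on simulated data
#'
#' Executes every stage in dependency order on a synthetic world generated
#' from `seed`, writing per-stage TSV/JSON outputs, a `manifest.json` (input
#' checksums, per-stage seeds and output paths) and a `report.md`. A fixed
#' seed reproduces byte-identical outputs. The single seed is fanned out to
#' the stages by fixed offsets so any stage can be re-run in isolation.
#'
#' @param config an [analysis_config()]; also accepts a path to a JSON file
#'   of overrides
#' @param synth a [synth_config()]
#' @param outdir output directory
#' @param seed master seed
#' @param n_per_subtype,cells_per_subcluster cohort sizes
#' @return the manifest, invisibly
#' @export
run_all <- function(config = analysis_config(), synth = synth_config(),
                    outdir = tempfile("stromacall_run_"), seed = 0L,
                    n_per_subtype = 25L, cells_per_subcluster = 50L) {
  if (is.character(config)) {
    over <- jsonlite::read_json(config, simplifyVector = TRUE)
    config <- do.call(analysis_config, over)
  }
  if (!inherits(config, "stromacall_config")) {
    stopf("config must be an analysis_config() or a JSON path")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  seeds <- stats::setNames(vapply(1:8, function(i) stage_seed(seed, i * 101L),
                                  numeric(1)),
                           c("simulate", "subtype", "enrich", "compartments",
                             "lr", "ligact", "tfnet", "causal"))
  report <- c("# stromacall run report", "")

  # 1. simulate ------------------------------------------------------------
  res <- make_resources(synth, seed = seeds[["simulate"]])
  bundle <- res$bundle; truth <- res$truth
  bulk <- make_bulk(bundle, truth, n_per_subtype, seed = seeds[["simulate"]])
  sc <- make_single_cell(bundle, truth, cells_per_subcluster,
                         seed = seeds[["simulate"]])
  write_expression(bulk$expr, p("bulk_expr.tsv"))
  report <- c(report, sprintf("- simulate: %d genes x %d bulk samples, %d cells",
                              nrow(bulk$expr), ncol(bulk$expr), ncol(sc$cells)))

  # 2. subtype -------------------------------------------------------------
  c1 <- classify_centroid(bulk$expr, bundle$subtype_centroids)
  c2 <- classify_signature_score(bulk$expr, bundle$subtype_signatures)
  calls <- subtype_calls(centroid = c1, signature = c2)
  filt <- consensus_filter(calls)
  utils::write.table(calls, p("subtype_calls.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(filt$summary, p("subtype_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  labels <- filt$labels
  expr_f <- bulk$expr[, filt$retained, drop = FALSE]
  report <- c(report, sprintf("- subtype: retained %d/%d congruent samples",
                              length(filt$retained), ncol(bulk$expr)))

  # 3. enrichment ----------------------------------------------------------
  de <- moderated_de(expr_f, ifelse(labels == "MES", "MES", "rest"),
                     contrast = "MES")
  gsea <- gsea_preranked(de_signature(de), bundle$hallmarks,
                         n_perm = config$n_permutations,
                         seed = seeds[["enrich"]])
  bins <- bin_hallmark_genes(de, bundle$hallmarks, bin = config$logfc_bin)
  ct_scores <- ssgsea(expr_f, bundle$cell_signatures)
  ct_profile <- celltype_profile(ct_scores, labels[colnames(expr_f)])
  utils::write.table(gsea, p("hallmark_gsea.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(bins, p("hallmark_bins.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ct_profile, p("celltype_profile.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report <- c(report, sprintf("- enrich: %d hallmarks tested, %d enriched (padj < 0.05)",
                              nrow(gsea), sum(gsea$p_adjusted < 0.05)))

  # 4. compartments --------------------------------------------------------
  comp <- assign_compartments(sc$cells, bundle$compartment_signatures,
                              sample_ids = sc$annot$sample_id,
                              seed = seeds[["compartments"]])
  utils::write.table(comp$assignments, p("compartment_assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(comp$composition, p("compartment_composition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- c(report, sprintf("- compartments: %d cells assigned",
                              nrow(comp$assignments)))

  # 5. ligand-receptor -----------------------------------------------------
  annot <- filter_subclusters(sc$annot)
  lr <- lr_consensus(sc$cells, annot, bundle$lr_resource,
                     n_perm = config$n_permutations, seed = seeds[["lr"]],
                     threshold = config$lr_rank_threshold)
  sig <- lr[lr$significant, , drop = FALSE]
  major_map <- stats::setNames(bundle$subcluster_info$major_type,
                               bundle$subcluster_info$subcluster)
  net_summary <- summarize_network(sig, major_map)
  utils::write.table(lr, p("lr_interactions.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  report <- c(report, sprintf("- lr: %d significant of %d scored interactions",
                              nrow(sig), nrow(lr)))

  # 6. ligand activity ------------------------------------------------------
  tumour_sub <- bundle$subcluster_info$subcluster[
    bundle$subcluster_info$major_type == "tumour"]
  to_tumour <- sig[sig$receiver %in% tumour_sub, , drop = FALSE]
  cand <- unique(to_tumour$ligand)
  emt <- bundle$hallmarks$HALLMARK_EPITHELIAL_MESENCHYMAL_TRANSITION
  if (length(cand)) {
    act <- ligand_activity(bundle$reg_potential, emt, candidate_ligands = cand)
    cv <- cv_ligand_activity(bundle$reg_potential, emt,
                             candidate_ligands = cand,
                             rounds = config$cv_rounds,
                             folds = config$cv_folds,
                             seed = seeds[["ligact"]])
    act <- merge(act, cv, by = "ligand", sort = FALSE)
    top_lig <- utils::head(act$ligand, config$n_top_ligands)
    enr <- target_enrichment(bundle$reg_potential, top_lig, emt,
                             quantile = config$target_quantile)
    mes_expr <- expr_f[, labels[colnames(expr_f)] == "MES", drop = FALSE]
    hm_scores <- ssgsea(mes_expr, bundle$hallmarks)
    lrh <- corr_lr_hallmark(mes_expr,
                            unique(to_tumour[, c("ligand", "receptor")]),
                            hm_scores)
    utils::write.table(act, p("ligand_activity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(lrh, p("lr_hallmark_correlation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(frac_hallmark_in_top = enr$frac_hallmark_in_top,
           frac_background_in_top = enr$frac_background_in_top,
           fisher_p = enr$fisher_p),
      p("target_enrichment.json"), auto_unbox = TRUE, digits = NA)
    report <- c(report, sprintf(
      "- ligact: %d candidate ligands; top hallmark fraction %.3f (Fisher p = %.3g)",
      length(cand), enr$frac_hallmark_in_top, enr$fisher_p))
  } else {
    act <- data.frame(ligand = character(0), pcc = numeric(0))
    utils::write.table(act, p("ligand_activity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report <- c(report, "- ligact: no tumour-directed significant interactions")
  }

  # 7. TF network -----------------------------------------------------------
  tf_global <- tf_nes(de_signature(de), bundle$regulons,
                      min_targets = config$regulon_min_targets,
                      contrast = "MES_vs_rest")
  cyt <- unique(bundle$tf_cytokine$cytokine)
  comm <- tryCatch(
    assemble_comm_network(
      if (nrow(to_tumour)) to_tumour else sig,
      top_tfs(tf_global, config$n_top_tfs_network),
      bundle$lr_tf, bundle$tf_cytokine,
      de[de$gene %in% cyt, , drop = FALSE]),
    error = function(e) NULL)
  utils::write.table(tf_global, p("tf_activity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(comm)) {
    utils::write.table(comm$edges, p("comm_network_edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(comm$nodes, p("comm_network_nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  report <- c(report, sprintf("- tfnet: %d TFs ranked", nrow(tf_global)))

  # 8. causal ----------------------------------------------------------------
  pkn <- preprocess_pkn(bundle$pkn, min_sources = config$min_sources_pkn)
  pair <- pairwise_tf_nes(expr_f, labels[colnames(expr_f)], bundle$regulons,
                          min_targets = config$regulon_min_targets)
  sols <- list()
  for (ct in unique(pair$contrast)) {
    acts <- top_tfs(pair[pair$contrast == ct, ], config$n_top_tfs_global)
    meas <- data.frame(tf = acts$tf, sign = sign(acts$nes),
                       weight = abs(acts$nes), stringsAsFactors = FALSE)
    meas <- meas[meas$weight > 0, , drop = FALSE]
    sols[[ct]] <- carnival_solve(pkn, meas, bundle$kinase_list,
                                 beta = config$carnival_beta,
                                 lambda = config$carnival_lambda)
  }
  measured_tfs <- unique(pair$tf)
  consensus <- pairwise_consensus(sols, exclude = measured_tfs)
  utils::write.table(consensus, p("consensus_targets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    lapply(sols, function(s) list(state = as.list(s$state),
                                  objective = s$objective)),
    p("causal_solutions.json"), auto_unbox = TRUE, digits = NA)
  report <- c(report, sprintf("- causal: %d consensus target(s): %s",
                              nrow(consensus),
                              paste(consensus$node, collapse = ", ")))

  writeLines(report, p("report.md"))
  outputs <- list.files(outdir, full.names = FALSE)
  outputs <- setdiff(outputs, "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("stromacall")),
    seed = seed, stage_seeds = as.list(seeds),
    config = unclass(config), synth_config = synth,
    n_per_subtype = n_per_subtype,
    cells_per_subcluster = cells_per_subcluster,
    outputs = stats::setNames(
      as.list(unname(tools::md5sum(file.path(outdir, outputs)))), outputs),
    consensus_targets = consensus$node
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
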