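# Synthetic-data generator. Emulates every external input of the analysis
# (bulk cohorts, an annotated single-cell matrix, hallmark and cell-type
# gene sets, a ligand-receptor resource, signed regulons, a signed
# prior-knowledge network, TF-cytokine and ligand-receptor-TF link tables,
# a ligand x gene regulatory-potential matrix and a kinase candidate list)
# with a planted, recoverable kinase -> TF -> target-gene cascade per
# subtype. The generator's defaults ARE the stated world of the test suite;
# they are config-exposed but not tuned per test.

# The 13 single-cell subclusters with their major cell types and the
# compartment each belongs to (tumour = epithelial; fibroblast/endothelial =
# stromal; the rest immune).
subcluster_info <- function() {
  data.frame(
    subcluster = c("Tum_KRT6A", "Tum_KRT14", "FB_RGS5", "FB_COL1A1",
                   "FB_ACTA2", "EC_PECAM1", "M_CCL18", "M_CXCL10",
                   "T_CD8A", "T_FOXP3", "B_MS4A1", "NK_GNLY", "DC_CD1C"),
    major_type = c("tumour", "tumour", "fibroblast", "fibroblast",
                   "fibroblast", "endothelial", "myeloid", "myeloid",
                   "T_cell", "T_cell", "B_cell", "NK", "dendritic"),
    compartment = c("epithelial", "epithelial", "stromal", "stromal",
                    "stromal", "stromal", "immune", "immune",
                    "immune", "immune", "immune", "immune", "immune"),
    stringsAsFactors = FALSE
  )
}

#' Synthetic-world configuration
#'
#' Sizes and effect settings of the simulated system: 2000 background genes,
#' 60 TF regulons of 20 signed targets, a layered acyclic prior-knowledge
#' network of 25 kinases and 50 intermediates (~15% inhibitory edges),
#' 40 ligands / 30 receptors, 12 cytokines, 2 planted kinases per subtype,
#' an effect size of 1 log2 unit and Gaussian noise sd 0.5 on bulk
#' intensities.
#'
#' @param n_genes background gene count
#' @param n_tfs,regulon_size regulon layout
#' @param n_kinases,n_intermediates,frac_inhibitory prior-network layout
#' @param n_ligands,n_receptors,n_cytokines resource sizes
#' @param k_planted planted kinases per subtype
#' @param n_markers_per_subtype centroid marker genes per subtype
#' @param compartment_signature_size,subcluster_marker_size single-cell
#'   signature sizes
#' @param n_hallmarks,hallmark_size hallmark collection layout
#' @param effect_size_log2 planted shift, log2 units
#' @param noise_sd bulk Gaussian noise sd, log2 units
#' @param marker_fold rate multiplier of marker genes in their cell type
#' @return named list of settings
#' @export
synth_config <- function(n_genes = 2000L, n_tfs = 60L, regulon_size = 20L,
                         n_kinases = 25L, n_intermediates = 50L,
                         frac_inhibitory = 0.15,
                         n_ligands = 40L, n_receptors = 30L,
                         n_cytokines = 12L, k_planted = 2L,
                         n_markers_per_subtype = 50L,
                         compartment_signature_size = 30L,
                         subcluster_marker_size = 10L,
                         n_hallmarks = 10L, hallmark_size = 40L,
                         effect_size_log2 = 1.0, noise_sd = 0.5,
                         marker_fold = 4) {
  as.list(environment())
}

#' Generate the synthetic resource bundle and its ground truth
#'
#' Builds all external resources plus a `GroundTruth` record. The
#' prior-knowledge network is a layered DAG (kinase -> intermediate -> TF)
#' in which every intermediate has exactly one kinase parent and every TF
#' exactly one intermediate parent, so sign propagation along planted paths
#' is unambiguous; low-evidence decoy edges (n_sources < 3) are added to
#' exercise evidence filtering.
#'
#' @param config see [synth_config()]
#' @param seed integer seed; fixed seed gives identical output
#' @return list with elements `bundle` and `truth`
#' @export
make_resources <- function(config = synth_config(), seed = 0L) {
  cfg <- config
  if (cfg$k_planted * 4L > cfg$n_kinases) {
    stopf("infeasible config: %d planted kinases needed but only %d kinases",
          cfg$k_planted * 4L, cfg$n_kinases)
  }
  if (cfg$n_intermediates < cfg$n_kinases * 2L) {
    stopf("infeasible config: need >= 2 intermediates per kinase")
  }
  with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    tfs <- sprintf("TF%02d", seq_len(cfg$n_tfs))
    kinases <- sprintf("KIN%02d", seq_len(cfg$n_kinases))
    meds <- sprintf("MED%02d", seq_len(cfg$n_intermediates))
    ligands <- sprintf("LG%02d", seq_len(cfg$n_ligands))
    receptors <- sprintf("RC%02d", seq_len(cfg$n_receptors))
    cytokines <- sprintf("CYT%02d", seq_len(cfg$n_cytokines))

    # Signed regulons: 20 targets each, 75% activating.
    regulons <- do.call(rbind, lapply(tfs, function(tf) {
      data.frame(tf = tf,
                 target = sample(genes, cfg$regulon_size),
                 mode = ifelse(stats::runif(cfg$regulon_size) < 0.75, 1L, -1L),
                 confidence = sample(c("A", "B", "C"), cfg$regulon_size, replace = TRUE),
                 stringsAsFactors = FALSE)
    }))

    # Layered PKN: kinase i feeds intermediates 2i-1 and 2i; TFs are
    # assigned round-robin to intermediates (in-degree exactly 1).
    rsign <- function(n) ifelse(stats::runif(n) < cfg$frac_inhibitory, -1L, 1L)
    km_edges <- data.frame(
      source = rep(kinases, each = 2L),
      sign = rsign(cfg$n_kinases * 2L),
      target = meds[seq_len(cfg$n_kinases * 2L)],
      n_sources = sample(3:8, cfg$n_kinases * 2L, replace = TRUE),
      stringsAsFactors = FALSE
    )
    med_parent_of_tf <- meds[((seq_len(cfg$n_tfs) - 1L) %% (cfg$n_kinases * 2L)) + 1L]
    mt_edges <- data.frame(
      source = med_parent_of_tf,
      sign = rsign(cfg$n_tfs),
      target = tfs,
      n_sources = sample(3:8, cfg$n_tfs, replace = TRUE),
      stringsAsFactors = FALSE
    )
    decoys <- data.frame(
      source = sample(kinases, 20L, replace = TRUE),
      sign = rsign(20L),
      target = sample(meds, 20L, replace = TRUE),
      n_sources = sample(1:2, 20L, replace = TRUE),
      stringsAsFactors = FALSE
    )
    pkn <- rbind(km_edges, mt_edges, decoys)

    # Plant two kinases per subtype (disjoint across subtypes), mostly
    # activating perturbations.
    planted_pool <- sample(kinases, cfg$k_planted * 4L)
    planted_kinases <- stats::setNames(vector("list", 4L), SUBTYPES)
    planted_tfs <- stats::setNames(vector("list", 4L), SUBTYPES)
    planted_path_nodes <- stats::setNames(vector("list", 4L), SUBTYPES)
    for (i in seq_along(SUBTYPES)) {
      ks <- planted_pool[((i - 1L) * cfg$k_planted + 1L):(i * cfg$k_planted)]
      signs <- ifelse(stats::runif(cfg$k_planted) < 0.7, 1L, -1L)
      planted_kinases[[i]] <- data.frame(kinase = ks, sign = signs,
                                         stringsAsFactors = FALSE)
      # Propagate kinase sign down the (high-evidence) forest.
      tf_rows <- list(); path_nodes <- character(0)
      for (j in seq_along(ks)) {
        e1 <- km_edges[km_edges$source == ks[j], , drop = FALSE]
        path_nodes <- c(path_nodes, ks[j], e1$target)
        for (r in seq_len(nrow(e1))) {
          e2 <- mt_edges[mt_edges$source == e1$target[r], , drop = FALSE]
          if (nrow(e2)) {
            tf_rows[[length(tf_rows) + 1L]] <- data.frame(
              tf = e2$target,
              sign = signs[j] * e1$sign[r] * e2$sign,
              stringsAsFactors = FALSE)
            path_nodes <- c(path_nodes, e2$target)
          }
        }
      }
      planted_tfs[[i]] <- do.call(rbind, tf_rows)
      planted_path_nodes[[i]] <- unique(path_nodes)
    }

    # Gene pools: centroid markers, compartment signatures and subcluster
    # markers are drawn from genes that are not regulon targets, so planted
    # TF programs and identity programs stay orthogonal.
    free <- setdiff(genes, regulons$target)
    take <- function(n) {
      picked <- free[seq_len(n)]
      free <<- free[-seq_len(n)]
      picked
    }
    free <- sample(free)
    centroid_markers <- stats::setNames(
      lapply(SUBTYPES, function(s) take(cfg$n_markers_per_subtype)), SUBTYPES)
    compartment_sets <- list(
      epithelial = take(cfg$compartment_signature_size),
      stromal = take(cfg$compartment_signature_size),
      immune = take(cfg$compartment_signature_size)
    )
    sc_info <- subcluster_info()
    subcluster_markers <- stats::setNames(
      lapply(seq_len(nrow(sc_info)), function(i) take(cfg$subcluster_marker_size)),
      sc_info$subcluster)

    # Hallmarks: one mesenchymal program made of genes genuinely shifted up
    # in MES (positive-shift planted targets plus MES markers); decoy sets
    # from genes untouched in every subtype.
    mes_up <- character(0)
    pt <- planted_tfs[["MES"]]
    for (r in seq_len(nrow(pt))) {
      tg <- regulons[regulons$tf == pt$tf[r], ]
      mes_up <- c(mes_up, tg$target[tg$mode * pt$sign[r] > 0])
    }
    mes_up <- unique(c(mes_up, centroid_markers[["MES"]]))
    emt <- sample(mes_up, min(cfg$hallmark_size, length(mes_up)))
    all_planted_targets <- regulons$target[
      regulons$tf %in% unlist(lapply(planted_tfs, `[[`, "tf"))]
    untouched <- setdiff(free, all_planted_targets)
    hallmarks <- stats::setNames(
      lapply(seq_len(cfg$n_hallmarks - 1L),
             function(i) sample(untouched, cfg$hallmark_size)),
      sprintf("HALLMARK_CONTROL_%02d", seq_len(cfg$n_hallmarks - 1L)))
    hallmarks <- c(list(HALLMARK_EPITHELIAL_MESENCHYMAL_TRANSITION = emt), hallmarks)
    attr(hallmarks, "source_tag") <- "synthetic_hallmarks"

    # Ligand-receptor resource: ligands 1..n_receptors pair with single
    # receptors; the remainder use two-subunit complexes ("A_B").
    rec_entry <- character(cfg$n_ligands)
    for (i in seq_len(cfg$n_ligands)) {
      if (i <= cfg$n_receptors) {
        rec_entry[i] <- receptors[i]
      } else {
        a <- ((i - cfg$n_receptors - 1L) %% cfg$n_receptors) + 1L
        b <- (a %% cfg$n_receptors) + 1L
        rec_entry[i] <- paste(receptors[a], receptors[b], sep = "_")
      }
    }
    lr_resource <- data.frame(ligand = ligands, receptor = rec_entry,
                              stringsAsFactors = FALSE)

    # Planted communication: two stromal/myeloid sender subclusters signal
    # to the tumour subclusters through 3 ligands each.
    senders <- c("M_CCL18", "FB_RGS5")
    pl <- sample(ligands[seq_len(cfg$n_receptors)], 6L)  # single-receptor ligands
    planted_ligands <- list(M_CCL18 = pl[1:3], FB_RGS5 = pl[4:6])
    planted_receivers <- c("Tum_KRT6A", "Tum_KRT14")

    # Regulatory potential: small background mass; planted ligands
    # concentrate on the mesenchymal hallmark genes they shift in tumour
    # cells (tied together in make_single_cell).
    reg_potential <- matrix(stats::runif(cfg$n_ligands * cfg$n_genes, 0, 0.08),
                            nrow = cfg$n_ligands,
                            dimnames = list(ligands, genes))
    for (l in unlist(planted_ligands)) {
      reg_potential[l, emt] <- stats::runif(length(emt), 0.6, 1.0)
    }

    # TF -> cytokine links (CytReg-like): half the cytokines are wired to
    # planted MES TFs so the communication network has dysregulated nodes.
    mes_tfs <- unique(planted_tfs[["MES"]]$tf)
    tf_cyt <- do.call(rbind, lapply(seq_len(cfg$n_cytokines), function(j) {
      tf1 <- if (j <= cfg$n_cytokines / 2) sample(mes_tfs, 1L) else sample(tfs, 1L)
      tf2 <- sample(setdiff(tfs, tf1), 1L)
      data.frame(tf = c(tf1, tf2), cytokine = cytokines[j],
                 mode = sample(c(1L, 1L, -1L), 2L, replace = TRUE),
                 stringsAsFactors = FALSE)
    }))

    # Ligand-receptor-TF links (CellCall-like): planted ligands point at
    # planted MES TFs, the rest at random TFs.
    lr_tf <- do.call(rbind, lapply(seq_len(nrow(lr_resource)), function(i) {
      lg <- lr_resource$ligand[i]
      tf_pick <- if (lg %in% unlist(planted_ligands)) {
        sample(mes_tfs, min(2L, length(mes_tfs)))
      } else {
        sample(tfs, 2L)
      }
      data.frame(ligand = lg, receptor = lr_resource$receptor[i], tf = tf_pick,
                 stringsAsFactors = FALSE)
    }))

    truth <- list(
      planted_kinases = planted_kinases,
      planted_tfs = planted_tfs,
      planted_path_nodes = planted_path_nodes,
      planted_ligands = planted_ligands,
      planted_receivers = planted_receivers,
      hallmark_membership = list(
        HALLMARK_EPITHELIAL_MESENCHYMAL_TRANSITION = emt),
      effect_size_log2 = cfg$effect_size_log2,
      noise_sd = cfg$noise_sd,
      subtype_of_sample = NULL
    )

    expr_genes <- c(genes, ligands, receptors, cytokines)
    bundle <- list(
      pkn = pkn,
      regulons = regulons,
      lr_resource = lr_resource,
      reg_potential = reg_potential,
      tf_cytokine = tf_cyt,
      lr_tf = lr_tf,
      kinase_list = kinases,
      cell_signatures = c(compartment_sets, subcluster_markers),
      compartment_signatures = compartment_sets,
      subcluster_markers = subcluster_markers,
      hallmarks = hallmarks,
      centroid_markers = centroid_markers,
      subcluster_info = sc_info,
      expr_genes = expr_genes,
      config = cfg
    )
    bundle$subtype_centroids <- 7 + synthetic_shifts(bundle, truth) *
      cfg$effect_size_log2
    bundle$subtype_signatures <- stats::setNames(lapply(SUBTYPES, function(s) {
      sh <- synthetic_shifts(bundle, truth)[, s]
      names(sh)[sh > 0]
    }), SUBTYPES)
    list(bundle = bundle, truth = truth)
  })
}

# Per-gene, per-subtype shift pattern in units of effect_size_log2: planted
# TF targets move by mode x TF sign; centroid markers by +1; planted
# ligands/receptor subunits by +1 in MES (stroma-derived signal enriched in
# mesenchymal bulk); cytokines wired to planted TFs move with them.
synthetic_shifts <- function(bundle, truth) {
  genes <- bundle$expr_genes
  shifts <- matrix(0, nrow = length(genes), ncol = 4L,
                   dimnames = list(genes, SUBTYPES))
  for (s in SUBTYPES) {
    pt <- truth$planted_tfs[[s]]
    for (r in seq_len(nrow(pt))) {
      tg <- bundle$regulons[bundle$regulons$tf == pt$tf[r], ]
      shifts[tg$target, s] <- shifts[tg$target, s] + tg$mode * pt$sign[r]
    }
    shifts[bundle$centroid_markers[[s]], s] <-
      shifts[bundle$centroid_markers[[s]], s] + 1
    cy <- merge(bundle$tf_cytokine, pt, by = "tf")
    if (nrow(cy)) {
      for (r in seq_len(nrow(cy))) {
        shifts[cy$cytokine[r], s] <- shifts[cy$cytokine[r], s] +
          cy$mode[r] * cy$sign[r]
      }
    }
  }
  pl <- unlist(truth$planted_ligands)
  subunits <- unlist(strsplit(
    bundle$lr_resource$receptor[bundle$lr_resource$ligand %in% pl], "_"))
  shifts[pl, "MES"] <- shifts[pl, "MES"] + 1
  shifts[subunits, "MES"] <- shifts[subunits, "MES"] + 1
  shifts
}

#' Simulate a bulk expression cohort
#'
#' Baseline log2 intensities are Normal(7, 1) per gene; subtype-specific
#' shifts of `effect_size_log2` log2 units are added on top (planted TF
#' targets, centroid markers, planted ligand/receptor genes and wired
#' cytokines) plus i.i.d. Gaussian noise. With `noise_sd = 0` all shifts
#' are exact.
#'
#' @param bundle,truth from [make_resources()]
#' @param n_per_subtype samples per subtype (>= 2)
#' @param seed integer seed
#' @return list with `expr` (genes x samples log2 matrix) and
#'   `subtype_of_sample` (named character vector)
#' @export
make_bulk <- function(bundle, truth, n_per_subtype = 25L, seed = 0L) {
  if (n_per_subtype < 2L) stopf("n_per_subtype must be >= 2")
  with_seed(seed, {
    genes <- bundle$expr_genes
    n <- n_per_subtype * 4L
    labels <- rep(SUBTYPES, each = n_per_subtype)
    ids <- sprintf("S%03d", seq_len(n))
    baseline <- stats::rnorm(length(genes), mean = 7, sd = 1)
    shifts <- synthetic_shifts(bundle, truth) * truth$effect_size_log2
    expr <- matrix(baseline, nrow = length(genes), ncol = n,
                   dimnames = list(genes, ids))
    expr <- expr + shifts[, labels]
    if (truth$noise_sd > 0) {
      expr <- expr + matrix(stats::rnorm(length(expr), sd = truth$noise_sd),
                            nrow = nrow(expr))
    }
    list(expr = expr, subtype_of_sample = stats::setNames(labels, ids))
  })
}

#' Simulate an annotated single-cell matrix
#'
#' Counts are drawn per gene from a log-normal base rate and a Poisson
#' observation layer. Compartment-signature genes and subcluster markers are
#' elevated (`marker_fold`, default 4x) in their cells; planted ligands are
#' strongly elevated in their sender subcluster and near-absent elsewhere;
#' cognate receptor subunits are elevated in the tumour receivers; and in
#' tumour cells each gene's rate grows with its maximal regulatory potential
#' under the planted ligands, so ligand targets really move in receivers.
#'
#' @param bundle,truth from [make_resources()]
#' @param cells_per_subcluster cells per subcluster (>= 5)
#' @param seed integer seed
#' @return list with `counts`, log-normalized `cells`
#'   (log2(1 + CP10K)) and `annot` (cell_id, major_type, subcluster,
#'   sample_id)
#' @export
make_single_cell <- function(bundle, truth, cells_per_subcluster = 50L,
                             seed = 0L) {
  if (cells_per_subcluster < 5L) stopf("cells_per_subcluster must be >= 5")
  with_seed(seed, {
    info <- bundle$subcluster_info
    genes <- bundle$expr_genes
    n_cells <- cells_per_subcluster * nrow(info)
    annot <- data.frame(
      cell_id = sprintf("C%04d", seq_len(n_cells)),
      subcluster = rep(info$subcluster, each = cells_per_subcluster),
      stringsAsFactors = FALSE
    )
    annot$major_type <- info$major_type[match(annot$subcluster, info$subcluster)]
    annot$sample_id <- rep_len(c("SC1", "SC2"), n_cells)

    base_rate <- stats::rlnorm(length(genes), meanlog = log(0.3), sdlog = 0.7)
    names(base_rate) <- genes
    fold <- bundle$config$marker_fold
    pl <- unlist(truth$planted_ligands)
    pl_senders <- rep(names(truth$planted_ligands),
                      times = lengths(truth$planted_ligands))
    pl_subunits <- lapply(stats::setNames(pl, pl), function(l) {
      strsplit(bundle$lr_resource$receptor[bundle$lr_resource$ligand == l], "_")[[1]]
    })
    tumour_pot <- apply(bundle$reg_potential[pl, , drop = FALSE], 2, max)

    lam <- matrix(base_rate, nrow = length(genes), ncol = n_cells,
                  dimnames = list(genes, annot$cell_id))
    for (i in seq_len(nrow(info))) {
      cols <- annot$subcluster == info$subcluster[i]
      comp_genes <- bundle$compartment_signatures[[info$compartment[i]]]
      lam[comp_genes, cols] <- lam[comp_genes, cols] * fold
      mk <- bundle$subcluster_markers[[info$subcluster[i]]]
      lam[mk, cols] <- lam[mk, cols] * fold
    }
    # Planted ligands: high in their sender, near-zero everywhere else.
    lam[pl, ] <- lam[pl, ] * 0.02
    for (j in seq_along(pl)) {
      cols <- annot$subcluster == pl_senders[j]
      lam[pl[j], cols] <- base_rate[pl[j]] * 2 * fold
      rcols <- annot$subcluster %in% truth$planted_receivers
      lam[pl_subunits[[j]], rcols] <- base_rate[pl_subunits[[j]]] * 2 * fold
    }
    tum_cols <- annot$major_type == "tumour"
    lam[names(tumour_pot), tum_cols] <-
      lam[names(tumour_pot), tum_cols] * (1 + 3 * tumour_pot)

    size_factor <- stats::rlnorm(n_cells, 0, 0.1)
    counts <- matrix(stats::rpois(length(lam), lam * rep(size_factor, each = nrow(lam))),
                     nrow = nrow(lam), dimnames = dimnames(lam))
    lib <- pmax(colSums(counts), 1)
    cells <- log2(1 + t(t(counts) / lib) * 1e4)
    list(counts = counts, cells = cells, annot = annot)
  })
}

#' Write a full simulated input set to disk
#'
#' Writes bulk and single-cell matrices, annotations, GMT collections,
#' SIF-like networks, resource tables and a `ground_truth.json`, all in the
#' package's interchange formats.
#'
#' @param outdir output directory (created if missing)
#' @param config see [synth_config()]
#' @param n_per_subtype,cells_per_subcluster cohort sizes
#' @param seed integer seed fanned out to the generator stages
#' @return invisibly, a named vector of written paths
#' @export
write_simulation <- function(outdir, config = synth_config(),
                             n_per_subtype = 25L, cells_per_subcluster = 50L,
                             seed = 0L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- make_resources(config, seed = stage_seed(seed, 1L))
  bulk <- make_bulk(res$bundle, res$truth, n_per_subtype,
                    seed = stage_seed(seed, 2L))
  sc <- make_single_cell(res$bundle, res$truth, cells_per_subcluster,
                         seed = stage_seed(seed, 3L))
  p <- function(f) file.path(outdir, f)
  write_expression(bulk$expr, p("bulk_expr.tsv"))
  utils::write.table(
    data.frame(sample_id = names(bulk$subtype_of_sample),
               subtype = bulk$subtype_of_sample),
    p("bulk_subtypes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_expression(sc$cells, p("sc_lognorm.tsv"))
  utils::write.table(sc$annot, p("sc_annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(res$bundle$hallmarks, p("hallmarks.gmt"))
  write_gmt(res$bundle$compartment_signatures, p("compartments.gmt"))
  write_gmt(res$bundle$cell_signatures, p("cell_signatures.gmt"))
  write_gmt(res$bundle$subtype_signatures, p("subtype_signatures.gmt"))
  write_signed_network(res$bundle$pkn, p("pkn.tsv"))
  utils::write.table(res$bundle$regulons, p("regulons.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$bundle$lr_resource, p("lr_resource.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$bundle$tf_cytokine, p("tf_cytokine.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$bundle$lr_tf, p("lr_tf_links.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_expression(res$bundle$reg_potential, p("reg_potential.tsv"))
  write_expression(res$bundle$subtype_centroids, p("subtype_centroids.tsv"))
  writeLines(res$bundle$kinase_list, p("kinases.txt"))
  jsonlite::write_json(res$truth, p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA)
  files <- c("bulk_expr.tsv", "bulk_subtypes.tsv", "sc_lognorm.tsv",
             "sc_annotation.tsv", "hallmarks.gmt", "compartments.gmt",
             "cell_signatures.gmt", "subtype_signatures.gmt", "pkn.tsv",
             "regulons.tsv", "lr_resource.tsv", "tf_cytokine.tsv",
             "lr_tf_links.tsv", "reg_potential.tsv", "subtype_centroids.tsv",
             "kinases.txt", "ground_truth.json")
  invisible(stats::setNames(file.path(outdir, files), files))
}
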