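# Regulon-based transcription-factor activity: signed analytic rank
# enrichment of each TF's targets in a differential signature, pairwise
# subtype contrasts, and assembly of the TF-guided intercellular
# communication network.

#' Filter a regulon table to usable regulons
#'
#' @param regulons data.frame(tf, target, mode) (optionally `confidence`)
#' @param genes genes present in the data; targets outside are dropped
#' @param min_targets minimum targets after intersection (default 10, the
#'   published cut)
#' @param confidence optional confidence levels to keep (e.g. c("A","B","C"))
#' @return filtered regulon data.frame
#' @export
filter_regulons <- function(regulons, genes, min_targets = 10L,
                            confidence = NULL) {
  if (!is.null(confidence) && "confidence" %in% colnames(regulons)) {
    regulons <- regulons[regulons$confidence %in% confidence, , drop = FALSE]
  }
  regulons <- regulons[regulons$target %in% genes, , drop = FALSE]
  regulons <- regulons[!duplicated(regulons[, c("tf", "target")]), , drop = FALSE]
  sizes <- table(regulons$tf)
  small <- names(sizes)[sizes < min_targets]
  if (length(small)) {
    sc_log("filter_regulons: excluding %d TF(s) with < %d usable targets",
           length(small), min_targets)
  }
  regulons[!(regulons$tf %in% small), , drop = FALSE]
}

#' Analytic TF activity (NES) from a ranked signature
#'
#' Genes are rank-transformed to normal quantiles q_i = qnorm(rank_i /
#' (N + 1)); a regulon's enrichment is ES = sum(mode_i q_i) / sqrt(n).
#' The NES standardizes ES by its exact null standard deviation under
#' random target positions (sampling without replacement from the finite
#' quantile population):
#' Var(ES) = sigma_q^2 (n N - M^2) / (n (N - 1)) with M = sum(mode_i), so
#' NES is a calibrated z-score at any universe size. Being rank-based, NES
#' is invariant to strictly monotone transforms of the signature, and
#' negating the signature negates every NES exactly.
#'
#' @param signature named numeric vector (finite)
#' @param regulons data.frame(tf, target, mode)
#' @param min_targets regulons falling below this after intersecting with
#'   the signature are excluded with a log entry
#' @param contrast label stored on the result
#' @return data.frame(tf, nes, n_targets_used, contrast), sorted by
#'   decreasing |nes| with ties broken by tf name
#' @export
tf_nes <- function(signature, regulons, min_targets = 10L,
                   contrast = "contrast") {
  regulons <- filter_regulons(regulons, names(signature), min_targets)
  if (!nrow(regulons)) stopf("no regulon passes the size filter")
  N <- length(signature)
  q <- stats::qnorm(rank(signature, ties.method = "average") / (N + 1))
  names(q) <- names(signature)
  sigma2 <- mean(q^2) - mean(q)^2  # population variance of the quantiles
  tfs <- unique(regulons$tf)
  res <- lapply(tfs, function(tf) {
    tg <- regulons[regulons$tf == tf, ]
    n <- nrow(tg)
    es <- sum(tg$mode * q[tg$target]) / sqrt(n)
    m <- sum(tg$mode)
    v <- sigma2 * (n * N - m^2) / (n * (N - 1))
    data.frame(tf = tf, nes = es / sqrt(v), n_targets_used = n,
               contrast = contrast, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(-abs(out$nes), out$tf), ]
  rownames(out) <- NULL
  out
}

#' Pairwise TF activity between subtypes
#'
#' For every contrast MES_vs_X (X in the other subtypes) and its
#' reciprocal, the signature is the moderated t of group A vs group B;
#' reciprocal signatures are exact negations, so reciprocal NES values are
#' exact negations too.
#'
#' @param expr genes x samples log2 matrix
#' @param labels subtype per sample (aligned to columns)
#' @param regulons data.frame(tf, target, mode)
#' @param reference subtype compared against the others (default "MES")
#' @param min_targets regulon size cut
#' @return data.frame of [tf_nes()] results, one block per contrast
#' @export
pairwise_tf_nes <- function(expr, labels, regulons, reference = "MES",
                            min_targets = 10L) {
  labels <- as.character(labels)
  others <- setdiff(intersect(SUBTYPES, unique(labels)), reference)
  if (!(reference %in% labels) || !length(others)) {
    stopf("labels must contain '%s' and at least one other subtype", reference)
  }
  res <- list()
  for (x in others) {
    sel <- labels %in% c(reference, x)
    # zero-variance cohorts (e.g. noise-free simulations) have no moderated
    # t; fall back to the plain difference of means, which induces the same
    # ranking in that regime
    de <- tryCatch(moderated_de(expr[, sel, drop = FALSE], labels[sel],
                                contrast = reference),
                   error = function(e) {
                     if (!grepl("degenerate", conditionMessage(e))) stop(e)
                     NULL
                   })
    sig <- if (is.null(de)) {
      sc_log("pairwise_tf_nes: degenerate variances; ranking by log2 fold-change")
      rowMeans(expr[, labels == reference, drop = FALSE]) -
        rowMeans(expr[, labels == x, drop = FALSE])
    } else {
      de_signature(de)
    }
    fwd <- tf_nes(sig, regulons, min_targets,
                  contrast = paste0(reference, "_vs_", x))
    rev <- tf_nes(-sig, regulons, min_targets,
                  contrast = paste0(x, "_vs_", reference))
    res[[length(res) + 1L]] <- fwd
    res[[length(res) + 1L]] <- rev
  }
  do.call(rbind, res)
}

#' Select the top TFs by absolute NES
#'
#' @param tf_acts data.frame from [tf_nes()] (single contrast)
#' @param k number of TFs
#' @return the top-k rows (deterministic: |nes| descending, name ascending)
#' @export
top_tfs <- function(tf_acts, k) {
  ord <- order(-abs(tf_acts$nes), tf_acts$tf)
  tf_acts[ord[seq_len(min(k, nrow(tf_acts)))], , drop = FALSE]
}

#' Assemble the TF-guided intercellular communication network
#'
#' TFs (pre-selected, e.g. the top 50 by |NES|) are retained only if they
#' have at least one TF-to-cytokine link; significant tumour-directed LR
#' pairs attach to retained TFs through the ligand-receptor-TF link table;
#' cytokine nodes carry their differential expression and a
#' `regulator_count` equal to their in-degree from retained TFs.
#'
#' @param sig_lr data.frame of significant interactions (ligand, receptor)
#' @param tf_acts data.frame(tf, nes) of candidate TFs
#' @param lr_tf_links data.frame(ligand, receptor, tf)
#' @param tf_cytokine data.frame(tf, cytokine, mode)
#' @param cytokine_de data.frame from [moderated_de()] covering cytokines
#' @return list with `nodes` (id, type, attributes) and `edges`
#'   (from, to, type, mode)
#' @export
assemble_comm_network <- function(sig_lr, tf_acts, lr_tf_links, tf_cytokine,
                                  cytokine_de) {
  if (!nrow(sig_lr) || !nrow(tf_acts) || !nrow(lr_tf_links) ||
      !nrow(tf_cytokine)) {
    stopf("all communication-network inputs must be nonempty")
  }
  retained <- intersect(tf_acts$tf, unique(tf_cytokine$tf))
  if (!length(retained)) stopf("no TF retained: none has a cytokine link")
  sc_log("assemble_comm_network: %d of %d TFs retained", length(retained),
         nrow(tf_acts))
  lr_key <- unique(paste(sig_lr$ligand, sig_lr$receptor))
  links <- lr_tf_links[paste(lr_tf_links$ligand, lr_tf_links$receptor) %in%
                         lr_key & lr_tf_links$tf %in% retained, , drop = FALSE]
  tc <- tf_cytokine[tf_cytokine$tf %in% retained, , drop = FALSE]

  edges <- rbind(
    if (nrow(links)) data.frame(from = links$ligand, to = links$receptor,
                                type = "lr", mode = 1L,
                                stringsAsFactors = FALSE),
    if (nrow(links)) data.frame(from = links$receptor, to = links$tf,
                                type = "receptor_tf", mode = 1L,
                                stringsAsFactors = FALSE),
    data.frame(from = tc$tf, to = tc$cytokine, type = "tf_cytokine",
               mode = tc$mode, stringsAsFactors = FALSE)
  )
  edges <- edges[!duplicated(edges), , drop = FALSE]

  cyt <- unique(tc$cytokine)
  de_map <- cytokine_de[match(cyt, cytokine_de$gene), , drop = FALSE]
  reg_count <- vapply(cyt, function(cc) length(unique(tc$tf[tc$cytokine == cc])),
                      integer(1))
  nodes <- rbind(
    if (nrow(links)) data.frame(id = unique(links$ligand), type = "ligand",
                                nes = NA_real_, log2fc = NA_real_,
                                p_adjusted = NA_real_,
                                regulator_count = NA_integer_,
                                stringsAsFactors = FALSE),
    if (nrow(links)) data.frame(id = unique(links$receptor), type = "receptor",
                                nes = NA_real_, log2fc = NA_real_,
                                p_adjusted = NA_real_,
                                regulator_count = NA_integer_,
                                stringsAsFactors = FALSE),
    data.frame(id = retained, type = "tf",
               nes = tf_acts$nes[match(retained, tf_acts$tf)],
               log2fc = NA_real_, p_adjusted = NA_real_,
               regulator_count = NA_integer_, stringsAsFactors = FALSE),
    data.frame(id = cyt, type = "cytokine", nes = NA_real_,
               log2fc = de_map$log2fc, p_adjusted = de_map$p_adjusted,
               regulator_count = reg_count, stringsAsFactors = FALSE)
  )
  rownames(nodes) <- rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}
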