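# Compartment assignment of single cells: module-score each of the
# epithelial / stromal / immune signatures, z-normalize scores per sample,
# assign by argmax.

#' Module score of a gene signature
#'
#' Score = mean normalized expression of the signature genes minus the mean
#' of a control gene set drawn per signature gene from its average-expression
#' bin (genes are cut into `n_bins` bins by across-cell mean; `n_ctrl`
#' controls per signature gene, sampled without the signature gene itself).
#' Seeded and deterministic.
#'
#' @param cells genes x cells log-normalized matrix
#' @param signature character vector of genes
#' @param n_bins expression bins (default 25)
#' @param n_ctrl control genes per signature gene (default 50)
#' @param seed integer seed
#' @return named per-cell numeric score
#' @export
score_signature <- function(cells, signature, n_bins = 25L, n_ctrl = 50L,
                            seed = 0L) {
  sig <- intersect(signature, rownames(cells))
  if (!length(sig)) stopf("no signature gene present in the matrix")
  avg <- rowMeans(cells)
  # rank-based cut so bins are (near) equal occupancy
  bins <- cut(rank(avg, ties.method = "first"), breaks = n_bins, labels = FALSE)
  names(bins) <- rownames(cells)
  ctrl <- with_seed(seed, {
    unlist(lapply(sig, function(g) {
      pool <- setdiff(names(bins)[bins == bins[g]], g)
      if (!length(pool)) return(g)
      sample(pool, min(n_ctrl, length(pool)))
    }))
  })
  colMeans(cells[sig, , drop = FALSE]) - colMeans(cells[ctrl, , drop = FALSE])
}

#' Assign cells to epithelial/stromal/immune compartments
#'
#' Cell-level signature scores are z-normalized (per sample by default, the
#' convention when samples were normalized separately) and each cell takes
#' the compartment with the highest z. Exact ties break deterministically in
#' the order epithelial < immune < stromal.
#'
#' @param cells genes x cells log-normalized matrix
#' @param signatures named list with elements `epithelial`, `stromal`,
#'   `immune`
#' @param sample_ids per-cell sample id (required when `per_sample`)
#' @param per_sample z-normalize within sample rather than globally
#' @param n_bins,n_ctrl,seed passed to [score_signature()]
#' @return list with `assignments` (data.frame: cell_id, raw scores,
#'   z-scores, compartment) and `composition` (per-sample percentages, one
#'   decimal)
#' @export
assign_compartments <- function(cells, signatures, sample_ids = NULL,
                                per_sample = TRUE, n_bins = 25L,
                                n_ctrl = 50L, seed = 0L) {
  comps <- c("epithelial", "stromal", "immune")
  if (!all(comps %in% names(signatures))) {
    stopf("signatures must contain epithelial, stromal and immune sets")
  }
  if (per_sample && is.null(sample_ids)) {
    stopf("per_sample z-normalization needs sample_ids")
  }
  raw <- vapply(comps, function(cp) {
    score_signature(cells, signatures[[cp]], n_bins, n_ctrl, seed = seed)
  }, numeric(ncol(cells)))
  groups <- if (per_sample) as.character(sample_ids) else rep("all", ncol(cells))
  z <- raw
  for (g in unique(groups)) {
    idx <- groups == g
    for (cp in comps) {
      sdv <- stats::sd(raw[idx, cp])
      if (is.na(sdv) || sdv == 0) {
        stopf("signature '%s' has constant scores in sample '%s'; z undefined", cp, g)
      }
      z[idx, cp] <- (raw[idx, cp] - mean(raw[idx, cp])) / sdv
    }
  }
  tie_order <- c("epithelial", "immune", "stromal")
  zt <- z[, tie_order, drop = FALSE]
  compartment <- tie_order[apply(zt, 1, which.max)]
  assignments <- data.frame(cell_id = colnames(cells),
                            sample_id = groups,
                            score_epithelial = raw[, "epithelial"],
                            score_stromal = raw[, "stromal"],
                            score_immune = raw[, "immune"],
                            z_epithelial = z[, "epithelial"],
                            z_stromal = z[, "stromal"],
                            z_immune = z[, "immune"],
                            compartment = compartment,
                            stringsAsFactors = FALSE)
  rownames(assignments) <- NULL
  composition <- do.call(rbind, lapply(unique(groups), function(g) {
    sub <- assignments$compartment[assignments$sample_id == g]
    data.frame(sample_id = g, compartment = comps,
               n = vapply(comps, function(cp) sum(sub == cp), integer(1)),
               percent = round_half_up(
                 100 * vapply(comps, function(cp) mean(sub == cp), numeric(1)), 1),
               stringsAsFactors = FALSE)
  }))
  rownames(composition) <- NULL
  list(assignments = assignments, composition = composition)
}
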