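# Consensus ligand-receptor inference between annotated subclusters: three
# transparent scorers (magnitude, cluster-permutation significance,
# specificity) combined by robust rank aggregation; interactions are called
# significant at aggregated rank < 0.05.

#' Drop subclusters with too few cells
#'
#' @param annot data.frame with columns `cell_id` and `subcluster`
#' @param min_cells minimum cells per subcluster (default 5, the published
#'   cut)
#' @return filtered annotation
#' @export
filter_subclusters <- function(annot, min_cells = 5L) {
  tab <- table(annot$subcluster)
  drop <- names(tab)[tab < min_cells]
  if (length(drop)) {
    sc_log("filter_subclusters: removing %d subcluster(s) with < %d cells: %s",
           length(drop), min_cells, paste(drop, collapse = ", "))
  }
  out <- annot[!(annot$subcluster %in% drop), , drop = FALSE]
  if (!nrow(out)) stopf("all subclusters removed at min_cells = %d", min_cells)
  out
}

# Split "A_B" receptor-complex entries into subunit vectors.
receptor_subunits <- function(receptor) strsplit(receptor, "_", fixed = TRUE)

#' Score ligand-receptor interactions with three methods
#'
#' For every (sender, receiver, ligand-receptor) triple over all ordered
#' subcluster pairs:
#' * `m1` mean-expression magnitude: (mean ligand in sender + mean receptor
#'   in receiver) / 2, with receptor complexes using the minimum subunit
#'   mean; defined only when the ligand and every subunit are detected in at
#'   least `expr_prop` of the respective subcluster's cells (otherwise NA).
#' * `m2` permutation p-value of that magnitude under seeded cluster-label
#'   shuffles: (1 + #{permuted >= observed}) / (1 + n_perm).
#' * `m3` specificity: the product of the sender's share of total ligand
#'   expression and the receiver's share of total receptor expression across
#'   clusters.
#'
#' Resource entries whose ligand or any receptor subunit is absent from the
#' matrix are skipped with a log entry.
#'
#' @param cells genes x cells log-normalized matrix
#' @param annot annotation data.frame (`cell_id`, `subcluster`), aligned to
#'   `colnames(cells)` by cell_id
#' @param resource data.frame(ligand, receptor) with complexes as `"A_B"`
#' @param expr_prop detection-proportion gate (default 0.1)
#' @param n_perm permutations for `m2` (default 1000)
#' @param seed integer seed
#' @return data.frame(sender, receiver, ligand, receptor, m1, m2, m3)
#' @export
score_methods <- function(cells, annot, resource, expr_prop = 0.1,
                          n_perm = 1000L, seed = 0L) {
  idx <- match(annot$cell_id, colnames(cells))
  if (anyNA(idx)) stopf("annotation cells missing from the matrix")
  cells <- cells[, idx, drop = FALSE]
  clusters <- sort(unique(annot$subcluster))
  if (length(clusters) < 2L) stopf("need >= 2 subclusters")
  subs <- receptor_subunits(resource$receptor)
  present <- resource$ligand %in% rownames(cells) &
    vapply(subs, function(s) all(s %in% rownames(cells)), logical(1))
  if (any(!present)) {
    sc_log("score_methods: skipping %d resource entries with absent genes",
           sum(!present))
  }
  resource <- resource[present, , drop = FALSE]
  subs <- subs[present]
  if (!nrow(resource)) stopf("no resource entry has all genes in the matrix")

  genes <- unique(c(resource$ligand, unlist(subs)))
  M <- cells[genes, , drop = FALSE]
  tM <- t(M)
  labf <- factor(annot$subcluster, levels = clusters)
  csize <- as.integer(table(labf))
  mu <- rowsum(tM, labf) / csize                      # clusters x genes
  prop <- rowsum((tM > 0) + 0, labf) / csize

  n_lr <- nrow(resource)
  grid <- expand.grid(si = seq_along(clusters), ri = seq_along(clusters),
                      li = seq_len(n_lr))
  sender <- clusters[grid$si]
  receiver <- clusters[grid$ri]
  lig <- resource$ligand[grid$li]

  # Receptor summaries per (cluster, resource row): min over subunits.
  rec_mu <- vapply(subs, function(s) {
    if (length(s) == 1L) mu[, s] else apply(mu[, s, drop = FALSE], 1, min)
  }, numeric(length(clusters)))
  rec_prop_ok <- vapply(subs, function(s) {
    if (length(s) == 1L) prop[, s] >= expr_prop else
      apply(prop[, s, drop = FALSE] >= expr_prop, 1, all)
  }, logical(length(clusters)))

  lig_mu <- mu[cbind(grid$si, match(lig, colnames(mu)))]
  rec_mu_v <- rec_mu[cbind(grid$ri, grid$li)]
  m1_raw <- (lig_mu + rec_mu_v) / 2
  gate <- prop[cbind(grid$si, match(lig, colnames(prop)))] >= expr_prop &
    rec_prop_ok[cbind(grid$ri, grid$li)]
  m1 <- ifelse(gate, m1_raw, NA_real_)

  lig_tot <- colSums(mu)[match(lig, colnames(mu))]
  rec_tot <- colSums(rec_mu)[grid$li]
  m3 <- ifelse(lig_tot > 0 & rec_tot > 0,
               (lig_mu / lig_tot) * (rec_mu_v / rec_tot), NA_real_)

  # Permutation null for the magnitude under cluster-label shuffles.
  lig_col <- match(lig, colnames(mu))
  exceed <- integer(length(m1_raw))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      pl <- sample(as.integer(labf))
      mu_p <- rowsum(tM, pl) / as.integer(table(factor(pl, levels = seq_along(clusters))))
      rec_mu_p <- vapply(subs, function(s) {
        if (length(s) == 1L) mu_p[, s] else apply(mu_p[, s, drop = FALSE], 1, min)
      }, numeric(length(clusters)))
      stat <- (mu_p[cbind(grid$si, lig_col)] + rec_mu_p[cbind(grid$ri, grid$li)]) / 2
      exceed <- exceed + (stat >= m1_raw)
    }
  })
  m2 <- (1 + exceed) / (1 + n_perm)

  data.frame(sender = sender, receiver = receiver, ligand = lig,
             receptor = resource$receptor[grid$li],
             m1 = m1, m2 = m2, m3 = m3, stringsAsFactors = FALSE)
}

#' Robust rank aggregation of method scores
#'
#' Each method ranks all interactions (best = 1; larger is better for
#' magnitude/specificity, smaller is better for p-value-like columns;
#' missing scores take the worst rank so an NA can never promote an
#' interaction). With normalized ranks r_(1) <= ... <= r_(M) over the M
#' methods, the aggregation score is rho = min_k BetaCDF(r_(k); k, M-k+1)
#' and the aggregated rank is min(rho x M, 1) (Bonferroni-style
#' correction).
#'
#' @param scores data.frame from [score_methods()] (or any data.frame
#'   containing the score columns)
#' @param directions named vector over score columns, `+1` if larger is
#'   better, `-1` if smaller is better
#' @return `scores` with extra columns `aggregated_rank` and per-method
#'   normalized ranks `rank_<method>`
#' @export
aggregate_ranks <- function(scores,
                            directions = c(m1 = 1, m2 = -1, m3 = 1)) {
  methods <- names(directions)
  if (length(methods) < 2L) stopf("rank aggregation needs >= 2 methods")
  n <- nrow(scores)
  norm_ranks <- vapply(methods, function(m) {
    x <- scores[[m]] * directions[[m]]
    r <- rank(-x, ties.method = "average", na.last = "keep")
    r[is.na(r)] <- n
    r / n
  }, numeric(n))
  M <- length(methods)
  rho <- apply(norm_ranks, 1, function(r) {
    rs <- sort(r)
    min(stats::pbeta(rs, seq_len(M), M - seq_len(M) + 1))
  })
  out <- scores
  colnames(norm_ranks) <- paste0("rank_", methods)
  out <- cbind(out, norm_ranks)
  out$aggregated_rank <- pmin(rho * M, 1)
  out
}

#' Full ligand-receptor consensus call
#'
#' Convenience wrapper: score, aggregate and flag significance at
#' `threshold` on the aggregated rank.
#'
#' @inheritParams score_methods
#' @param threshold aggregated-rank significance cut (default 0.05)
#' @return data.frame with scores, ranks, `aggregated_rank`, `significant`
#' @export
lr_consensus <- function(cells, annot, resource, expr_prop = 0.1,
                         n_perm = 1000L, seed = 0L, threshold = 0.05) {
  out <- aggregate_ranks(score_methods(cells, annot, resource, expr_prop,
                                       n_perm, seed))
  out$significant <- out$aggregated_rank < threshold
  out
}

#' Summarize a significant interaction network
#'
#' @param interactions data.frame of significant interactions (sender,
#'   receiver, ligand, receptor)
#' @param subcluster_major named vector mapping subcluster -> major cell
#'   type
#' @param unique_by count a major type's unique (ligand, receptor) pairs by
#'   either-side participation (default) or sender side only
#' @return list: `totals` per subcluster, `sender_receiver` proportions,
#'   `unique_per_major`, `ligand_ranks`
#' @export
summarize_network <- function(interactions, subcluster_major,
                              unique_by = c("either", "sender")) {
  unique_by <- match.arg(unique_by)
  subclusters <- sort(unique(names(subcluster_major)))
  totals <- vapply(subclusters, function(sc) {
    sum(interactions$sender == sc | interactions$receiver == sc)
  }, integer(1))
  n <- nrow(interactions)
  sr <- if (n) {
    agg <- stats::aggregate(list(count = rep(1L, n)),
                            by = list(sender = interactions$sender,
                                      receiver = interactions$receiver),
                            FUN = sum)
    agg$proportion <- agg$count / n
    agg
  } else {
    data.frame(sender = character(0), receiver = character(0),
               count = integer(0), proportion = numeric(0))
  }
  majors <- sort(unique(subcluster_major))
  uniq <- vapply(majors, function(mt) {
    scs <- names(subcluster_major)[subcluster_major == mt]
    inv <- if (unique_by == "either") {
      interactions$sender %in% scs | interactions$receiver %in% scs
    } else {
      interactions$sender %in% scs
    }
    length(unique(paste(interactions$ligand[inv], interactions$receptor[inv])))
  }, integer(1))
  lig_counts <- if (n) sort(table(interactions$ligand), decreasing = TRUE) else
    table(character(0))
  ligand_ranks <- data.frame(ligand = names(lig_counts),
                             n_interactions = as.integer(lig_counts),
                             rank = if (length(lig_counts))
                               rank(-as.integer(lig_counts), ties.method = "min")
                             else integer(0),
                             stringsAsFactors = FALSE)
  list(totals = data.frame(subcluster = subclusters, total = totals,
                           stringsAsFactors = FALSE),
       sender_receiver = sr,
       unique_per_major = data.frame(major_type = majors,
                                     unique_interactions = uniq,
                                     stringsAsFactors = FALSE),
       ligand_ranks = ligand_ranks)
}
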