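# Ligand activity against hallmark programs: Pearson correlation between a
# ligand's regulatory-potential vector and the gene-set indicator over a
# gene universe, with k-fold cross-validated stability, top-ligand target
# potential with top-quantile Fisher enrichment, and the bulk LR-pair /
# hallmark ssGSEA correlation.

#' Rank ligands by activity on a gene set
#'
#' Activity of a ligand is the Pearson correlation between its
#' regulatory-potential row and the 0/1 membership indicator of `gene_set`
#' over `universe`. Candidate ligands are removed from the gene set before
#' scoring (a ligand must not predict itself). Constant potential rows give
#' NA and rank last; ties break by ligand name.
#'
#' @param potential ligand x gene nonnegative matrix
#' @param gene_set character vector (e.g. one hallmark)
#' @param universe gene universe; defaults to the potential matrix columns
#' @param candidate_ligands ligands to score; restricted to rows of
#'   `potential`
#' @return data.frame(ligand, pcc) sorted by decreasing pcc
#' @export
ligand_activity <- function(potential, gene_set,
                            universe = colnames(potential),
                            candidate_ligands = rownames(potential)) {
  if (!length(candidate_ligands)) stopf("empty candidate ligand list")
  cand <- intersect(candidate_ligands, rownames(potential))
  if (!length(cand)) stopf("no candidate ligand present in the potential matrix")
  universe <- intersect(universe, colnames(potential))
  gene_set <- setdiff(gene_set, cand)
  ind <- as.numeric(universe %in% gene_set)
  if (sum(ind) == 0) stopf("gene_set does not overlap the universe")
  pcc <- vapply(cand, function(l) {
    x <- potential[l, universe]
    if (stats::sd(x) == 0 || stats::sd(ind) == 0) return(NA_real_)
    stats::cor(x, ind)
  }, numeric(1))
  out <- data.frame(ligand = cand, pcc = pcc, stringsAsFactors = FALSE)
  out <- out[order(-ifelse(is.na(out$pcc), -Inf, out$pcc), out$ligand), ]
  rownames(out) <- NULL
  out
}

#' Cross-validated ligand activity
#'
#' Per round, the gene set is partitioned into `folds` folds; each
#' evaluation recomputes activity with the held-out fold's genes relabeled
#' as non-members, and per-ligand mean and sd are taken over the
#' rounds x folds evaluations.
#'
#' @inheritParams ligand_activity
#' @param rounds,folds cross-validation layout (default 5 x 5)
#' @param seed integer seed (partitions are deterministic given the seed)
#' @return data.frame(ligand, cv_mean, cv_sd)
#' @export
cv_ligand_activity <- function(potential, gene_set,
                               universe = colnames(potential),
                               candidate_ligands = rownames(potential),
                               rounds = 5L, folds = 5L, seed = 0L) {
  cand <- intersect(candidate_ligands, rownames(potential))
  universe <- intersect(universe, colnames(potential))
  gene_set <- setdiff(intersect(gene_set, universe), cand)
  if (length(gene_set) < folds) stopf("gene set smaller than fold count")
  evals <- with_seed(seed, {
    res <- list()
    for (r in seq_len(rounds)) {
      fold_of <- sample(rep_len(seq_len(folds), length(gene_set)))
      for (f in seq_len(folds)) {
        kept <- gene_set[fold_of != f]
        ind <- as.numeric(universe %in% kept)
        res[[length(res) + 1L]] <- vapply(cand, function(l) {
          x <- potential[l, universe]
          if (stats::sd(x) == 0 || stats::sd(ind) == 0) return(NA_real_)
          stats::cor(x, ind)
        }, numeric(1))
      }
    }
    do.call(rbind, res)
  })
  data.frame(ligand = cand,
             cv_mean = colMeans(evals),
             cv_sd = apply(evals, 2, stats::sd),
             stringsAsFactors = FALSE)
}

# Two-sided Fisher exact p for a 2x2 table by summing hypergeometric point
# probabilities no larger than the observed table's (standard convention).
fisher_exact_p <- function(a, b, c, d) {
  m <- a + b          # row 1 margin (e.g. hallmark genes)
  n <- c + d
  k <- a + c          # column 1 margin (e.g. top-predicted genes)
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Top-quantile target enrichment of a hallmark
#'
#' Per-gene prediction score = max (or mean) regulatory potential over the
#' top ligands; "top-predicted" genes exceed the universe's
#' `quantile`-quantile of that score. Enrichment of the hallmark among
#' top-predicted genes is tested with a two-sided Fisher exact test.
#'
#' @param potential ligand x gene matrix
#' @param top_ligands ligands defining the prediction score
#' @param hallmark gene set tested for enrichment
#' @param universe gene universe
#' @param quantile top-score quantile (default 0.95, i.e. top 5%)
#' @param combine `"max"` (default) or `"mean"` across top ligands
#' @return list: contingency (2x2 integer matrix), fractions, fisher_p
#' @export
target_enrichment <- function(potential, top_ligands, hallmark,
                              universe = colnames(potential),
                              quantile = 0.95, combine = c("max", "mean")) {
  combine <- match.arg(combine)
  if (!length(top_ligands)) stopf("top_ligands must be nonempty")
  top_ligands <- intersect(top_ligands, rownames(potential))
  universe <- intersect(universe, colnames(potential))
  sub <- potential[top_ligands, universe, drop = FALSE]
  score <- if (combine == "max") apply(sub, 2, max) else colMeans(sub)
  cut <- stats::quantile(score, quantile, names = FALSE)
  top <- score > cut
  in_hm <- universe %in% hallmark
  a <- sum(in_hm & top); b <- sum(in_hm & !top)
  c_ <- sum(!in_hm & top); d <- sum(!in_hm & !top)
  tab <- matrix(c(a, c_, b, d), nrow = 2,
                dimnames = list(c("hallmark", "background"), c("top", "not_top")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate contingency table; p = 1")
    p <- 1
  } else {
    p <- fisher_exact_p(a, b, c_, d)
  }
  list(contingency = tab,
       frac_hallmark_in_top = if (a + b > 0) a / (a + b) else NA_real_,
       frac_background_in_top = if (c_ + d > 0) c_ / (c_ + d) else NA_real_,
       fisher_p = p)
}

#' Correlate LR-pair expression with hallmark scores across samples
#'
#' Pair expression is the mean of ligand and receptor log2 expression per
#' sample (complex receptors average their subunits first); Pearson r and a
#' two-sided p from the t transform with n - 2 df, per (pair, hallmark).
#'
#' @param bulk_expr genes x samples log2 matrix (e.g. MES samples only)
#' @param lr_pairs data.frame(ligand, receptor)
#' @param hallmark_scores samples x hallmark score matrix (e.g. from
#'   [ssgsea()])
#' @return data.frame(ligand, receptor, hallmark, r, p)
#' @export
corr_lr_hallmark <- function(bulk_expr, lr_pairs, hallmark_scores) {
  n <- ncol(bulk_expr)
  if (n < 3L) stopf("need >= 3 samples for correlation")
  stopifnot(identical(colnames(bulk_expr), rownames(hallmark_scores)))
  res <- list()
  for (i in seq_len(nrow(lr_pairs))) {
    lg <- lr_pairs$ligand[i]
    subs <- receptor_subunits(lr_pairs$receptor[i])[[1]]
    if (!(lg %in% rownames(bulk_expr)) || !all(subs %in% rownames(bulk_expr))) next
    rec <- colMeans(bulk_expr[subs, , drop = FALSE])
    pe <- (bulk_expr[lg, ] + rec) / 2
    for (hm in colnames(hallmark_scores)) {
      hs <- hallmark_scores[, hm]
      if (stats::sd(pe) == 0 || stats::sd(hs) == 0) {
        r <- NA_real_; p <- NA_real_
      } else {
        r <- stats::cor(pe, hs)
        tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
        p <- 2 * stats::pt(-abs(tt), df = n - 2)
      }
      res[[length(res) + 1L]] <- data.frame(
        ligand = lg, receptor = lr_pairs$receptor[i], hallmark = hm,
        r = r, p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) stopf("no ligand-receptor pair present in bulk expression")
  rownames(out) <- NULL
  out
}
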