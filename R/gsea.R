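# Preranked GSEA with a gene-permutation null, Barbie-style single-sample
# GSEA, per-subtype cell-type profiles and the log2FC bin summary.

# Weighted Kolmogorov-Smirnov running-sum enrichment score. `stat` must be
# sorted in the caller; here we take the full named signature and a set.
gsea_es <- function(stat, set, weight_exponent = 1) {
  ord <- order(stat, decreasing = TRUE)
  r <- stat[ord]
  hits <- names(r) %in% set
  n <- length(r)
  n_set <- sum(hits)
  if (n_set == 0 || n_set == n) return(NA_real_)
  w <- abs(r)^weight_exponent
  inc <- numeric(n)
  denom <- sum(w[hits])
  if (denom == 0) {
    inc[hits] <- 1 / n_set  # all-zero stats degrade to unweighted steps
  } else {
    inc[hits] <- w[hits] / denom
  }
  inc[!hits] <- -1 / (n - n_set)
  rs <- cumsum(inc)
  # extreme deviation; an exact positive/negative tie resolves to the
  # positive extreme so the statistic is implementation-stable
  mx <- max(rs); mn <- min(rs)
  if (mx + 1e-12 >= -mn) mx else mn
}

#' Preranked gene set enrichment analysis
#'
#' ES is the extreme deviation of the weighted running sum (hit increments
#' |r|^w normalized over the set, miss decrements 1/(N - n_set)). The null
#' permutes gene labels (equivalently, re-draws set positions); NES divides
#' ES by the mean |null ES| of matching sign, and the permutation p-value
#' uses the matching-sign tail with the +1 correction. Sets overlapping the
#' signature by fewer than `min_overlap` genes are skipped.
#'
#' @param signature named numeric vector (any order); finite values
#' @param sets named list of gene sets
#' @param weight_exponent GSEA weight exponent (default 1)
#' @param n_perm permutations (>= 100 recommended; 0 is an error)
#' @param seed integer seed for the permutation null
#' @param min_overlap minimum set/signature overlap
#' @return data.frame(set, size, ES, NES, p, p_adjusted, leading_edge)
#' @export
gsea_preranked <- function(signature, sets, weight_exponent = 1,
                           n_perm = 1000L, seed = 0L, min_overlap = 3L) {
  if (n_perm == 0L) stopf("n_perm must be positive")
  if (n_perm < 100L) warning("n_perm < 100 gives unstable permutation p-values")
  if (anyNA(signature) || any(!is.finite(signature))) {
    stopf("signature must be finite")
  }
  ord <- order(signature, decreasing = TRUE)
  r <- signature[ord]
  n <- length(r)
  sizes <- vapply(sets, function(s) sum(names(r) %in% s), integer(1))
  usable <- sizes >= min_overlap & sizes < n
  if (any(!usable)) {
    sc_log("gsea_preranked: skipping %d set(s) with overlap < %d",
           sum(!usable), min_overlap)
  }
  res <- lapply(names(sets)[usable], function(nm) {
    set <- sets[[nm]]
    es <- gsea_es(r, set, weight_exponent)
    n_set <- sum(names(r) %in% set)
    null_es <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        fake <- names(r)[sample.int(n, n_set)]
        gsea_es(r, fake, weight_exponent)
      }, numeric(1))
    })
    same <- null_es[sign(null_es) == sign(es)]
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    hits <- names(r) %in% set
    rs <- cumsum(ifelse(hits,
                        abs(r)^weight_exponent / max(sum(abs(r[hits])^weight_exponent), .Machine$double.eps),
                        -1 / (n - n_set)))
    peak <- if (es >= 0) which.max(rs) else which.min(rs)
    le <- if (es >= 0) names(r)[seq_len(peak)][hits[seq_len(peak)]] else
      names(r)[peak:n][hits[peak:n]]
    data.frame(set = nm, size = n_set, ES = es, NES = nes, p = p,
               leading_edge = paste(le, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    return(data.frame(set = character(0), size = integer(0), ES = numeric(0),
                      NES = numeric(0), p = numeric(0),
                      p_adjusted = numeric(0), leading_edge = character(0)))
  }
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out[, c("set", "size", "ES", "NES", "p", "p_adjusted", "leading_edge")]
}

#' Single-sample GSEA (Barbie-style)
#'
#' Per sample, genes are ranked by expression (top gene gets rank weight
#' N^alpha); the score is the summed difference between the weighted
#' in-set ECDF and the unweighted out-of-set ECDF. Sets with no overlap
#' yield NA, not zero.
#'
#' @param expr genes x samples matrix
#' @param sets named list of gene sets
#' @param alpha rank weight exponent (default 0.25)
#' @param normalize min-max normalize each set's scores across samples
#' @return samples x sets score matrix
#' @export
ssgsea <- function(expr, sets, alpha = 0.25, normalize = FALSE) {
  n <- nrow(expr)
  scores <- matrix(NA_real_, nrow = ncol(expr), ncol = length(sets),
                   dimnames = list(colnames(expr), names(sets)))
  memb <- lapply(sets, function(s) rownames(expr) %in% s)
  for (j in seq_len(ncol(expr))) {
    ord <- order(expr[, j], decreasing = TRUE,
                 method = "radix")  # stable: ties keep row order
    rw <- (n - seq_len(n) + 1)^alpha  # descending rank weights
    for (k in seq_along(sets)) {
      hits <- memb[[k]][ord]
      n_set <- sum(hits)
      if (n_set == 0 || n_set == n) next
      win <- rw * hits
      ecdf_in <- cumsum(win) / sum(win)
      ecdf_out <- cumsum(!hits) / (n - n_set)
      scores[j, k] <- sum(ecdf_in - ecdf_out)
    }
  }
  if (normalize) {
    rng <- apply(scores, 2, function(x) diff(range(x, na.rm = TRUE)))
    mins <- apply(scores, 2, min, na.rm = TRUE)
    scores <- sweep(sweep(scores, 2, mins), 2, ifelse(rng > 0, rng, 1), "/")
  }
  scores
}

#' Per-subtype cell-type profile
#'
#' For each cell type (score column): subtype means, z-scaled across
#' subtypes, and log2(subtype mean / dataset mean) where both are positive.
#'
#' @param scores samples x cell-type score matrix
#' @param labels subtype label per sample (named or aligned)
#' @return data.frame(cell_type, subtype, mean, z, log2fc_vs_mean)
#' @export
celltype_profile <- function(scores, labels) {
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(scores))
  subtypes <- intersect(SUBTYPES, unique(labels))
  out <- list()
  for (ct in colnames(scores)) {
    mu <- vapply(subtypes, function(s) mean(scores[labels == s, ct]), numeric(1))
    sdv <- stats::sd(mu)
    z <- if (is.na(sdv) || sdv == 0) rep(0, length(mu)) else (mu - mean(mu)) / sdv
    ds_mean <- mean(scores[, ct])
    lfc <- rep(NA_real_, length(mu))
    ok <- mu > 0 & ds_mean > 0
    lfc[ok] <- log2(mu[ok] / ds_mean)
    out[[ct]] <- data.frame(cell_type = ct, subtype = subtypes, mean = mu,
                            z = z, log2fc_vs_mean = lfc,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bin gene-level log2 fold-changes per gene set
#'
#' Genes are categorized as decreased (log2FC < -bin), unchanged
#' (-bin <= log2FC < bin) or increased (log2FC >= bin); the half-open
#' boundaries put exactly -bin into "unchanged" and exactly +bin into
#' "increased".
#'
#' @param de data.frame from [moderated_de()]
#' @param sets named list of gene sets
#' @param bin bin half-width (default 0.25)
#' @return data.frame(set, decreased, unchanged, increased)
#' @export
bin_hallmark_genes <- function(de, sets, bin = 0.25) {
  lfc <- stats::setNames(de$log2fc, de$gene)
  res <- lapply(names(sets), function(nm) {
    x <- lfc[intersect(sets[[nm]], names(lfc))]
    data.frame(set = nm,
               decreased = sum(x < -bin),
               unchanged = sum(x >= -bin & x < bin),
               increased = sum(x >= bin),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
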