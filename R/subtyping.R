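# Molecular subtyping with congruence filtering. The published analysis
# kept only samples on which all classifiers agreed ("ideal subtype
# representations"); the congruence rule is the defined computation here,
# applied over two transparent, replaceable classifiers: correlation to
# subtype centroids and mean z-scored signature expression.

#' Classify samples by correlation to subtype centroids
#'
#' @param expr genes x samples log2 matrix
#' @param centroids genes x subtype matrix (columns MES, IMR, DIF, PRO in
#'   any order)
#' @param method correlation flavour
#' @return list with `labels` (named character) and `scores`
#'   (samples x subtypes correlation matrix)
#' @export
classify_centroid <- function(expr, centroids, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  shared <- intersect(rownames(expr), rownames(centroids))
  if (length(shared) < 10L) {
    stopf("only %d genes shared between expression and centroids (need >= 10)",
          length(shared))
  }
  scores <- stats::cor(expr[shared, , drop = FALSE],
                       centroids[shared, , drop = FALSE], method = method)
  labels <- argmax_subtype(scores)
  list(labels = labels, scores = scores)
}

#' Classify samples by mean z-scored signature expression
#'
#' Each gene is z-scored across samples; a sample's score for a subtype is
#' the mean z of that subtype's signature genes. Genes with zero variance
#' contribute z = 0.
#'
#' @param expr genes x samples log2 matrix
#' @param signatures named list with one gene set per subtype
#' @return list with `labels` and `scores` (samples x subtypes)
#' @export
classify_signature_score <- function(expr, signatures) {
  sds <- apply(expr, 1, stats::sd)
  z <- (expr - rowMeans(expr)) / ifelse(sds > 0, sds, 1)
  z[sds == 0, ] <- 0
  scores <- vapply(names(signatures), function(s) {
    gs <- intersect(signatures[[s]], rownames(expr))
    if (!length(gs)) stopf("signature '%s' has no overlap with the data", s)
    colMeans(z[gs, , drop = FALSE])
  }, numeric(ncol(expr)))
  rownames(scores) <- colnames(expr)
  list(labels = argmax_subtype(scores), scores = scores)
}

# Deterministic argmax over subtype score columns; ties break to the
# earliest subtype in canonical order MES, IMR, DIF, PRO.
argmax_subtype <- function(scores) {
  ord <- intersect(SUBTYPES, colnames(scores))
  scores <- scores[, ord, drop = FALSE]
  labels <- ord[apply(scores, 1, which.max)]
  stats::setNames(labels, rownames(scores))
}

#' Combine classifier outputs into per-sample subtype calls
#'
#' @param ... named classifier results as returned by [classify_centroid()]
#'   or [classify_signature_score()]; at least two
#' @return data.frame with one row per sample: per-classifier labels,
#'   `consensus_label` (NA unless congruent), `congruent`, and `margin`
#'   (best minus second-best score of the first classifier)
#' @export
subtype_calls <- function(...) {
  cls <- list(...)
  if (length(cls) < 2L) stopf("congruence needs >= 2 classifiers")
  if (is.null(names(cls)) || any(!nzchar(names(cls)))) {
    names(cls) <- paste0("classifier", seq_along(cls))
  }
  samples <- names(cls[[1]]$labels)
  lab <- vapply(cls, function(cl) cl$labels[samples], character(length(samples)))
  congruent <- apply(lab, 1, function(r) length(unique(r)) == 1L)
  s1 <- cls[[1]]$scores[samples, , drop = FALSE]
  margin <- apply(s1, 1, function(r) {
    r <- sort(r, decreasing = TRUE)
    r[1] - r[2]
  })
  out <- data.frame(sample_id = samples, lab, stringsAsFactors = FALSE,
                    check.names = FALSE)
  colnames(out)[-1] <- names(cls)
  out$consensus_label <- ifelse(congruent, lab[, 1], NA_character_)
  out$congruent <- congruent
  out$margin <- margin
  rownames(out) <- NULL
  out
}

#' Per-subtype shares, printed-style
#'
#' Percentages are count / total x 100, rounded half-up to one decimal —
#' the convention behind printed cohort tables (e.g. 42/119 = 35.3).
#'
#' @param counts named integer vector of per-subtype counts
#' @return data.frame(subtype, n, percent)
#' @export
subtype_percentages <- function(counts) {
  total <- sum(counts)
  data.frame(subtype = names(counts), n = as.integer(counts),
             percent = round_half_up(100 * as.integer(counts) / total, 1),
             stringsAsFactors = FALSE)
}

#' Retain samples with congruent predictions across all classifiers
#'
#' @param calls data.frame from [subtype_calls()]
#' @return list with `retained` (sample ids), `labels` (named vector over
#'   retained samples) and `summary` (per-subtype counts and percentages
#'   over the retained set)
#' @export
consensus_filter <- function(calls) {
  keep <- calls[calls$congruent, , drop = FALSE]
  labels <- stats::setNames(keep$consensus_label, keep$sample_id)
  counts <- stats::setNames(integer(length(SUBTYPES)), SUBTYPES)
  tab <- table(factor(keep$consensus_label, levels = SUBTYPES))
  counts[names(tab)] <- as.integer(tab)
  sc_log("consensus_filter: retained %d/%d samples", nrow(keep), nrow(calls))
  list(retained = keep$sample_id, labels = labels,
       summary = subtype_percentages(counts))
}
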