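# Empirical-Bayes moderated two-group differential expression. The
# moderated t shrinks per-gene variances toward a prior fitted by method of
# moments on the log pooled variances (the scaled-F hierarchical model);
# degrees of freedom add up, which stabilizes small-cohort contrasts.

# Invert the trigamma function by Newton iteration (monotone, convex).
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy) || yy <= 0) return(Inf)
    if (yy > 1e7) return(1 / sqrt(yy))
    x <- 0.5 + 1 / yy
    for (i in 1:60) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif) < 1e-10 * x) break
    }
    x
  }, numeric(1))
}

# Method-of-moments fit of the variance prior (d0, s0^2) from log pooled
# variances with df degrees of freedom each.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) stopf("too few positive gene variances to fit a prior")
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s0sq <- exp(emean)
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0sq = s0sq)
}

#' Moderated two-group differential expression
#'
#' Per gene: log2 fold-change = mean(group A) - mean(group B); pooled
#' within-group variance s2 with n1 + n2 - 2 df; prior (d0, s0^2) fitted by
#' method of moments on log s2; posterior variance
#' (d0 s0^2 + df s2) / (d0 + df); moderated t = log2FC / sqrt(post_var *
#' (1/n1 + 1/n2)) with d0 + df degrees of freedom; two-sided p and BH
#' adjustment.
#'
#' @param expr genes x samples log2 matrix
#' @param groups vector over samples with exactly two levels; `contrast`
#'   names the level whose mean comes first
#' @param contrast level treated as group A (default: first level)
#' @return data.frame(gene, log2fc, t_moderated, p, p_adjusted) plus
#'   attributes `d0` and `s0sq`
#' @export
moderated_de <- function(expr, groups, contrast = NULL) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) stopf("groups must have exactly two levels")
  a <- contrast %||% lv[1]
  b <- setdiff(lv, a)
  ia <- which(groups == a); ib <- which(groups == b)
  if (length(ia) < 2L || length(ib) < 2L) stopf("need >= 2 samples per group")
  n1 <- length(ia); n2 <- length(ib)
  ma <- rowMeans(expr[, ia, drop = FALSE])
  mb <- rowMeans(expr[, ib, drop = FALSE])
  va <- apply(expr[, ia, drop = FALSE], 1, stats::var)
  vb <- apply(expr[, ib, drop = FALSE], 1, stats::var)
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * va + (n2 - 1) * vb) / df
  if (all(s2 == 0)) stopf("degenerate input: zero within-group variance for all genes")
  prior <- fit_variance_prior(s2, df)
  s2_post <- if (is.infinite(prior$d0)) {
    rep(prior$s0sq, length(s2))
  } else {
    (prior$d0 * prior$s0sq + df * s2) / (prior$d0 + df)
  }
  lfc <- ma - mb
  tmod <- lfc / sqrt(s2_post * (1 / n1 + 1 / n2))
  df_total <- min(prior$d0 + df, 1e6)
  p <- 2 * stats::pt(-abs(tmod), df = df_total)
  out <- data.frame(gene = rownames(expr), log2fc = lfc, t_moderated = tmod,
                    p = p, p_adjusted = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "d0") <- prior$d0
  attr(out, "s0sq") <- prior$s0sq
  out
}

#' Ranked signature from a moderated contrast
#'
#' @param de data.frame from [moderated_de()]
#' @param stat column used as the ranking statistic
#' @return named numeric vector (finite, one value per gene)
#' @export
de_signature <- function(de, stat = "t_moderated") {
  s <- stats::setNames(de[[stat]], de$gene)
  s[is.finite(s)]
}
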