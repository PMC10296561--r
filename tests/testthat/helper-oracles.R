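options(stromacall.verbose = FALSE)

# Independent oracle implementations used to check the package's fast
# paths. These are written as literal, loop-based transcriptions of the
# definitions and deliberately share no code with the package internals.

# Brute-force GSEA running sum: walk the ranked list position by position.
oracle_gsea_es <- function(stats, set, w = 1) {
  stats <- sort(stats, decreasing = TRUE)
  hit_w <- 0
  for (g in names(stats)) if (g %in% set) hit_w <- hit_w + abs(stats[[g]])^w
  n <- length(stats)
  n_set <- sum(names(stats) %in% set)
  run <- 0
  mx <- -Inf; mn <- Inf
  for (g in names(stats)) {
    if (g %in% set) {
      run <- run + if (hit_w > 0) abs(stats[[g]])^w / hit_w else 1 / n_set
    } else {
      run <- run - 1 / (n - n_set)
    }
    if (run > mx) mx <- run
    if (run < mn) mn <- run
  }
  if (mx + 1e-12 >= -mn) mx else mn
}

# Beta order-statistic CDF via the binomial sum
# P(r_(k) <= x) = sum_{j=k..M} C(M, j) x^j (1-x)^(M-j), then rho and the
# Bonferroni-corrected aggregated rank.
oracle_rra <- function(norm_ranks) {
  r <- sort(norm_ranks)
  M <- length(r)
  rho <- Inf
  for (k in seq_len(M)) {
    p <- 0
    for (j in k:M) p <- p + choose(M, j) * r[k]^j * (1 - r[k])^(M - j)
    rho <- min(rho, p)
  }
  min(rho * M, 1)
}

# Fisher two-sided p by explicit enumeration of all tables with the
# observed margins, probabilities from binomial coefficients.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; N <- a + b + c + d
  tot <- choose(N, k)
  p_obs <- choose(r1, a) * choose(r2, k - a) / tot
  p <- 0
  for (aa in 0:min(r1, k)) {
    if (k - aa > r2) next
    pr <- choose(r1, aa) * choose(r2, k - aa) / tot
    if (pr <= p_obs * (1 + 1e-7)) p <- p + pr
  }
  p
}

# Random signed network for solver cross-checks; nodes/edges small enough
# for full enumeration. DAG by construction unless cyclic = TRUE.
rand_signed_network <- function(n, m, cyclic = FALSE) {
  nodes <- sprintf("N%02d", seq_len(n))
  if (cyclic) {
    src <- sample(n, m, replace = TRUE)
    tgt <- sample(n, m, replace = TRUE)
    keep <- src != tgt
    src <- src[keep]; tgt <- tgt[keep]
  } else {
    a <- replicate(m, sort(sample(n, 2)))
    src <- a[1, ]; tgt <- a[2, ]
  }
  if (!length(src)) { src <- 1L; tgt <- 2L }
  edges <- unique(data.frame(
    source = nodes[src],
    sign = sample(c(1L, -1L), length(src), replace = TRUE),
    target = nodes[tgt], n_sources = 5L, stringsAsFactors = FALSE))
  nodes_in <- unique(c(edges$source, edges$target))
  cand <- sample(nodes_in, max(1, stats::rbinom(1, length(nodes_in), 0.3)))
  mtf <- sample(nodes_in, max(1, stats::rbinom(1, length(nodes_in), 0.4)))
  meas <- data.frame(tf = mtf,
                     sign = sample(c(1L, -1L), length(mtf), replace = TRUE),
                     weight = round(stats::runif(length(mtf), 0.5, 3), 2),
                     stringsAsFactors = FALSE)
  scores <- stats::setNames(round(stats::rnorm(length(nodes_in)), 2), nodes_in)
  list(edges = edges, cand = cand, meas = meas, scores = scores)
}

# Tiny labelled expression fixture.
toy_expr <- function(n_genes = 20, n_samples = 10, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, 7, 1), nrow = n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

quiet <- function(expr) {
  withr_old <- options(stromacall.verbose = FALSE)
  on.exit(options(withr_old))
  force(expr)
}
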