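#' @keywords internal
"_PACKAGE"

# Canonical subtype order; used for deterministic tie-breaks everywhere.
SUBTYPES <- c("MES", "IMR", "DIF", "PRO")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed percentages in the
#' literature use conventional half-up rounding, so share computations go
#' through this helper.
#'
#' @param x numeric vector
#' @param digits number of decimal digits
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so package functions never perturb user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Seed fan-out: one user-facing seed, fixed per-stage offsets, so stages can
# be rerun in isolation and still reproduce the orchestrated run.
stage_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

sc_log <- function(...) {
  if (isTRUE(getOption("stromacall.verbose", TRUE))) {
    message("[stromacall] ", sprintf(...))
  }
  invisible(NULL)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Analysis configuration
#'
#' Scalar settings shared across pipeline stages. Defaults reproduce the
#' published analysis settings: ligand-receptor aggregated-rank threshold
#' 0.05, 1000 permutations, 5 rounds of 5-fold cross-validation, top 10
#' ligands, top-5% target quantile, regulons of at least 10 targets, top
#' 100 TFs for causal inference and top 50 for the communication network,
#' beta-weight 0.9, log2 fold-change bin 0.25 and a minimum of 3 independent
#' sources for prior-knowledge edges.
#'
#' @param lr_rank_threshold significance threshold on aggregated LR ranks
#' @param n_permutations permutation count for permutation-based scores
#' @param cv_rounds,cv_folds cross-validation layout for ligand activity
#' @param n_top_ligands ligands carried into target-potential analysis
#' @param target_quantile quantile defining "most strongly predicted" targets
#' @param regulon_min_targets minimum regulon size after data intersection
#' @param n_top_tfs_global TFs (by |NES|) fed to causal inference
#' @param n_top_tfs_network TFs (by |NES|) considered for the communication
#'   network
#' @param carnival_beta node-parsimony weight of the causal objective
#' @param carnival_lambda pathway-reward weight of the causal objective
#' @param logfc_bin half-width of the "unchanged" log2FC bin
#' @param min_sources_pkn minimum evidence count for prior-knowledge edges
#' @param assume_log2 treat input expression as already log2; when FALSE,
#'   readers apply log2(x + 1)
#' @param rng_seed default seed
#' @return a named list with class `"stromacall_config"`
#' @export
analysis_config <- function(lr_rank_threshold = 0.05,
                            n_permutations = 1000L,
                            cv_rounds = 5L,
                            cv_folds = 5L,
                            n_top_ligands = 10L,
                            target_quantile = 0.95,
                            regulon_min_targets = 10L,
                            n_top_tfs_global = 100L,
                            n_top_tfs_network = 50L,
                            carnival_beta = 0.9,
                            carnival_lambda = 0.1,
                            logfc_bin = 0.25,
                            min_sources_pkn = 3L,
                            assume_log2 = TRUE,
                            rng_seed = 0L) {
  cfg <- list(
    lr_rank_threshold = lr_rank_threshold,
    n_permutations = as.integer(n_permutations),
    cv_rounds = as.integer(cv_rounds),
    cv_folds = as.integer(cv_folds),
    n_top_ligands = as.integer(n_top_ligands),
    target_quantile = target_quantile,
    regulon_min_targets = as.integer(regulon_min_targets),
    n_top_tfs_global = as.integer(n_top_tfs_global),
    n_top_tfs_network = as.integer(n_top_tfs_network),
    carnival_beta = carnival_beta,
    carnival_lambda = carnival_lambda,
    logfc_bin = logfc_bin,
    min_sources_pkn = as.integer(min_sources_pkn),
    assume_log2 = isTRUE(assume_log2),
    rng_seed = as.integer(rng_seed)
  )
  if (cfg$lr_rank_threshold < 0 || cfg$lr_rank_threshold > 1) {
    stopf("lr_rank_threshold must lie in [0, 1]")
  }
  if (cfg$target_quantile <= 0 || cfg$target_quantile >= 1) {
    stopf("target_quantile must lie in (0, 1)")
  }
  if (cfg$n_permutations < 1L) stopf("n_permutations must be positive")
  if (cfg$carnival_beta < 0) stopf("carnival_beta must be nonnegative")
  if (cfg$min_sources_pkn < 1L) stopf("min_sources_pkn must be >= 1")
  structure(cfg, class = "stromacall_config")
}
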