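# Readers/writers for the interchange formats used across the pipeline:
# dense TSV/CSV expression matrices, MatrixMarket triplets, GMT gene-set
# collections and SIF-like signed networks, plus microarray probe collapse.

#' Validate an expression matrix
#'
#' An expression matrix is a plain numeric matrix (genes in rows, samples or
#' cells in columns) with unique, non-missing dimnames and finite values.
#'
#' @param x numeric matrix
#' @return `x`, invisibly, after validation
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stopf("expression must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stopf("expression matrix must carry gene rownames and sample colnames")
  }
  dup_g <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_g)) {
    stopf("duplicate gene identifiers: %s", paste(utils::head(dup_g, 5), collapse = ", "))
  }
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s)) {
    stopf("duplicate sample identifiers: %s", paste(utils::head(dup_s, 5), collapse = ", "))
  }
  if (anyNA(x) || any(!is.finite(x))) stopf("expression matrix contains non-finite values")
  invisible(x)
}

#' Read an expression matrix
#'
#' Dense TSV/CSV files must have a header row of sample identifiers and gene
#' identifiers in the first column. MatrixMarket triplets (`format =
#' "mtx_triplet"`) are read with [Matrix::readMM()] and expect sidecar row
#' and column identifier files (one id per line).
#'
#' @param path file path
#' @param format one of `"tsv"`, `"csv"`, `"mtx_triplet"`
#' @param rows,cols id files for the MTX format; default `<path>.rows` /
#'   `<path>.cols`
#' @param assume_log2 when FALSE, values are transformed by `log2(x + 1)`
#' @return numeric matrix (genes x samples)
#' @export
read_expression <- function(path, format = c("tsv", "csv", "mtx_triplet"),
                            rows = paste0(path, ".rows"),
                            cols = paste0(path, ".cols"),
                            assume_log2 = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "mtx_triplet") {
    m <- tryCatch(
      as.matrix(Matrix::readMM(path)),
      error = function(e) stopf("malformed MTX triplet in %s: %s", path, conditionMessage(e))
    )
    gene_ids <- readLines(rows)
    sample_ids <- readLines(cols)
    if (length(gene_ids) != nrow(m) || length(sample_ids) != ncol(m)) {
      stopf("MTX dimensions (%d x %d) do not match id files (%d x %d)",
            nrow(m), ncol(m), length(gene_ids), length(sample_ids))
    }
    dimnames(m) <- list(gene_ids, sample_ids)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                             colClasses = "character", quote = "\"",
                             comment.char = "", stringsAsFactors = FALSE)
    if (ncol(raw) < 2) stopf("%s: expected an id column plus at least one sample", path)
    gene_ids <- raw[[1]]
    vals <- suppressWarnings(
      vapply(raw[-1], function(col) as.numeric(col), numeric(nrow(raw)))
    )
    vals <- matrix(vals, nrow = nrow(raw),
                   dimnames = list(gene_ids, colnames(raw)[-1]))
    if (anyNA(vals)) {
      bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
      stopf("%s: malformed numeric cell at row %d (gene '%s'), column '%s'",
            path, bad[1], gene_ids[bad[1]], colnames(vals)[bad[2]])
    }
    m <- vals
  }
  if (!assume_log2) m <- log2(m + 1)
  validate_expression_matrix(m)
  m
}

#' Write an expression matrix as dense TSV
#'
#' @param x numeric matrix with dimnames
#' @param path destination
#' @export
write_expression <- function(x, path) {
  validate_expression_matrix(x)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file
#' @param source_tag label recorded on the collection
#' @return named list of unique gene vectors with attribute `source_tag`
#' @export
read_gmt <- function(path, source_tag = basename(path)) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(structure(stats::setNames(list(), character(0)), source_tag = source_tag))
  }
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stopf("%s line %d: GMT lines need name, description and >= 1 gene", path, i)
    }
    nms[i] <- parts[1]
    sets[[i]] <- unique(parts[-(1:2)])
  }
  structure(stats::setNames(sets, nms), source_tag = source_tag)
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of gene vectors
#' @param path destination
#' @param descriptions optional per-set description column (defaults to "na")
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (!length(sets)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) stopf("all sets must be named")
  if (any(lengths(sets) == 0)) stopf("empty gene sets are not allowed")
  desc <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], unique(sets[[i]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Collapse probe-level intensities to gene level
#'
#' Implements the "MaxMean" rule: for each gene, retain the probe with the
#' largest across-sample mean. Ties break to the lexicographically smallest
#' probe id so results are independent of input order. Probes without a gene
#' mapping are dropped with a logged count.
#'
#' @param values probes x samples numeric matrix with probe rownames
#' @param probe_to_gene named character vector, probe id -> gene symbol;
#'   probes absent from the map (or mapped to NA/"") count as unmapped
#' @param rule collapse rule; only `"max_mean"` is implemented
#' @return genes x samples matrix; every row is one of the input probe rows
#' @export
collapse_probes <- function(values, probe_to_gene, rule = c("max_mean")) {
  rule <- match.arg(rule)
  if (is.null(rownames(values))) stopf("probe matrix must have probe rownames")
  genes <- probe_to_gene[rownames(values)]
  genes[genes %in% ""] <- NA_character_
  unmapped <- sum(is.na(genes))
  if (unmapped > 0) {
    sc_log("collapse_probes: dropping %d/%d unmapped probes", unmapped, nrow(values))
  }
  keep <- !is.na(genes)
  if (!any(keep)) stopf("no probe maps to any gene")
  values <- values[keep, , drop = FALSE]
  genes <- genes[keep]
  means <- rowMeans(values)
  ord <- order(genes, -means, rownames(values), method = "radix")
  pick <- ord[!duplicated(genes[ord])]
  out <- values[pick, , drop = FALSE]
  rownames(out) <- genes[pick]
  out[order(rownames(out)), , drop = FALSE]
}

#' Read a SIF-like signed, weighted network
#'
#' Expects a TSV with columns `source`, `sign`, `target`, `n_sources`.
#' Sign tokens `1`, `-1`, `activation`, `inhibition` are normalized to
#' +/- 1; anything else (including `both`, whose splitting belongs to
#' [preprocess_pkn()]) is a parse error. Row order is preserved.
#'
#' @param path TSV file
#' @return data.frame(source, sign, target, n_sources)
#' @export
read_signed_network <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  info <- file.info(path)
  first <- readLines(path, n = 1L)
  if (info$size == 0 || !length(first)) {
    return(data.frame(source = character(0), sign = integer(0),
                      target = character(0), n_sources = integer(0),
                      stringsAsFactors = FALSE))
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", stringsAsFactors = FALSE)
  need <- c("source", "sign", "target", "n_sources")
  if (!all(need %in% colnames(df))) {
    stopf("%s: expected columns %s", path, paste(need, collapse = ", "))
  }
  sign_map <- c("1" = 1L, "+1" = 1L, "activation" = 1L,
                "-1" = -1L, "inhibition" = -1L)
  sgn <- sign_map[df$sign]
  if (anyNA(sgn)) {
    bad <- which(is.na(sgn))[1]
    stopf("%s row %d: unknown sign token '%s'", path, bad, df$sign[bad])
  }
  n_src <- suppressWarnings(as.integer(df$n_sources))
  if (anyNA(n_src) || any(n_src < 0)) stopf("%s: n_sources must be nonnegative integers", path)
  data.frame(source = df$source, sign = as.integer(sgn), target = df$target,
             n_sources = n_src, stringsAsFactors = FALSE)
}

#' Write a signed network as SIF-like TSV
#' @param edges data.frame(source, sign, target, n_sources)
#' @param path destination
#' @export
write_signed_network <- function(edges, path) {
  utils::write.table(edges[, c("source", "sign", "target", "n_sources")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
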