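toy_sc <- function() {
  # 6 cells, 2 clusters; ligand L expressed only in A, receptor R only in B
  m <- rbind(L = c(3, 3, 3, 0, 0, 0),
             R = c(0, 0, 0, 2, 2, 2),
             H = c(1, 1, 1, 1, 1, 1))
  colnames(m) <- paste0("c", 1:6)
  annot <- data.frame(cell_id = colnames(m),
                      subcluster = rep(c("A", "B"), each = 3))
  list(cells = m, annot = annot)
}

test_that("subcluster filtering applies the 5-cell boundary", {
  annot <- data.frame(cell_id = paste0("c", 1:14),
                      subcluster = rep(c("A", "B", "C"), c(5, 4, 5)))
  out <- filter_subclusters(annot)
  expect_setequal(unique(out$subcluster), c("A", "C"))  # 4 cells removed, 5 kept
  expect_identical(filter_subclusters(out), out)
  expect_error(filter_subclusters(annot, min_cells = 100), "all subclusters")
})

test_that("method scores hit their closed-form anchors", {
  fx <- toy_sc()
  res <- score_methods(fx$cells, fx$annot,
                       data.frame(ligand = "L", receptor = "R"),
                       n_perm = 200, seed = 1)
  ab <- res[res$sender == "A" & res$receiver == "B", ]
  # exclusive expression -> specificity exactly 1
  expect_equal(ab$m3, 1.0)
  expect_equal(ab$m1, (3 + 2) / 2)
  # ligand absent in sender -> m1 missing, not zero
  ba <- res[res$sender == "B" & res$receiver == "A", ]
  expect_true(is.na(ba$m1))
  # absent resource genes are skipped, all-absent errors
  expect_error(score_methods(fx$cells, fx$annot,
                             data.frame(ligand = "X", receptor = "Y"),
                             n_perm = 10), "no resource entry")
})

test_that("permutation p matches exhaustive label enumeration on a toy", {
  fx <- toy_sc()
  res <- score_methods(fx$cells, fx$annot,
                       data.frame(ligand = "L", receptor = "R"),
                       n_perm = 4000, seed = 7)
  obs <- res$m1[res$sender == "A" & res$receiver == "B"]
  # enumerate all C(6,3) = 20 assignments of cells to cluster A
  combos <- combn(6, 3)
  stats <- apply(combos, 2, function(ia) {
    ib <- setdiff(1:6, ia)
    (mean(fx$cells["L", ia]) + mean(fx$cells["R", ib])) / 2
  })
  p0 <- mean(stats >= obs)
  p_exact_ish <- (1 + 4000 * p0) / (1 + 4000)
  got <- res$m2[res$sender == "A" & res$receiver == "B"]
  se <- sqrt(p0 * (1 - p0) / 4000)
  expect_lt(abs(got - p_exact_ish), 4 * se + 1e-6)
})

test_that("rank aggregation reproduces closed-form beta order statistics", {
  # two methods, normalized ranks 0.1 and 0.5
  df <- data.frame(a = c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1),
                   b = c(5, 10, 9, 8, 7, 6, 4, 3, 2, 1))
  out <- aggregate_ranks(df, directions = c(a = 1, b = 1))
  # top interaction: ranks (1/10, 5/10) -> rho = 1-(0.9)^2 = 0.19 -> 0.38
  expect_equal(out$aggregated_rank[1], 0.38, tolerance = 1e-12)
  # unanimity dominates: best-by-all ranks strictly first
  df2 <- data.frame(a = 5:1, b = 5:1, c = 5:1)
  out2 <- aggregate_ranks(df2, directions = c(a = 1, b = 1, c = 1))
  expect_true(out2$aggregated_rank[1] < min(out2$aggregated_rank[-1]))
  # all-tied methods -> equal aggregated ranks
  df3 <- data.frame(a = rep(1, 4), b = rep(2, 4))
  out3 <- aggregate_ranks(df3, directions = c(a = 1, b = 1))
  expect_equal(length(unique(out3$aggregated_rank)), 1L)
  # invariant to method relabeling
  out4 <- aggregate_ranks(df[, c("b", "a")], directions = c(b = 1, a = 1))
  expect_equal(out4$aggregated_rank, out$aggregated_rank)
})

test_that("missing scores rank worst and cannot promote an interaction", {
  df <- data.frame(a = c(10, NA, 8, 6, 4), b = c(10, 9, 8, 7, 6))
  out <- aggregate_ranks(df, directions = c(a = 1, b = 1))
  expect_equal(out$rank_a[2], 1.0)
  # row 2 is second-best by b but its NA a-rank keeps it behind row 1
  expect_gt(out$aggregated_rank[2], out$aggregated_rank[1])
  expect_equal(out$aggregated_rank[2], 1.0)  # min(2 * pbeta(0.4; 1, 2), 1)
})

test_that("network summary counts, dedups and ranks as stated", {
  sig <- data.frame(
    sender = c("A", "A", "B", "B", "C", "C"),
    receiver = c("B", "C", "A", "A", "A", "B"),
    ligand = c("L1", "L1", "L1", "L2", "L2", "L2"),
    receptor = c("R1", "R1", "R1", "R2", "R2", "R2"))
  mm <- c(A = "tumour", B = "fibro", C = "fibro")
  s <- summarize_network(sig, mm)
  expect_equal(s$totals$total[s$totals$subcluster == "A"], 5L)
  expect_equal(sum(s$sender_receiver$count), 6L)
  expect_equal(s$sender_receiver$proportion[
    s$sender_receiver$sender == "A" & s$sender_receiver$receiver == "B"], 1 / 6)
  # tumour participates in (L1,R1) and (L2,R2) -> 2 unique
  expect_equal(s$unique_per_major$unique_interactions[
    s$unique_per_major$major_type == "tumour"], 2L)
  expect_equal(s$ligand_ranks$rank, c(1L, 1L))
  empty <- summarize_network(sig[0, ], mm)
  expect_true(all(empty$totals$total == 0))
})

test_that("planted interactions are significant; absent ligands never are", {
  r <- make_resources(seed = 0)
  sc <- make_single_cell(r$bundle, r$truth, cells_per_subcluster = 30, seed = 0)
  lr <- lr_consensus(sc$cells, sc$annot, r$bundle$lr_resource,
                     n_perm = 300, seed = 2)
  for (snd in names(r$truth$planted_ligands)) {
    for (lg in r$truth$planted_ligands[[snd]]) {
      rows <- lr[lr$ligand == lg & lr$sender == snd &
                   lr$receiver %in% r$truth$planted_receivers, ]
      expect_true(all(rows$significant))
    }
  }
  # a ligand with literally zero expression in the sender cannot score
  zero_expr <- tapply(seq_len(ncol(sc$cells)), sc$annot$subcluster,
                      function(ix) rowSums(sc$cells[lr$ligand[1], ix, drop = FALSE]))
  lig_sum <- rowsum(t(sc$cells[unique(lr$ligand), , drop = FALSE]),
                    sc$annot$subcluster)
  for (i in seq_len(nrow(lr))) {
    if (lig_sum[lr$sender[i], lr$ligand[i]] == 0) {
      expect_true(is.na(lr$m1[i]))
      expect_false(lr$significant[i])
    }
  }
})
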