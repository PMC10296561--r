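test_that("ligand activity correlates potential with set membership", {
  g <- paste0("g", 1:6)
  pot <- rbind(L1 = c(1, 1, 0, 0, 0, 0),   # equals the indicator
               L2 = c(0.2, 0.2, 0.2, 0.2, 0.2, 0.2),  # constant -> NA
               L3 = c(0.9, 0.1, 0.8, 0.3, 0.2, 0.1))
  colnames(pot) <- g
  act <- ligand_activity(pot, c("g1", "g2"))
  expect_equal(act$pcc[act$ligand == "L1"], 1.0)
  expect_true(is.na(act$pcc[act$ligand == "L2"]))
  expect_equal(act$ligand[nrow(act)], "L2")  # NA ranks last
  # arithmetic oracle for L3
  ind <- c(1, 1, 0, 0, 0, 0)
  expect_equal(act$pcc[act$ligand == "L3"], cor(pot["L3", ], ind))
  # invariance to positive affine rescaling of a potential row
  pot2 <- pot
  pot2["L3", ] <- 3 * pot2["L3", ] + 0.7
  act2 <- ligand_activity(pot2, c("g1", "g2"))
  expect_equal(act2$pcc, act$pcc)
  # ligands are removed from the gene set before scoring
  pot3 <- rbind(pot, g1 = c(1, 0, 0, 0, 0, 0))
  act3 <- ligand_activity(pot3, c("g1", "g2"))
  ind_no_lig <- c(0, 1, 0, 0, 0, 0)
  expect_equal(act3$pcc[act3$ligand == "L3"], cor(pot["L3", ], ind_no_lig))
  expect_error(ligand_activity(pot, "g1", candidate_ligands = character(0)),
               "empty candidate")
})

test_that("cross-validated activity behaves like held-out scoring", {
  set.seed(5)
  g <- paste0("g", 1:30)
  pot <- matrix(runif(2 * 30, 0, 0.1), nrow = 2, dimnames = list(c("L1", "L2"), g))
  set <- g[1:10]
  pot["L1", set] <- 1  # potential equal to the indicator pattern
  cv <- cv_ligand_activity(pot, set, rounds = 2, folds = 5, seed = 3)
  # held-out positives are counted as negatives -> 0 < cv pcc < 1
  expect_true(cv$cv_mean[cv$ligand == "L1"] > 0 &&
                cv$cv_mean[cv$ligand == "L1"] < 1)
  cv2 <- cv_ligand_activity(pot, set, rounds = 2, folds = 5, seed = 3)
  expect_identical(cv, cv2)
  expect_error(cv_ligand_activity(pot, g[1:3], folds = 5), "smaller than")
})

test_that("Fisher exact p matches enumeration and anchors", {
  # identical proportions -> p = 1
  expect_equal(stromacall:::fisher_exact_p(1, 9, 1, 9), 1.0)
  # [[5,0],[0,5]] -> 2/252
  expect_equal(stromacall:::fisher_exact_p(5, 0, 0, 5), 2 / choose(10, 5),
               tolerance = 1e-12)
  set.seed(8)
  for (i in 1:50) {
    a <- rpois(1, 3); b <- rpois(1, 3); c <- rpois(1, 3); d <- rpois(1, 3)
    expect_equal(stromacall:::fisher_exact_p(a, b, c, d),
                 oracle_fisher(a, b, c, d), tolerance = 1e-10)
  }
})

test_that("target enrichment builds consistent tables", {
  g <- sprintf("g%03d", 1:100)
  pot <- matrix(runif(2 * 100, 0, 0.5), nrow = 2,
                dimnames = list(c("L1", "L2"), g))
  hallmark <- g[1:10]
  # distinct high scores (a tied block at the quantile would fall outside
  # the strict > cut by definition)
  pot["L1", hallmark] <- seq(5, 10, length.out = 10)
  te <- target_enrichment(pot, c("L1", "L2"), hallmark)
  # every top-predicted gene is a hallmark gene
  expect_equal(te$contingency["background", "top"], 0L)
  expect_gte(te$contingency["hallmark", "top"], 4L)
  expect_equal(sum(te$contingency), 100)
  expect_equal(sum(te$contingency["hallmark", ]), 10)
  expect_equal(te$frac_hallmark_in_top,
               te$contingency["hallmark", "top"] / 10)
  expect_lt(te$fisher_p, 1e-4)
  expect_error(target_enrichment(pot, character(0), hallmark), "nonempty")
})

test_that("LR-pair/hallmark correlation matches the t transform", {
  set.seed(9)
  expr <- toy_expr(6, 10, seed = 9)
  rownames(expr)[1:2] <- c("L", "R")
  hm <- matrix(colMeans(expr[c("L", "R"), ]), ncol = 1,
               dimnames = list(colnames(expr), "H1"))
  out <- corr_lr_hallmark(expr, data.frame(ligand = "L", receptor = "R"), hm)
  expect_equal(out$r, 1.0)
  hm2 <- matrix(rnorm(10), ncol = 1, dimnames = list(colnames(expr), "H1"))
  out2 <- corr_lr_hallmark(expr, data.frame(ligand = "L", receptor = "R"), hm2)
  ct <- cor.test(colMeans(expr[c("L", "R"), ]), hm2[, 1])
  expect_equal(out2$r, unname(ct$estimate))
  expect_equal(out2$p, ct$p.value, tolerance = 1e-10)
  expect_error(corr_lr_hallmark(expr[, 1:2, drop = FALSE],
                                data.frame(ligand = "L", receptor = "R"),
                                hm[1:2, , drop = FALSE]), ">= 3")
})
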