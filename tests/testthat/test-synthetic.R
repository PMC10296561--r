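test_that("make_resources is deterministic and honours its invariants", {
  r1 <- make_resources(seed = 5)
  r2 <- make_resources(seed = 5)
  expect_identical(r1, r2)
  r3 <- make_resources(seed = 6)
  expect_false(identical(r1$bundle$regulons$target, r3$bundle$regulons$target))

  b <- r1$bundle; tr <- r1$truth
  expect_true(all(table(b$regulons$tf) == synth_config()$regulon_size))
  expect_true(all(table(b$regulons$tf) >= 10))
  # every planted ligand appears in the LR resource
  expect_true(all(unlist(tr$planted_ligands) %in% b$lr_resource$ligand))
  # planted TF signs follow the sign algebra along the (unique) PKN paths
  pkn <- b$pkn[b$pkn$n_sources >= 3, ]
  for (s in c("MES", "IMR", "DIF", "PRO")) {
    pk <- tr$planted_kinases[[s]]
    pt <- tr$planted_tfs[[s]]
    for (i in seq_len(nrow(pt))) {
      e2 <- pkn[pkn$target == pt$tf[i], ]
      e1 <- pkn[pkn$target == e2$source & pkn$source %in% pk$kinase, ]
      expect_equal(nrow(e1), 1L)
      ksign <- pk$sign[pk$kinase == e1$source]
      expect_equal(pt$sign[i], ksign * e1$sign * e2$sign)
    }
  }
  # infeasible config
  expect_error(make_resources(synth_config(n_kinases = 4L)), "infeasible")
})

test_that("make_bulk plants exact shifts at zero noise", {
  cfg <- synth_config(noise_sd = 0)
  r <- make_resources(cfg, seed = 3)
  bulk <- make_bulk(r$bundle, r$truth, n_per_subtype = 3, seed = 4)
  expect_equal(ncol(bulk$expr), 12)
  expect_equal(as.integer(table(bulk$subtype_of_sample)), rep(3L, 4))
  pt <- r$truth$planted_tfs$MES
  tg <- r$bundle$regulons[r$bundle$regulons$tf == pt$tf[1], ]
  other_tfs <- setdiff(unlist(lapply(r$truth$planted_tfs, `[[`, "tf")),
                       pt$tf[1])
  other_targets <- r$bundle$regulons$target[r$bundle$regulons$tf %in% other_tfs]
  mes_only <- setdiff(tg$target, other_targets)
  tg <- tg[match(mes_only[1], tg$target), ]
  g <- tg$target[1]
  mes <- mean(bulk$expr[g, bulk$subtype_of_sample == "MES"])
  # PRO samples carry no MES program for this gene (disjoint planted TFs)
  ref <- mean(bulk$expr[g, bulk$subtype_of_sample == "PRO"])
  expect_equal(mes - ref, tg$mode[1] * pt$sign[1] * cfg$effect_size_log2,
               tolerance = 1e-12)
  expect_error(make_bulk(r$bundle, r$truth, n_per_subtype = 1), ">= 2")
})

test_that("make_single_cell plants senders and annotates every cell", {
  r <- make_resources(seed = 2)
  sc <- make_single_cell(r$bundle, r$truth, cells_per_subcluster = 20, seed = 2)
  expect_equal(ncol(sc$cells), 20 * 13)
  expect_false(anyNA(sc$annot$major_type))
  # subcluster -> major type is a function
  expect_equal(nrow(unique(sc$annot[, c("subcluster", "major_type")])), 13)
  # a planted ligand's mean expression peaks in its sender subcluster
  for (snd in names(r$truth$planted_ligands)) {
    for (lg in r$truth$planted_ligands[[snd]]) {
      mu <- tapply(sc$cells[lg, ], sc$annot$subcluster, mean)
      expect_equal(names(which.max(mu)), snd)
    }
  }
  expect_error(make_single_cell(r$bundle, r$truth, cells_per_subcluster = 4),
               ">= 5")
})

test_that("write_simulation emits a readable, reloadable input set", {
  d <- withr::local_tempdir()
  paths <- write_simulation(d, synth_config(), n_per_subtype = 2,
                            cells_per_subcluster = 5, seed = 11)
  expect_true(all(file.exists(paths)))
  expr <- read_expression(paths[["bulk_expr.tsv"]])
  expect_equal(ncol(expr), 8)
  hm <- read_gmt(paths[["hallmarks.gmt"]])
  expect_true("HALLMARK_EPITHELIAL_MESENCHYMAL_TRANSITION" %in% names(hm))
  pkn <- read_signed_network(paths[["pkn.tsv"]])
  expect_true(all(pkn$sign %in% c(-1L, 1L)))
})
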