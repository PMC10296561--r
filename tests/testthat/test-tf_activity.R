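test_that("tf_nes is extremal, symmetric and rank-invariant", {
  set.seed(13)
  genes <- sprintf("g%03d", 1:200)
  sig <- setNames(sort(rnorm(200), decreasing = TRUE), genes)
  reg_top <- data.frame(tf = "T1", target = genes[1:15], mode = 1L)
  # all +1 targets at the top ranks: maximal positive NES for that size
  nes_top <- tf_nes(sig, reg_top, contrast = "x")$nes
  expect_gt(nes_top, 0)
  for (i in 1:5) {
    rnd <- data.frame(tf = "T1", target = sample(genes, 15), mode = 1L)
    expect_lte(tf_nes(sig, rnd)$nes, nes_top + 1e-12)
  }
  # symmetric placement around the median -> NES ~ 0
  sym <- data.frame(tf = "T1", target = genes[c(1:7, 194:200)], mode = 1L)
  expect_lt(abs(tf_nes(sig, sym)$nes), 0.5)
  # invariance under strictly monotone transform
  reg <- data.frame(tf = "T1", target = sample(genes, 20), mode = rep(c(1L, -1L), 10))
  expect_equal(tf_nes(sig, reg)$nes, tf_nes(exp(sig), reg)$nes)
  # flipping all modes negates NES exactly
  reg_f <- transform(reg, mode = -mode)
  expect_equal(tf_nes(sig, reg_f)$nes, -tf_nes(sig, reg)$nes)
  # size filter excludes small regulons
  small <- data.frame(tf = "T2", target = genes[1:5], mode = 1L)
  expect_error(tf_nes(sig, small), "no regulon")
  both <- rbind(reg, small)
  expect_equal(tf_nes(sig, both)$tf, "T1")
})

test_that("analytic NES is calibrated against a permutation z", {
  set.seed(14)
  genes <- sprintf("g%04d", 1:800)
  sig <- setNames(rnorm(800), genes)
  for (i in 1:3) {
    n <- sample(12:25, 1)
    reg <- data.frame(tf = "T", target = sample(genes, n),
                      mode = sample(c(1L, -1L), n, replace = TRUE, prob = c(0.8, 0.2)))
    nes <- tf_nes(sig, reg)$nes
    q <- qnorm(rank(sig) / 801)
    es_obs <- sum(reg$mode * q[match(reg$target, genes)]) / sqrt(n)
    null <- vapply(1:20000, function(j) {
      sum(reg$mode * q[sample.int(800, n)]) / sqrt(n)
    }, numeric(1))
    z_emp <- (es_obs - mean(null)) / sd(null)
    expect_lt(abs(nes - z_emp), 0.1)
  }
})

test_that("pairwise contrasts are exactly antisymmetric and recover truth", {
  cfg <- synth_config(noise_sd = 0)
  r <- make_resources(cfg, seed = 21)
  bulk <- make_bulk(r$bundle, r$truth, n_per_subtype = 4, seed = 22)
  pw <- pairwise_tf_nes(bulk$expr, bulk$subtype_of_sample, r$bundle$regulons)
  for (x in c("IMR", "DIF", "PRO")) {
    f <- pw[pw$contrast == paste0("MES_vs_", x), ]
    b <- pw[pw$contrast == paste0(x, "_vs_MES"), ]
    expect_equal(setNames(b$nes, b$tf)[f$tf], -setNames(f$nes, f$tf)[f$tf],
                 tolerance = 1e-10)
    # zero-noise: every planted MES TF has its planted NES sign
    pt <- r$truth$planted_tfs$MES
    got <- setNames(f$nes, f$tf)[pt$tf]
    expect_equal(unname(sign(got)), pt$sign)
  }
  expect_error(pairwise_tf_nes(bulk$expr,
                               rep("MES", ncol(bulk$expr)),
                               r$bundle$regulons), "at least one other")
  # top-k selection is deterministic and returns k rows
  f <- pw[pw$contrast == "MES_vs_IMR", ]
  expect_equal(nrow(top_tfs(f, 7)), 7)
  expect_equal(top_tfs(f, 7), top_tfs(f[sample(nrow(f)), ], 7))
})

test_that("communication network applies retention and regulator counts", {
  sig_lr <- data.frame(ligand = c("L1", "L2", "L3", "L4", "L5"),
                       receptor = c("R1", "R2", "R3", "R4", "R5"))
  tf_acts <- data.frame(tf = c("T1", "T2", "T3"), nes = c(3, -2, 1))
  links <- data.frame(ligand = c("L1", "L2", "L9"),
                      receptor = c("R1", "R2", "R9"),
                      tf = c("T1", "T2", "T1"))
  tc <- data.frame(tf = c("T1", "T2", "T1", "T2"),
                   cytokine = c("C1", "C1", "C2", "C2"),
                   mode = c(1L, -1L, 1L, 1L))
  de <- data.frame(gene = c("C1", "C2"), log2fc = c(1.2, -0.4),
                   t_moderated = c(5, -2), p = c(0.001, 0.1),
                   p_adjusted = c(0.01, 0.2))
  net <- assemble_comm_network(sig_lr, tf_acts, links, tc, de)
  # T3 has no cytokine link -> dropped
  expect_setequal(net$nodes$id[net$nodes$type == "tf"], c("T1", "T2"))
  # both cytokines are regulated by 2 retained TFs
  expect_equal(net$nodes$regulator_count[net$nodes$type == "cytokine"],
               c(2L, 2L))
  expect_equal(net$nodes$log2fc[net$nodes$id == "C1"], 1.2)
  # L9/R9 not significant -> excluded; hand-drawn edge set
  expect_setequal(paste(net$edges$from, net$edges$to),
                  c("L1 R1", "L2 R2", "R1 T1", "R2 T2",
                    "T1 C1", "T2 C1", "T1 C2", "T2 C2"))
  # no retained TF -> error
  expect_error(assemble_comm_network(sig_lr, data.frame(tf = "T9", nes = 1),
                                     links, tc, de), "no TF retained")
})
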