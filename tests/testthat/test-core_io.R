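test_that("expression readers round-trip and report malformed input", {
  m <- toy_expr(5, 3)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, tsv)
  expect_equal(read_expression(tsv), m)

  csv_bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "A\t1.0\t2.0", "B\tx\t3.0"), csv_bad)
  expect_error(read_expression(csv_bad), "row 2.*'B'.*'s1'")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1", "A\t1", "A\t2"), dup)
  expect_error(read_expression(dup), "duplicate gene identifiers: A")

  # log2 transform applied on request
  raw <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1", "A\t3", "B\t7"), raw)
  expect_equal(unname(read_expression(raw, assume_log2 = FALSE)[, 1]),
               log2(c(4, 8)))
})

test_that("MTX triplet reading honours id files and bounds", {
  d <- withr::local_tempdir()
  mtx <- file.path(d, "m.mtx")
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "2 2 3", "1 1 1.5", "2 1 2.5", "2 2 3.5"), mtx)
  writeLines(c("gA", "gB"), paste0(mtx, ".rows"))
  writeLines(c("s1", "s2"), paste0(mtx, ".cols"))
  m <- read_expression(mtx, format = "mtx_triplet")
  expect_equal(m["gB", "s2"], 3.5)
  expect_equal(m["gA", "s2"], 0)

  bad <- file.path(d, "bad.mtx")
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "2 2 1", "3 1 1.0"), bad)
  writeLines(c("gA", "gB"), paste0(bad, ".rows"))
  writeLines(c("s1", "s2"), paste0(bad, ".cols"))
  expect_error(read_expression(bad, format = "mtx_triplet"), "malformed MTX")
})

test_that("GMT round-trips, warns on empty, errors on short lines", {
  sets <- list(S1 = c("g1", "g2"), S2 = c("g3", "g2", "g4"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  back <- read_gmt(f)
  expect_equal(unname(lengths(back)), c(2L, 3L))
  expect_equal(back$S2, sets$S2)

  empty <- withr::local_tempfile(fileext = ".gmt")
  writeLines(character(0), empty)
  expect_warning(out <- read_gmt(empty), "empty GMT")
  expect_length(out, 0)

  short <- withr::local_tempfile(fileext = ".gmt")
  writeLines("S1\tdesc", short)
  expect_error(read_gmt(short), "line 1")
})

test_that("collapse_probes applies MaxMean with deterministic ties", {
  vals <- rbind(p1 = c(1, 1), p2 = c(2, 2), p3 = c(5, 5), q1 = c(3, 3))
  colnames(vals) <- c("s1", "s2")
  map <- c(p1 = "A", p2 = "A", p3 = "B", q1 = NA)
  withr::with_options(list(stromacall.verbose = TRUE),
                      expect_message(collapse_probes(vals, map), "dropping 1/4"))
  out <- collapse_probes(vals, map)
  expect_equal(rownames(out), c("A", "B"))
  expect_equal(unname(out["A", ]), c(2, 2))  # p2 has the larger mean

  # tie: lexicographically smaller probe id wins
  vals2 <- rbind(pa = c(1, 3), pb = c(3, 1))
  colnames(vals2) <- c("s1", "s2")
  out2 <- collapse_probes(vals2, c(pa = "A", pb = "A"))
  expect_equal(unname(out2["A", ]), c(1, 3))

  # every output row equals some input row; identity when 1 probe/gene
  expect_equal(unname(collapse_probes(vals2, c(pa = "A", pb = "B"))),
               unname(vals2[order(c("A", "B")), ]))
  expect_error(collapse_probes(vals2, c(pa = NA, pb = NA)), "no probe maps")
})

test_that("signed network reader normalizes tokens and rejects 'both'", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\tsign\ttarget\tn_sources",
               "K1\tactivation\tTF1\t4",
               "K2\t-1\tTF2\t3"), f)
  net <- read_signed_network(f)
  expect_equal(net$sign, c(1L, -1L))
  expect_equal(net$source, c("K1", "K2"))

  g <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\tsign\ttarget\tn_sources", "K1\tboth\tTF1\t4"), g)
  expect_error(read_signed_network(g), "unknown sign token 'both'")

  h <- withr::local_tempfile(fileext = ".tsv")
  file.create(h)
  expect_equal(nrow(read_signed_network(h)), 0)

  # round-trip
  out <- withr::local_tempfile(fileext = ".tsv")
  write_signed_network(net, out)
  expect_equal(read_signed_network(out), net)
})
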