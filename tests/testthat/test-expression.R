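test_that("expression tables load with header sniffing and validation", {
  f <- tempfile()
  writeLines(c("AT1G01010\t2.5", "AT1G01020\t-0.3"), f)
  expect_equal(loadExpression(f),
               c(AT1G01010 = 2.5, AT1G01020 = -0.3))

  fh <- tempfile()
  writeLines(c("gene\tfc", "AT1G01010\t2.5"), fh)
  expect_equal(loadExpression(fh), c(AT1G01010 = 2.5))

  fd <- tempfile()
  writeLines(c("AT1G01010\t2.5", "AT1G01010\t1.0"), fd)
  expect_error(loadExpression(fd), "duplicate.*AT1G01010")

  fb <- tempfile()
  writeLines(c("AT1G01010\t2.5", "AT1G01030\tabc"), fb)
  expect_error(loadExpression(fb), "non-numeric.*AT1G01030")

  fe <- tempfile(); file.create(fe)
  expect_error(loadExpression(fe), "empty")
})

test_that("fold-change thresholding handles both scales and directions", {
  expect_true(isAboveThreshold(-1.5, 1, "log2"))
  expect_false(isAboveThreshold(0.5, 1, "log2"))
  expect_true(isAboveThreshold(0.25, 2, "linear"))   # 4-fold down
  expect_true(isAboveThreshold(3, 2, "linear"))
  expect_false(isAboveThreshold(1.5, 2, "linear"))
  expect_error(isAboveThreshold(-1, 2, "linear"), "> 0")
})

test_that("binding score terms follow the enrichment-ratio formula", {
  # equal proportions: ln(1) = 0
  expect_equal(bindingScore(1, 2, 10, 4, 20), 0)
  # empty locus: empty sum
  expect_equal(bindingScore(numeric(0), numeric(0), numeric(0), 4, 20), 0)
  # worked example: 2 * ln((2/10)/(4/40)) = 2 ln 2
  expect_equal(bindingScore(1, 2, 10, 4, 40), 2 * log(2))
  # V_PWM scales linearly
  expect_equal(bindingScore(0.5, 2, 10, 4, 40), log(2))
  # zero-count guard: no infinities
  expect_equal(bindingScore(1, 0, 10, 4, 40), 0)
  expect_equal(bindingScore(1, 2, 10, 0, 40), 0)

  # additivity over any partition of the hit list
  set.seed(21)
  v <- runif(10); bfs <- sample(1:5, 10, TRUE); bts <- bfs + sample(1:5, 10, TRUE)
  total <- bindingScore(v, bfs, bts, 12, 60)
  cut <- sample(1:9, 1)
  expect_equal(bindingScore(v[1:cut], bfs[1:cut], bts[1:cut], 12, 60) +
                 bindingScore(v[-(1:cut)], bfs[-(1:cut)], bts[-(1:cut)],
                              12, 60),
               total)

  # monotone in B_FC_Spec with everything else fixed
  bs1 <- bindingScore(1, 2, 10, 4, 40)
  bs2 <- bindingScore(1, 3, 10, 4, 40)
  expect_gte(bs2, bs1)
})

test_that("chi-squared enrichment matches hand arithmetic on 2x2 tables", {
  # identical DE proportions: homogeneity, stat 0, p 1
  r <- chiSquareEnrichment(40, 20, 20, 10)
  expect_equal(r$stat, 0)
  expect_equal(r$p, 1)

  r2 <- chiSquareEnrichment(40, 20, 20, 10, include_specific_in_all = TRUE)
  expect_equal(r2$stat, 0)

  # table [[30,10],[10,30]]: all expected cells 20,
  # stat = 4 * (30-20)^2/20 = 20 (hand-evaluated sum of (O-E)^2/E)
  r3 <- chiSquareEnrichment(genes_with_sites_all = 80,
                            genes_with_sites_and_DE_all = 40,
                            genes_with_sites_spec = 40,
                            genes_with_sites_and_DE_spec = 30)
  expect_equal(unname(r3$table), rbind(c(30, 10), c(10, 30)))
  expect_equal(r3$stat, 20, tolerance = 1e-12)
  expect_equal(r3$df, 1L)
  # independent arithmetic oracle on the same table
  O <- r3$table
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(r3$stat, sum((O - E)^2 / E), tolerance = 1e-12)

  # zero expected cell: flagged, not computed
  r4 <- chiSquareEnrichment(10, 0, 5, 0)
  expect_false(r4$computed)
  expect_true(is.na(r4$p))

  expect_error(chiSquareEnrichment(10, 11, 5, 2), "inconsistent")
})

test_that("target classes split on threshold and site presence", {
  expr <- c(g1 = 2.0, g2 = 1.5, g3 = 0.2)
  cls <- classifyTargets(c("g1", "g2", "g3", "g4"), c(2L, 0L, 5L, 1L),
                         expr, FCT = 1)
  expect_equal(cls$target_class,
               c("primary", "secondary", "unchanged", "unchanged"))
  expect_equal(cls$flag, c("", "", "", "no expression data"))
})

test_that("binding score report assembles consistent genome-wide counts", {
  hits <- data.frame(
    gene_id = c("g1", "g1", "g2", "g3", "g4"),
    strand = "forward",
    sequence = c("GGA", "GGT", "GGA", "GGA", "GGT"),
    region = c("utr5", "exon_cds", "intergenic5", "utr3", "intron"),
    stringsAsFactors = FALSE)
  expr <- c(g1 = 2, g2 = -1.5, g3 = 0.1, g4 = 0.2, g5 = 3)
  rpt <- bindingScoreReport(hits, expr, FCT = 1, specific_word = "GGA")
  enr <- attr(rpt, "enrichment")
  expect_equal(enr$B_Tot, 5L)
  expect_equal(enr$B_FC, 3L)          # sites in DE genes g1 (2) + g2 (1)
  expect_equal(enr$B_Tot_Spec, 3L)    # GGA sites
  expect_equal(enr$B_FC_Spec, 2L)     # GGA in g1, g2
  expect_lte(enr$B_FC_Spec, enr$B_FC)
  expect_lte(enr$B_Tot_Spec, enr$B_Tot)

  expect_equal(rpt$target_class[rpt$gene_id == "g1"], "primary")
  expect_equal(rpt$target_class[rpt$gene_id == "g5"], "secondary")
  expect_equal(rpt$target_class[rpt$gene_id == "g3"], "unchanged")
  # gene without hits has BS 0; regions column lists hit kinds in order
  expect_equal(rpt$BS[rpt$gene_id == "g5"], 0)
  expect_equal(rpt$regions[rpt$gene_id == "g1"], "utr5,exon_cds")

  # reverse-strand hits are counted in motif orientation
  hits_rc <- hits
  hits_rc$strand <- "reverse"
  hits_rc$sequence <- vapply(c("TCC", "ACC", "TCC", "TCC", "ACC"),
                             identity, "")
  rpt2 <- bindingScoreReport(hits_rc, expr, FCT = 1, specific_word = "GGA")
  expect_equal(attr(rpt2, "enrichment")$B_Tot_Spec, 3L)
})
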