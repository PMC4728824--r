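test_that("IUPAC compilation follows the degeneration table", {
  expect_setequal(compileIupac("R")@allowed[[1]], c("A", "G"))
  expect_setequal(compileIupac("Y")@allowed[[1]], c("C", "T"))
  expect_setequal(compileIupac("S")@allowed[[1]], c("C", "G"))
  expect_setequal(compileIupac("W")@allowed[[1]], c("A", "T"))
  expect_setequal(compileIupac("K")@allowed[[1]], c("G", "T"))
  expect_setequal(compileIupac("M")@allowed[[1]], c("A", "C"))
  expect_setequal(compileIupac("B")@allowed[[1]], c("C", "G", "T"))
  expect_setequal(compileIupac("D")@allowed[[1]], c("A", "G", "T"))
  expect_setequal(compileIupac("H")@allowed[[1]], c("A", "C", "T"))
  expect_setequal(compileIupac("V")@allowed[[1]], c("A", "C", "G"))
  expect_setequal(compileIupac("N")@allowed[[1]], c("A", "C", "G", "T"))
  expect_identical(lengths(compileIupac("ACGT")@allowed),
                   setNames(rep(1L, 4), c("A", "C", "G", "T")))
  expect_identical(motifText(compileIupac("acgw")), "ACGW")
  expect_error(compileIupac("ACGX"), "invalid IUPAC character 'X' at position 4")
})

test_that("pattern reverse complement is the standard code mapping", {
  expect_identical(motifText(reverseComplementPattern(compileIupac("ATCCG"))),
                   "CGGAT")
  expect_identical(motifText(reverseComplementPattern(compileIupac("R"))),
                   "Y")
  # complement of {A,G} is {C,T}
  expect_setequal(reverseComplementPattern(compileIupac("R"))@allowed[[1]],
                  c("C", "T"))
  set.seed(3)
  for (i in 1:25) {
    p <- compileIupac(random_iupac(sample(1:12, 1)))
    expect_identical(
      motifText(reverseComplementPattern(reverseComplementPattern(p))),
      motifText(p))
  }
})

test_that("scanning reports all matches with coordinates and labels", {
  u <- unit_from_seq("AAATCCGAA")
  h <- scanUnit(u, compileIupac("ATCCG"))
  expect_equal(nrow(h), 1L)
  expect_equal(h$unit_offset, 2L)
  expect_equal(h$sequence, "ATCCG")
  expect_equal(h$start, 3L)
  expect_equal(h$end, 7L)

  # overlapping matches are all reported
  h2 <- scanUnit(unit_from_seq("AAAA"), compileIupac("AA"))
  expect_equal(h2$unit_offset, 0:2)

  # palindromic site in mode both: one hit per strand
  h3 <- scanUnit(unit_from_seq("TTGAATTCTT"),
                 compileIupac("GAATTC", strandMode = "both"))
  expect_equal(nrow(h3), 2L)
  expect_setequal(h3$strand, c("forward", "reverse"))
  expect_equal(unique(h3$unit_offset), 2L)

  # genome N never matches, pattern N included
  expect_equal(nrow(scanUnit(unit_from_seq("AANAA"), compileIupac("ANA"))),
               0L)
  expect_equal(nrow(scanUnit(unit_from_seq("AANAA"), compileIupac("NNN"))),
               0L)

  # motif longer than the unit: empty result, not an error
  expect_equal(nrow(scanUnit(unit_from_seq("ACG"), compileIupac("ACGTACGT"))),
               0L)
})

test_that("boundary-spanning motifs carry both region labels", {
  u <- unit_from_segments("AAAATCCGAA", c("utr5", "exon_cds"), c(5L, 5L))
  h <- scanUnit(u, compileIupac("ATCCG"))
  expect_equal(nrow(h), 1L)
  expect_equal(h$region, "utr5|exon_cds")
})

test_that("optimized scan equals the naive reference on random cases", {
  set.seed(101)
  for (i in 1:120) {
    u <- unit_from_seq(random_seq(sample(0:300, 1), n_prob = 0.05))
    mode <- sample(c("forward", "reverse", "both"), 1)
    p <- compileIupac(random_iupac(sample(1:12, 1)), strandMode = mode)
    fast <- scanUnit(u, p)
    slow <- scanUnitNaive(u, p)
    expect_identical(fast, slow)
  }
})

test_that("reverse-strand hits are forward hits of the complement pattern", {
  set.seed(202)
  for (i in 1:30) {
    u <- unit_from_seq(random_seq(200))
    p <- compileIupac(random_iupac(6), strandMode = "reverse")
    rc <- reverseComplementPattern(compileIupac(motifText(p)))
    expect_identical(scanUnit(u, p)$unit_offset,
                     scanUnit(u, rc)$unit_offset)
  }
})

test_that("PWM probabilities multiply across columns", {
  point <- newPWM(matrix(c(1, 0, 0, 0, 0, 0, 1, 0), nrow = 4))  # "AG"
  expect_equal(pwmMatchProb(point, "AG"), 1.0)
  expect_equal(pwmMatchProb(point, "AC"), 0.0)
  half <- newPWM(matrix(c(.5, .5, 0, 0, 0, 0, .5, .5), nrow = 4))
  expect_equal(pwmMatchProb(half, "AG"), 0.25)
  expect_error(pwmMatchProb(half, "A"), "length")

  # monotone: raising the used entry never lowers the probability
  m <- matrix(c(.4, .3, .2, .1, .25, .25, .25, .25), nrow = 4)
  base <- prod(m[1, 1], m[2, 2])
  m2 <- m; m2[1, 1] <- .6
  expect_gte(prod(m2[1, 1], m2[2, 2]), base)
})

test_that("PWM reduces to an IUPAC pattern by probability floor", {
  pwm <- newPWM(matrix(c(.5, .5, 0, 0, 0, 0, .5, .5), nrow = 4))
  expect_identical(motifText(pwmToPattern(pwm, 0.05)), "MK")
  point <- newPWM(matrix(c(1, 0, 0, 0, 0, 0, 1, 0), nrow = 4))
  expect_identical(motifText(pwmToPattern(point)), pwmConsensus(point))
  unif <- newPWM(matrix(rep(.25, 8), nrow = 4))
  expect_identical(motifText(pwmToPattern(unif, 0.05)), "NN")
  expect_error(pwmToPattern(pwm, 0.9), "lower min_prob")
})

test_that("PWM files load as probabilities or common-total counts", {
  f <- tempfile(fileext = ".pwm")
  writeLines(c("# test matrix", "A 8 0", "C 2 0", "G 0 10", "T 0 0"), f)
  pwm <- readPWM(f)
  expect_equal(pwm@mat[, 1], c(A = .8, C = .2, G = 0, T = 0))
  expect_equal(pwmConsensus(pwm), "AG")
  f2 <- tempfile(fileext = ".pwm")
  writeLines(c("A 0.8 0", "C 0.2 0", "G 0 1", "T 0 0"), f2)
  expect_equal(readPWM(f2)@mat, pwm@mat, tolerance = 1e-9)
})

test_that("pattern expansion enumerates exactly the compatible words", {
  expect_identical(expandPattern(compileIupac("GGW")), c("GGA", "GGT"))
  expect_identical(expandPattern(compileIupac("ACG")), "ACG")
  expect_length(expandPattern(compileIupac("NN")), 16L)
})

test_that("Contain/Devoid filters follow the and/or truth table", {
  toy <- toy_annotation()   # G1 described as "protein kinase"
  gs <- loadGeneModels(toy$gff3, loadGenome(toy$fasta))
  h <- data.frame(gene_id = "G1", unit_offset = 0L)
  expect_equal(nrow(applyFilters(h, gs, contain = "kinase")), 1L)
  expect_equal(nrow(applyFilters(h, gs, devoid = "kinase")), 0L)
  expect_equal(nrow(applyFilters(h, gs, contain = "receptor")), 0L)
  expect_equal(nrow(applyFilters(h, gs, devoid = "receptor")), 1L)
  # "protein kinase" with contain=kinase AND devoid=protein -> removed
  expect_equal(nrow(applyFilters(h, gs, contain = "kinase",
                                 devoid = "protein", mode = "and")), 0L)
  # or: contain passes, so retained despite devoid failing
  expect_equal(nrow(applyFilters(h, gs, contain = "kinase",
                                 devoid = "protein", mode = "or")), 1L)
  expect_error(applyFilters(h, gs), "at least one")
})
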