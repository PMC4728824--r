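test_that("loadGenome reads, uppercases and validates FASTA", {
  fa <- write_fasta(list(chr1 = "ACGT"))
  g <- loadGenome(fa)
  expect_identical(chromosomeLengths(g), c(chr1 = 4L))

  fa2 <- write_fasta(list(chr1 = "acgtn"))
  expect_identical(as.character(chromosomeSeq(loadGenome(fa2), "chr1")),
                   "ACGTN")

  fa3 <- write_fasta(list(chr1 = "ACXGT"))
  expect_error(loadGenome(fa3), "invalid character 'X' at position 3")

  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_error(loadGenome(empty), "empty|read")
})

test_that("gene models partition loci into regions with derived introns", {
  toy <- toy_annotation()
  gs <- loadGeneModels(toy$gff3, loadGenome(toy$fasta))
  g <- getGene(gs, "G1")
  expect_length(g@transcripts, 1L)
  reg <- g@transcripts[[1]]@regions
  expect_setequal(reg$kind, c("utr5", "exon_cds", "intron", "utr3"))
  intron <- reg[reg$kind == "intron", ]
  expect_equal(intron$start, toy$off + 41)
  expect_equal(intron$end, toy$off + 60)
  expect_equal(intron$end - intron$start + 1, 20)
  # region arithmetic: CDS + UTR widths tile the exon span minus introns
  w <- function(k) sum(reg$end[reg$kind == k] - reg$start[reg$kind == k] + 1)
  expect_equal(w("utr5") + w("exon_cds") + w("utr3"), 80)
})

test_that("single-exon gene yields three regions and no intron", {
  fa <- write_fasta(list(c1 = strrep("ACGT", 30)))
  g <- write_gff3(c(
    gffrow("c1", "gene", 11, 60, "+", "ID=g;"),
    gffrow("c1", "mRNA", 11, 60, "+", "ID=t;Parent=g"),
    gffrow("c1", "exon", 11, 60, "+", "ID=e;Parent=t"),
    gffrow("c1", "five_prime_UTR", 11, 20, "+", "ID=u5;Parent=t"),
    gffrow("c1", "CDS", 21, 50, "+", "ID=c;Parent=t"),
    gffrow("c1", "three_prime_UTR", 51, 60, "+", "ID=u3;Parent=t")))
  gs <- loadGeneModels(g, loadGenome(fa))
  reg <- getGene(gs, "g")@transcripts[[1]]@regions
  expect_equal(nrow(reg), 3L)
  expect_false("intron" %in% reg$kind)
})

test_that("multi-isoform genes carry one TranscriptModel per mRNA", {
  fa <- write_fasta(list(c1 = strrep("ACGT", 50)))
  g <- write_gff3(c(
    gffrow("c1", "gene", 1, 150, "+", "ID=g;"),
    gffrow("c1", "mRNA", 1, 150, "+", "ID=t1;Parent=g"),
    gffrow("c1", "exon", 1, 50, "+", "ID=e1;Parent=t1"),
    gffrow("c1", "exon", 101, 150, "+", "ID=e2;Parent=t1"),
    gffrow("c1", "CDS", 1, 50, "+", "ID=c1;Parent=t1"),
    gffrow("c1", "CDS", 101, 150, "+", "ID=c2;Parent=t1"),
    gffrow("c1", "mRNA", 1, 150, "+", "ID=t2;Parent=g"),
    gffrow("c1", "exon", 1, 150, "+", "ID=e3;Parent=t2"),
    gffrow("c1", "CDS", 1, 150, "+", "ID=c3;Parent=t2")))
  gs <- loadGeneModels(g, loadGenome(fa))
  gene <- getGene(gs, "g")
  expect_length(gene@transcripts, 2L)
  # two-exon isoform gets the derived intron [51,100]
  reg1 <- gene@transcripts[[1]]@regions
  expect_equal(reg1[reg1$kind == "intron", c("start", "end")],
               data.frame(start = 51, end = 100),
               ignore_attr = TRUE)
})

test_that("malformed annotations are rejected with informative errors", {
  fa <- write_fasta(list(c1 = strrep("ACGT", 10)))
  orphan <- write_gff3(c(
    gffrow("c1", "gene", 1, 20, "+", "ID=g;"),
    gffrow("c1", "mRNA", 1, 20, "+", "ID=t;Parent=nosuch"),
    gffrow("c1", "exon", 1, 20, "+", "ID=e;Parent=t")))
  expect_error(loadGeneModels(orphan, loadGenome(fa)), "unknown gene Parent")

  beyond <- write_gff3(c(
    gffrow("c1", "gene", 1, 999, "+", "ID=g;"),
    gffrow("c1", "mRNA", 1, 999, "+", "ID=t;Parent=g"),
    gffrow("c1", "exon", 1, 999, "+", "ID=e;Parent=t")))
  expect_error(loadGeneModels(beyond, loadGenome(fa)),
               "beyond chromosome bounds")
})

# three genes with known gaps for intergenic truncation tests:
# gene A CDS 201..300 (+), gene B 601..700 with UTRs 581..600/701..720 (+),
# gene C CDS 1101..1200 (-); chromosome 1500 bp
flanked_annotation <- function() {
  fa <- write_fasta(list(c1 = strrep("ACGT", 375)))
  rows <- c(
    gffrow("c1", "gene", 201, 300, "+", "ID=A;"),
    gffrow("c1", "mRNA", 201, 300, "+", "ID=A.1;Parent=A"),
    gffrow("c1", "exon", 201, 300, "+", "ID=Ae;Parent=A.1"),
    gffrow("c1", "CDS", 201, 300, "+", "ID=Ac;Parent=A.1"),
    gffrow("c1", "gene", 581, 720, "+", "ID=B;"),
    gffrow("c1", "mRNA", 581, 720, "+", "ID=B.1;Parent=B"),
    gffrow("c1", "exon", 581, 720, "+", "ID=Be;Parent=B.1"),
    gffrow("c1", "five_prime_UTR", 581, 600, "+", "ID=Bu5;Parent=B.1"),
    gffrow("c1", "CDS", 601, 700, "+", "ID=Bc;Parent=B.1"),
    gffrow("c1", "three_prime_UTR", 701, 720, "+", "ID=Bu3;Parent=B.1"),
    gffrow("c1", "gene", 1101, 1200, "-", "ID=C;"),
    gffrow("c1", "mRNA", 1101, 1200, "-", "ID=C.1;Parent=C"),
    gffrow("c1", "exon", 1101, 1200, "-", "ID=Ce;Parent=C.1"),
    gffrow("c1", "CDS", 1101, 1200, "-", "ID=Cc;Parent=C.1"))
  loadGeneModels(write_gff3(rows), loadGenome(fa))
}

test_that("intergenic flanks truncate at flanking CDS and clamp at ends", {
  gs <- flanked_annotation()
  seg <- function(u) segmentMap(u)

  # gap upstream of B (tx 581..720) to A's CDS end 300 is 280 bp;
  # requesting 500 truncates to 280
  u <- buildScanUnit(gs, "B", kinds = "intergenic5", intergenic5 = 500L)
  expect_equal(unitLength(u), 280L)
  expect_equal(seg(u)$start, 301L)
  expect_equal(seg(u)$end, 580L)

  # blank length takes the full gap
  u2 <- buildScanUnit(gs, "B", kinds = "intergenic5")
  expect_equal(unitLength(u2), 280L)

  # a shorter request is honored exactly
  u3 <- buildScanUnit(gs, "B", kinds = "intergenic5", intergenic5 = 100L)
  expect_equal(seg(u3)$start, 481L)
  expect_equal(unitLength(u3), 100L)

  # gene A's upstream flank clamps at chromosome position 1
  uA <- buildScanUnit(gs, "A", kinds = "intergenic5", intergenic5 = 5000L)
  expect_equal(seg(uA)$start, 1L)
  expect_equal(unitLength(uA), 200L)

  # minus-strand gene C: its 5' flank is genomic-right, up to chromosome end
  uC <- buildScanUnit(gs, "C", kinds = "intergenic5")
  expect_equal(seg(uC)$start, 1201L)
  expect_equal(seg(uC)$end, 1500L)

  # C's 3' flank is genomic-left, truncated at B's CDS (end 700)
  uC3 <- buildScanUnit(gs, "C", kinds = "intergenic3")
  expect_equal(seg(uC3)$start, 701L)
  expect_equal(seg(uC3)$end, 1100L)

  # truncation invariant: length <= min(requested, gap), over many requests
  for (req in c(0L, 1L, 50L, 280L, 300L, 1000L)) {
    ur <- buildScanUnit(gs, "B", kinds = "intergenic5", intergenic5 = req)
    expect_lte(unitLength(ur), min(req, 280L))
  }
})

test_that("overlapping neighbours give an empty flank, not an error", {
  fa <- write_fasta(list(c1 = strrep("ACGT", 100)))
  rows <- c(
    gffrow("c1", "gene", 1, 120, "+", "ID=X;"),
    gffrow("c1", "mRNA", 1, 120, "+", "ID=X.1;Parent=X"),
    gffrow("c1", "exon", 1, 120, "+", "ID=Xe;Parent=X.1"),
    gffrow("c1", "CDS", 1, 120, "+", "ID=Xc;Parent=X.1"),
    gffrow("c1", "gene", 100, 200, "+", "ID=Y;"),
    gffrow("c1", "mRNA", 100, 200, "+", "ID=Y.1;Parent=Y"),
    gffrow("c1", "exon", 100, 200, "+", "ID=Ye;Parent=Y.1"),
    gffrow("c1", "CDS", 100, 200, "+", "ID=Yc;Parent=Y.1"))
  gs <- loadGeneModels(write_gff3(rows), loadGenome(fa))
  u <- buildScanUnit(gs, "Y", kinds = "intergenic5", intergenic5 = 50L)
  expect_equal(unitLength(u), 0L)
})

test_that("full selection is additive and minus-strand units read 5'->3'", {
  toy <- toy_annotation()
  gs <- loadGeneModels(toy$gff3, loadGenome(toy$fasta))
  u <- buildScanUnit(gs, "G1", kinds = regionKinds())
  # 100 bp gene body + full flanks (100 bp left gap, 200 bp right tail)
  expect_equal(unitLength(u), sum(segmentMap(u)$end -
                                    segmentMap(u)$start + 1L))
  expect_equal(unitLength(u), 400L)

  # minus-strand gene: unit equals segment-wise reverse complement
  fa <- write_fasta(list(c1 = "TTTTTATGCATTTTT"))
  rows <- c(
    gffrow("c1", "gene", 6, 10, "-", "ID=M;"),
    gffrow("c1", "mRNA", 6, 10, "-", "ID=M.1;Parent=M"),
    gffrow("c1", "exon", 6, 10, "-", "ID=Me;Parent=M.1"),
    gffrow("c1", "CDS", 6, 10, "-", "ID=Mc;Parent=M.1"))
  gsm <- loadGeneModels(write_gff3(rows), loadGenome(fa))
  um <- buildScanUnit(gsm, "M", kinds = "exon_cds")
  expect_identical(as.character(um@sequence), "TGCAT")
})

test_that("ATG-relative positions are signed with no zero", {
  toy <- toy_annotation()
  gs <- loadGeneModels(toy$gff3, loadGenome(toy$fasta))
  u <- buildScanUnit(gs, "G1", kinds = c("utr5", "exon_cds", "intron",
                                         "utr3"))
  # unit starts at the 10 bp 5'UTR; ATG is at unit offset 10
  expect_equal(atgRelativePosition(u, 10L), 1L)
  expect_equal(atgRelativePosition(u, 9L), -1L)
  expect_equal(atgRelativePosition(u, 0L), -10L)
  expect_equal(atgRelativePosition(u, 11L), 2L)
  expect_error(atgRelativePosition(u, unitLength(u)), "outside")
  expect_error(atgRelativePosition(u, -1L), "outside")
})

test_that("unit offset <-> genomic mapping round-trips on both strands", {
  set.seed(11)
  for (strand in c("+", "-")) {
    seq <- random_seq(120)
    u <- unit_from_segments(seq, c("utr5", "exon_cds", "intron", "utr3"),
                            c(20L, 40L, 30L, 30L), strand = strand,
                            atg = 21L, gstart = 501L)
    offs <- sample(0:119, 40)
    g <- unitOffsetToGenomic(u, offs)
    # independent inverse computed from the segment map
    s <- segmentMap(u)
    back <- vapply(seq_along(offs), function(i) {
      row <- which(s$start <= g[i] & s$end >= g[i])
      k <- if (strand == "-") s$end[row] - g[i] else g[i] - s$start[row]
      s$unit_start[row] + k
    }, 0L)
    expect_identical(back, offs)
  }
})
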