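# In-code fixtures shared across the test files.

# A ScanUnit wrapping a bare sequence as a single coding segment starting
# at genomic position 1 (ATG at position 1, so unit offsets map to +1, +2,
# ... positions).
unit_from_seq <- function(seq, strand = "+", kind = "exon_cds") {
  n <- nchar(seq)
  methods::new("ScanUnit", gene_id = "g1", transcript_id = "g1.1",
               chrom = "chrZ", strand = strand,
               sequence = Biostrings::DNAString(seq),
               segments = data.frame(kind = kind, start = 1L, end = n,
                                     unit_start = 0L, unit_end = n),
               atg = 1L)
}

# A ScanUnit with an explicit multi-segment map (contiguous genomic
# intervals), for boundary-spanning and coordinate round-trip tests.
unit_from_segments <- function(seq, kinds, widths, strand = "+",
                               atg = 1L, gstart = 1L) {
  stopifnot(sum(widths) == nchar(seq))
  ends <- cumsum(widths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  seg <- data.frame(kind = kinds, start = gstart + starts - 1L,
                    end = gstart + ends - 1L,
                    unit_start = starts - 1L, unit_end = ends)
  if (strand == "-") {   # gene-strand order = descending genomic
    seg <- seg[rev(seq_len(nrow(seg))), ]
    w <- seg$end - seg$start + 1L
    seg$unit_end <- cumsum(w)
    seg$unit_start <- seg$unit_end - w
    rownames(seg) <- NULL
  }
  methods::new("ScanUnit", gene_id = "g1", transcript_id = "g1.1",
               chrom = "chrZ", strand = strand,
               sequence = Biostrings::DNAString(seq), segments = seg,
               atg = as.integer(atg))
}

write_fasta <- function(records, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(records), function(n)
    c(paste0(">", n), records[[n]]))), path)
  path
}

write_gff3 <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

gffrow <- function(chrom, type, start, end, strand, attrs) {
  paste(chrom, "test", type, start, end, ".", strand, ".", attrs,
        sep = "\t")
}

# a plus-strand two-exon gene: 5'UTR 1..10, CDS 11..40 + 61..90 with
# intron 41..60, 3'UTR 91..100, on a 400 bp chromosome starting at 101
toy_annotation <- function() {
  seq <- paste(rep("ACGT", 100), collapse = "")
  fa <- write_fasta(list(chr1 = seq))
  off <- 100L
  g <- c(
    gffrow("chr1", "gene", off + 1, off + 100, "+", "ID=G1;Name=G1p;description=protein kinase"),
    gffrow("chr1", "mRNA", off + 1, off + 100, "+", "ID=G1.1;Parent=G1"),
    gffrow("chr1", "exon", off + 1, off + 40, "+", "ID=G1.1.e1;Parent=G1.1"),
    gffrow("chr1", "exon", off + 61, off + 100, "+", "ID=G1.1.e2;Parent=G1.1"),
    gffrow("chr1", "five_prime_UTR", off + 1, off + 10, "+", "ID=G1.1.u5;Parent=G1.1"),
    gffrow("chr1", "CDS", off + 11, off + 40, "+", "ID=G1.1.c1;Parent=G1.1"),
    gffrow("chr1", "CDS", off + 61, off + 90, "+", "ID=G1.1.c2;Parent=G1.1"),
    gffrow("chr1", "three_prime_UTR", off + 91, off + 100, "+", "ID=G1.1.u3;Parent=G1.1"))
  list(fasta = fa, gff3 = write_gff3(g), off = off)
}

random_iupac <- function(len, alphabet = c("A", "C", "G", "T", "R", "Y",
                                           "S", "W", "K", "M", "B", "D",
                                           "H", "V", "N")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_seq <- function(len, n_prob = 0) {
  if (len == 0L) return("")
  paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
               prob = c(rep((1 - n_prob) / 4, 4), n_prob)), collapse = "")
}
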