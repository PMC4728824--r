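# Scan-unit construction: the selected region classes of one isoform,
# concatenated 5'->3' on the gene strand, with intergenic flanks truncated
# at flanking coding sequence.

#' Build the scan unit of one transcript
#'
#' Assembles the selected region classes of a transcript into a single
#' gene-strand-oriented sequence with a segment map. Intergenic flanks
#' extend outward from the transcript's outermost annotated base (or from
#' the gene's own CDS extent with \code{flankFrom = "cds"}) by the requested
#' length, truncated at the nearest flanking gene's coding sequence or the
#' chromosome end, whichever comes first. A blank (\code{NA}) length takes
#' the full gap between genes. Overlapping neighbours (gap <= 0) yield an
#' empty flank, not an error. Contiguous selected regions are concatenated
#' without separators, so motifs can span region boundaries. Minus-strand
#' genes are reverse-complemented so the unit reads 5' to 3' on the gene
#' strand.
#'
#' @param geneSet A [GeneModelSet-class].
#' @param gene_id Gene to build the unit for.
#' @param transcript_id Transcript id; default the gene's first transcript.
#' @param kinds Subset of [regionKinds()] to include.
#' @param intergenic5,intergenic3 Requested flank lengths in bp
#'   (\code{NA} = full gap between genes).
#' @param flankFrom Anchor from which the flanks are measured:
#'   \code{"transcript"} (outermost annotated transcript base, default) or
#'   \code{"cds"} (the gene's own outermost CDS base).
#' @return A [ScanUnit-class].
#' @seealso [scanUnit()], [atgRelativePosition()]
#' @export
buildScanUnit <- function(geneSet, gene_id, transcript_id = NULL,
                          kinds = regionKinds(),
                          intergenic5 = NA_integer_,
                          intergenic3 = NA_integer_,
                          flankFrom = c("transcript", "cds")) {
  stopifnot(is(geneSet, "GeneModelSet"))
  flankFrom <- match.arg(flankFrom)
  bad <- setdiff(kinds, .REGION_KINDS)
  if (length(bad)) stop("unknown region kind: ", bad[1L])
  if (!is.na(intergenic5) && intergenic5 < 0)
    stop("intergenic5 must be >= 0 or NA")
  if (!is.na(intergenic3) && intergenic3 < 0)
    stop("intergenic3 must be >= 0 or NA")
  gene <- getGene(geneSet, gene_id)
  tx_ids <- vapply(gene@transcripts, function(t) t@transcript_id, "")
  if (is.null(transcript_id)) transcript_id <- tx_ids[1L]
  ti <- match(transcript_id, tx_ids)
  if (is.na(ti)) stop("unknown transcript '", transcript_id,
                      "' for gene '", gene_id, "'")
  tx <- gene@transcripts[[ti]]
  reg <- tx@regions
  chrom <- gene@chromosome
  chrom_len <- unname(chromosomeLengths(geneSet@genome)[chrom])
  minus <- gene@strand == "-"

  tx_s <- min(reg$start); tx_e <- max(reg$end)
  ex <- geneSet@extents
  others <- ex[ex$gene_id != gene_id & ex$chrom == chrom, , drop = FALSE]
  anchor_s <- if (flankFrom == "cds")
    ex$cds_start[ex$gene_id == gene_id] else tx_s
  anchor_e <- if (flankFrom == "cds")
    ex$cds_end[ex$gene_id == gene_id] else tx_e

  # genomic bound left of the anchor: 1 past the nearest flanking CDS that
  # starts before the anchor (an overlapping CDS pushes the bound past the
  # anchor => empty flank)
  left_cand <- others$cds_end[others$cds_start < anchor_s] + 1L
  bound_left <- max(c(1L, left_cand))
  right_cand <- others$cds_start[others$cds_end > anchor_e] - 1L
  bound_right <- min(c(chrom_len, right_cand))

  len5 <- if (minus) intergenic3 else intergenic5  # genomic-left flank length
  len3 <- if (minus) intergenic5 else intergenic3
  left_start <- if (is.na(len5)) bound_left else
    max(bound_left, anchor_s - as.integer(len5))
  left <- c(left_start, anchor_s - 1L)            # may be empty
  right_end <- if (is.na(len3)) bound_right else
    min(bound_right, anchor_e + as.integer(len3))
  right <- c(anchor_e + 1L, right_end)

  flank_rows <- list()
  if (left[1L] <= left[2L])
    flank_rows[[length(flank_rows) + 1L]] <- data.frame(
      kind = if (minus) "intergenic3" else "intergenic5",
      start = left[1L], end = left[2L])
  if (right[1L] <= right[2L])
    flank_rows[[length(flank_rows) + 1L]] <- data.frame(
      kind = if (minus) "intergenic5" else "intergenic3",
      start = right[1L], end = right[2L])
  all_reg <- rbind(do.call(rbind, c(list(reg), flank_rows)))
  all_reg <- all_reg[order(all_reg$start), , drop = FALSE]
  sel <- all_reg[all_reg$kind %in% kinds, , drop = FALSE]
  if (minus) sel <- sel[rev(seq_len(nrow(sel))), , drop = FALSE]

  cds <- reg[reg$kind == "exon_cds", , drop = FALSE]
  atg <- if (nrow(cds)) {
    if (minus) max(cds$end) else min(cds$start)
  } else {
    if (minus) tx_e else tx_s
  }

  chrom_seq <- chromosomeSeq(geneSet@genome, chrom)
  if (nrow(sel)) {
    pieces <- Biostrings::DNAStringSet(Map(function(s, e)
      Biostrings::subseq(chrom_seq, s, e), sel$start, sel$end))
    if (minus) pieces <- Biostrings::reverseComplement(pieces)
    unit_seq <- Biostrings::DNAString(paste(as.character(pieces),
                                            collapse = ""))
    w <- sel$end - sel$start + 1L
    sel$unit_end <- cumsum(w)
    sel$unit_start <- sel$unit_end - w
    rownames(sel) <- NULL
  } else {
    unit_seq <- Biostrings::DNAString("")
    sel <- data.frame(kind = character(0), start = integer(0),
                      end = integer(0), unit_start = integer(0),
                      unit_end = integer(0))
  }
  new("ScanUnit", gene_id = gene_id, transcript_id = transcript_id,
      chrom = chrom, strand = gene@strand, sequence = unit_seq,
      segments = sel, atg = as.integer(atg))
}

#' Total length of a scan unit
#'
#' @param unit A [ScanUnit-class].
#' @return Integer length in bp (the R_L of the scoring formulas).
#' @export
unitLength <- function(unit) {
  stopifnot(is(unit, "ScanUnit"))
  length(unit@sequence)
}

#' @describeIn unitLength The unit's segment map (region kind, genomic
#'   interval, 0-based half-open unit offsets).
#' @export
segmentMap <- function(unit) {
  stopifnot(is(unit, "ScanUnit"))
  unit@segments
}

#' Map unit offsets to genomic coordinates
#'
#' @param unit A [ScanUnit-class].
#' @param unit_offset 0-based offset(s) into the unit sequence.
#' @return Integer genomic coordinate(s), 1-based.
#' @export
unitOffsetToGenomic <- function(unit, unit_offset) {
  stopifnot(is(unit, "ScanUnit"))
  off <- as.integer(unit_offset)
  if (any(off < 0L | off >= unitLength(unit)))
    stop("unit offset outside [0, R_L)")
  s <- unit@segments
  seg <- findInterval(off, s$unit_start)
  k <- off - s$unit_start[seg]
  if (unit@strand == "-") s$end[seg] - k else s$start[seg] + k
}

#' ATG-relative signed position of a unit offset
#'
#' Positions are counted on the gene strand with the A of the start codon
#' as +1 and the base immediately 5' of it as -1; there is no position 0.
#' The frame is the unspliced gene-strand coordinate axis, so 5'-flank
#' positions are negative, matching the convention of reporting promoter
#' motifs at negative positions relative to the ATG.
#'
#' @param unit A [ScanUnit-class].
#' @param unit_offset 0-based offset(s) into the unit sequence.
#' @return Signed integer position(s); never 0.
#' @examples
#' # the base immediately upstream of the ATG is -1, the A itself is +1
#' @export
atgRelativePosition <- function(unit, unit_offset) {
  g <- unitOffsetToGenomic(unit, unit_offset)
  d <- if (unit@strand == "-") unit@atg - g else g - unit@atg
  ifelse(d >= 0L, d + 1L, d)
}

# region kinds overlapped by unit window [off, off + width)
.regionLabels <- function(unit, off, width) {
  s <- unit@segments
  hit <- s$unit_start < off + width & s$unit_end > off
  paste(s$kind[hit], collapse = "|")
}
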