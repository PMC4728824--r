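#' Load a genome FASTA
#'
#' Reads a (multi-record, wrapped or unwrapped) FASTA file, uppercases
#' soft-masked sequence and validates the alphabet against A/C/G/T/N.
#'
#' @param fasta_path Path to a FASTA file.
#' @return A [GenomeIndex-class].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGTN"), fa)
#' chromosomeLengths(loadGenome(fa))
#' @export
loadGenome <- function(fasta_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  raw <- tryCatch(Biostrings::readBStringSet(fasta_path),
                  error = function(e)
                    stop("malformed FASTA '", fasta_path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (length(raw) == 0L) stop("empty FASTA: ", fasta_path)
  txt <- toupper(as.character(raw))
  bad <- regexpr("[^ACGTN]", txt)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("record '%s' contains invalid character '%s' at position %d",
                 names(raw)[i], substr(txt[i], bad[i], bad[i]), bad[i]))
  }
  # first whitespace-delimited token of the header is the chromosome id
  ids <- sub("\\s.*$", "", names(raw))
  new("GenomeIndex", sequences = stats::setNames(DNAStringSet(txt), ids))
}

#' Chromosome lengths of a genome
#'
#' @param genome A [GenomeIndex-class].
#' @return Named integer vector of sequence lengths (bp).
#' @export
chromosomeLengths <- function(genome) {
  stopifnot(is(genome, "GenomeIndex"))
  stats::setNames(BiocGenerics::width(genome@sequences),
                  names(genome@sequences))
}

#' Chromosome sequence accessor
#'
#' @param genome A [GenomeIndex-class].
#' @param chrom Chromosome name.
#' @return A \code{DNAString}.
#' @export
chromosomeSeq <- function(genome, chrom) {
  stopifnot(is(genome, "GenomeIndex"))
  if (!chrom %in% names(genome@sequences))
    stop("unknown chromosome: ", chrom)
  genome@sequences[[chrom]]
}

.firstParent <- function(parent_list) {
  vapply(parent_list, function(x)
    if (length(x)) as.character(x[1L]) else NA_character_, "")
}

.mcolOrNA <- function(mc, field, n) {
  if (field %in% names(mc)) {
    v <- mc[[field]]
    if (is(v, "List") || is.list(v))
      v <- vapply(v, function(x)
        if (length(x)) paste(as.character(x), collapse = ";")
        else NA_character_, "")
    as.character(v)
  } else rep(NA_character_, n)
}

#' Load gene models from GFF3
#'
#' Parses \code{gene}, \code{mRNA}/\code{transcript}, \code{exon},
#' \code{CDS}, \code{five_prime_UTR} and \code{three_prime_UTR} features
#' into [GeneModel-class] objects. Introns are always derived as the gaps
#' between consecutive exons of a transcript (never read from intron
#' features, for determinism across GFF3 dialects). Transcripts without
#' annotated UTRs simply get no UTR regions; their coding exons abut the
#' intergenic flanks. \code{Name}, \code{description}, \code{annotation}
#' and \code{ec_number} attributes, when present, are carried through.
#'
#' @param gff3_path Path to a GFF3 file (attributes \code{ID}/\code{Parent}
#'   required).
#' @param genome The matching [GenomeIndex-class]; features beyond a
#'   chromosome's length are an error.
#' @return A [GeneModelSet-class].
#' @export
loadGeneModels <- function(gff3_path, genome) {
  stopifnot(is(genome, "GenomeIndex"))
  if (!file.exists(gff3_path)) stop("GFF3 file not found: ", gff3_path)
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  n <- length(gr)
  if (n == 0L) stop("GFF3 contains no features: ", gff3_path)
  type <- as.character(mc$type)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  starts <- BiocGenerics::start(gr)
  ends <- BiocGenerics::end(gr)
  strands <- as.character(BiocGenerics::strand(gr))
  ids <- .mcolOrNA(mc, "ID", n)
  parents <- .firstParent(if ("Parent" %in% names(mc)) mc$Parent
                          else vector("list", n))

  lens <- chromosomeLengths(genome)
  unknown_chr <- !chrom %in% names(lens)
  if (any(unknown_chr))
    stop("feature on unknown chromosome: ", chrom[which(unknown_chr)[1L]])
  over <- ends > lens[chrom] | starts < 1L
  if (any(over)) {
    i <- which(over)[1L]
    stop(sprintf("feature %s:%d-%d (%s) extends beyond chromosome bounds",
                 chrom[i], starts[i], ends[i], type[i]))
  }

  gene_rows <- which(type == "gene")
  tx_rows <- which(type %in% c("mRNA", "transcript"))
  if (length(gene_rows) == 0L) stop("no gene features in ", gff3_path)
  gene_ids <- ids[gene_rows]
  if (anyNA(gene_ids)) stop("gene feature without ID attribute")
  tx_parent <- parents[tx_rows]
  orphan <- !tx_parent %in% gene_ids
  if (any(orphan))
    stop("mRNA '", ids[tx_rows][which(orphan)[1L]],
         "' references unknown gene Parent '", tx_parent[which(orphan)[1L]], "'")

  part_rows <- which(type %in% c("exon", "CDS", "five_prime_UTR",
                                 "three_prime_UTR"))
  part_parent <- parents[part_rows]

  genes <- vector("list", length(gene_rows))
  names(genes) <- gene_ids
  ext <- vector("list", length(gene_rows))

  for (gi in seq_along(gene_rows)) {
    g <- gene_rows[gi]
    gid <- gene_ids[gi]
    g_strand <- strands[g]
    if (!g_strand %in% c("+", "-"))
      stop("gene '", gid, "' has no strand")
    tx_of_gene <- tx_rows[tx_parent == gid]
    if (length(tx_of_gene) == 0L)
      stop("gene '", gid, "' has no mRNA/transcript children")
    txs <- vector("list", length(tx_of_gene))
    for (ti in seq_along(tx_of_gene)) {
      t <- tx_of_gene[ti]
      tid <- ids[t]
      if (is.na(tid)) stop("transcript of gene '", gid, "' lacks ID")
      rows <- part_rows[part_parent == tid]
      ftype <- type[rows]
      fs <- starts[rows]; fe <- ends[rows]
      ex <- which(ftype == "exon")
      if (length(ex) == 0L)
        stop("transcript '", tid, "' has no exon features")
      o <- order(fs[ex])
      ex_s <- fs[ex][o]; ex_e <- fe[ex][o]
      if (any(ex_s[-1L] <= ex_e[-length(ex_e)]))
        stop("overlapping exons in transcript '", tid, "'")
      reg <- list()
      add <- function(kind, s, e) {
        if (length(s))
          reg[[length(reg) + 1L]] <<- data.frame(kind = kind, start = s,
                                                 end = e)
      }
      cds <- which(ftype == "CDS")
      u5 <- which(ftype == "five_prime_UTR")
      u3 <- which(ftype == "three_prime_UTR")
      if (length(cds)) {
        add("exon_cds", fs[cds], fe[cds])
      } else {
        # no annotated CDS: whole exons are treated as coding sequence
        add("exon_cds", ex_s, ex_e)
      }
      add("utr5", fs[u5], fe[u5])
      add("utr3", fs[u3], fe[u3])
      if (length(ex_s) > 1L)
        add("intron", ex_e[-length(ex_e)] + 1L, ex_s[-1L] - 1L)
      regions <- do.call(rbind, reg)
      regions <- regions[order(regions$start), , drop = FALSE]
      rownames(regions) <- NULL
      txs[[ti]] <- new("TranscriptModel", transcript_id = tid,
                       regions = regions)
    }
    genes[[gi]] <- new("GeneModel", gene_id = gid, chromosome = chrom[g],
                       strand = g_strand,
                       name = .mcolOrNA(mc, "Name", n)[g],
                       description = .mcolOrNA(mc, "description", n)[g],
                       annotation = .mcolOrNA(mc, "annotation", n)[g],
                       ec_numbers = {
                         e <- .mcolOrNA(mc, "ec_number", n)[g]
                         if (is.na(e)) character(0)
                         else strsplit(e, ";", fixed = TRUE)[[1L]]
                       },
                       transcripts = txs)
    all_reg <- do.call(rbind, lapply(txs, function(x) x@regions))
    cds_reg <- all_reg[all_reg$kind == "exon_cds", , drop = FALSE]
    ext[[gi]] <- data.frame(
      gene_id = gid, chrom = chrom[g], strand = g_strand,
      tx_start = min(all_reg$start), tx_end = max(all_reg$end),
      cds_start = if (nrow(cds_reg)) min(cds_reg$start) else min(all_reg$start),
      cds_end = if (nrow(cds_reg)) max(cds_reg$end) else max(all_reg$end),
      stringsAsFactors = FALSE)
  }
  new("GeneModelSet", genome = genome, genes = genes,
      extents = do.call(rbind, ext))
}

#' @describeIn loadGeneModels Gene ids held by a [GeneModelSet-class].
#' @param geneSet A [GeneModelSet-class].
#' @export
geneIds <- function(geneSet) {
  stopifnot(is(geneSet, "GeneModelSet"))
  names(geneSet@genes)
}

#' @describeIn loadGeneModels Retrieve one [GeneModel-class] by id.
#' @param gene_id Gene identifier.
#' @export
getGene <- function(geneSet, gene_id) {
  stopifnot(is(geneSet, "GeneModelSet"))
  g <- geneSet@genes[[gene_id]]
  if (is.null(g)) stop("unknown gene: ", gene_id)
  g
}
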