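#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet
#' @importClassesFrom Biostrings DNAString DNAStringSet
NULL

.REGION_KINDS <- c("intergenic5", "utr5", "exon_cds", "intron", "utr3",
                   "intergenic3")

#' The six selectable gene-region classes
#'
#' Every locus is partitioned, per transcript, into 5' intergenic flank,
#' 5' UTR, coding exon, intron, 3' UTR and 3' intergenic flank. Scan units
#' are built from any subset of these classes.
#'
#' @return Character vector of the six region kinds, 5' to 3' on the gene
#'   strand.
#' @examples
#' regionKinds()
#' @export
regionKinds <- function() .REGION_KINDS

#' GenomeIndex: an in-memory genome
#'
#' Holds chromosome sequences as an uppercase \code{DNAStringSet} restricted
#' to the \code{A/C/G/T/N} alphabet. Construct with [loadGenome()].
#'
#' @slot sequences \code{DNAStringSet}, one entry per chromosome.
#' @seealso [loadGenome()], [chromosomeLengths()]
#' @export
setClass("GenomeIndex", representation(sequences = "DNAStringSet"))

setValidity("GenomeIndex", function(object) {
  if (length(object@sequences) == 0L)
    return("genome contains no sequences")
  if (is.null(names(object@sequences)) || anyDuplicated(names(object@sequences)))
    return("chromosome names must be present and unique")
  af <- Biostrings::alphabetFrequency(object@sequences)
  bad <- rowSums(af) - rowSums(af[, c("A", "C", "G", "T", "N"), drop = FALSE])
  if (any(bad > 0))
    return(sprintf("sequence '%s' contains letters outside A/C/G/T/N",
                   names(object@sequences)[which(bad > 0)[1L]]))
  TRUE
})

#' TranscriptModel: one isoform's region partition
#'
#' @slot transcript_id Transcript identifier.
#' @slot regions \code{data.frame} with columns \code{kind}, \code{start},
#'   \code{end} (1-based closed genomic coordinates), ascending, one row per
#'   annotated or derived (intron) segment. Intergenic flanks are not stored
#'   here; they are computed per scan request by [buildScanUnit()].
#' @export
setClass("TranscriptModel",
         representation(transcript_id = "character", regions = "data.frame"))

setValidity("TranscriptModel", function(object) {
  r <- object@regions
  if (nrow(r) == 0L) return("transcript has no regions")
  if (!all(c("kind", "start", "end") %in% names(r)))
    return("regions must have kind/start/end columns")
  if (!all(r$kind %in% .REGION_KINDS))
    return("unknown region kind")
  if (any(r$start > r$end)) return("region start > end")
  if (is.unsorted(r$start)) return("regions must be sorted by start")
  TRUE
})

#' GeneModel: a locus with one or more isoforms
#'
#' @slot gene_id Locus identifier (AGI-style or otherwise).
#' @slot chromosome Chromosome name.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot name,description,annotation Free-text annotation fields carried
#'   through to results tables and used by the Contain/Devoid filters.
#' @slot ec_numbers Character vector of EC numbers (possibly empty).
#' @slot transcripts List of [TranscriptModel-class] objects.
#' @export
setClass("GeneModel",
         representation(gene_id = "character", chromosome = "character",
                        strand = "character", name = "character",
                        description = "character", annotation = "character",
                        ec_numbers = "character", transcripts = "list"))

setValidity("GeneModel", function(object) {
  if (!object@strand %in% c("+", "-")) return("strand must be + or -")
  if (length(object@transcripts) < 1L) return("gene needs >= 1 transcript")
  if (!all(vapply(object@transcripts, is, TRUE, "TranscriptModel")))
    return("transcripts must be TranscriptModel objects")
  TRUE
})

#' GeneModelSet: all gene models over a genome
#'
#' The central annotation container: a [GenomeIndex-class] plus one
#' [GeneModel-class] per locus, with a precomputed per-gene CDS/transcript
#' extent index used for intergenic truncation at flanking coding sequence.
#'
#' @slot genome [GenomeIndex-class].
#' @slot genes Named list of [GeneModel-class] objects.
#' @slot extents \code{data.frame} with one row per gene: \code{gene_id},
#'   \code{chrom}, \code{strand}, \code{tx_start}, \code{tx_end},
#'   \code{cds_start}, \code{cds_end}.
#' @seealso [loadGeneModels()], [buildScanUnit()]
#' @export
setClass("GeneModelSet",
         representation(genome = "GenomeIndex", genes = "list",
                        extents = "data.frame"))

#' ScanUnit: the concatenated selected regions of one transcript
#'
#' The sequence actually scanned for a locus: the selected region classes of
#' one isoform, concatenated without separators in 5' to 3' order on the
#' gene strand (reverse-complemented for minus-strand genes), together with
#' the segment map that converts unit offsets back to genomic coordinates
#' and region labels.
#'
#' @slot gene_id,transcript_id,chrom,strand Identity of the unit.
#' @slot sequence \code{DNAString}, gene-strand oriented.
#' @slot segments \code{data.frame}: \code{kind}, \code{start}, \code{end}
#'   (genomic, 1-based closed), \code{unit_start}, \code{unit_end} (0-based
#'   half-open offsets into \code{sequence}), rows in gene-strand order.
#' @slot atg Genomic coordinate of the A of the start codon (first CDS base
#'   on the gene strand; the transcript's outermost 5' base when the
#'   transcript has no annotated CDS).
#' @seealso [buildScanUnit()], [atgRelativePosition()], [scanUnit()]
#' @export
setClass("ScanUnit",
         representation(gene_id = "character", transcript_id = "character",
                        chrom = "character", strand = "character",
                        sequence = "DNAString", segments = "data.frame",
                        atg = "integer"))

setValidity("ScanUnit", function(object) {
  s <- object@segments
  if (nrow(s) > 0L) {
    widths <- s$end - s$start + 1L
    if (!all(widths == s$unit_end - s$unit_start))
      return("segment genomic width != unit width")
    if (s$unit_start[1L] != 0L ||
        !all(s$unit_start[-1L] == s$unit_end[-nrow(s)]))
      return("segment map must tile [0, R_L) exactly")
    if (sum(widths) != length(object@sequence))
      return("segment map does not cover the unit sequence")
  } else if (length(object@sequence) != 0L) {
    return("non-empty sequence with empty segment map")
  }
  TRUE
})

#' MotifPattern: a compiled IUPAC-degenerate motif
#'
#' @slot text Uppercase IUPAC string.
#' @slot allowed List of character vectors: the concrete bases admitted at
#'   each position (subsets of A/C/G/T; genome \code{N} never matches).
#' @slot strand_mode \code{"forward"}, \code{"reverse"} or \code{"both"},
#'   relative to the gene strand of the scanned unit.
#' @seealso [compileIupac()], [scanUnit()]
#' @export
setClass("MotifPattern",
         representation(text = "character", allowed = "list",
                        strand_mode = "character"))

setValidity("MotifPattern", function(object) {
  if (nchar(object@text) != length(object@allowed))
    return("allowed sets must have one entry per pattern position")
  if (!object@strand_mode %in% c("forward", "reverse", "both"))
    return("strand_mode must be forward/reverse/both")
  ok <- vapply(object@allowed, function(s)
    length(s) > 0L && all(s %in% c("A", "C", "G", "T")), TRUE)
  if (!all(ok)) return("each allowed set must be a nonempty subset of ACGT")
  TRUE
})

#' MotifPWM: a position weight matrix
#'
#' A 4 x L matrix of per-position base probabilities (rows A/C/G/T, columns
#' positions; each column sums to 1).
#'
#' @slot mat Numeric matrix with rownames \code{A,C,G,T}.
#' @seealso [readPWM()], [pwmMatchProb()], [pwmToPattern()]
#' @export
setClass("MotifPWM", representation(mat = "matrix"))

setValidity("MotifPWM", function(object) {
  m <- object@mat
  if (!identical(rownames(m), c("A", "C", "G", "T")))
    return("PWM rows must be named A, C, G, T in that order")
  if (ncol(m) < 1L) return("PWM needs >= 1 column")
  if (any(m < 0)) return("PWM entries must be >= 0")
  if (any(abs(colSums(m) - 1) > 1e-9))
    return("each PWM column must sum to 1 (within 1e-9)")
  TRUE
})

#' BackgroundModel: genome nucleotide frequencies
#'
#' @slot freqs Named numeric vector over A/C/G/T summing to 1. The default,
#'   [defaultBackground()], is the Arabidopsis model A=T=0.32, C=G=0.18.
#' @export
setClass("BackgroundModel", representation(freqs = "numeric"))

setValidity("BackgroundModel", function(object) {
  f <- object@freqs
  if (!identical(names(f), c("A", "C", "G", "T")))
    return("freqs must be named A, C, G, T in that order")
  if (any(f < 0)) return("frequencies must be >= 0")
  if (abs(sum(f) - 1) > 1e-9) return("frequencies must sum to 1 (within 1e-9)")
  TRUE
})

#' InteractionStore: undirected gene-gene interaction edges
#'
#' @slot edges \code{data.frame}: \code{gene_a}, \code{gene_b} (canonical
#'   order, \code{gene_a <= gene_b}), \code{evidence} (\code{"biochemical"}
#'   or \code{"computational"}), \code{method} (free text, \code{";"}-merged
#'   across duplicate listings).
#' @seealso [loadInteractions()], [interactionNeighborhood()]
#' @export
setClass("InteractionStore", representation(edges = "data.frame"))

#' Neighborhood: a BFS interactor neighborhood of one gene
#'
#' @slot root Root gene id.
#' @slot depth Expansion depth requested.
#' @slot edges \code{data.frame} as in [InteractionStore-class] plus a
#'   \code{depth} column (the BFS layer at which the edge was first reached).
#' @slot nodes Character vector of member gene ids (root first, then by
#'   discovery layer, lexicographic within a layer).
#' @export
setClass("Neighborhood",
         representation(root = "character", depth = "integer",
                        edges = "data.frame", nodes = "character"))

#' FixtureSpec: parameters of the synthetic-data generator
#'
#' Defines the deterministic study conditions simulated by
#' [generateFixture()] and [simulateEnrichment()]: a background-sampled
#' genome with parametric gene structures, planted motif sites, and
#' differential-expression labels with optional word-specific enrichment.
#'
#' @slot seed Integer; fully determines all outputs.
#' @slot n_chromosomes,n_genes Genome shape.
#' @slot background [BackgroundModel-class] used for background sampling.
#' @slot motif IUPAC string of the planted motif.
#' @slot n_planted_sites Total sites planted.
#' @slot region_probs Named probabilities over the six region kinds;
#'   realized site counts use largest-remainder quotas so every kind with
#'   positive probability is represented.
#' @slot de_fraction Fraction of genes labelled differentially expressed.
#' @slot enrichment_odds Odds ratio of planting a SPECIFIC-word site in a DE
#'   vs non-DE gene; sites of other words are placed with odds 1. At 1 the
#'   whole design is null.
#' @slot specific_word The enriched concrete word; \code{""} selects the
#'   lexicographically first word of the motif.
#' @slot fc_de_mean,fc_de_sd Absolute log2 fold-change distribution of DE
#'   genes (sign random).
#' @slot fc_null_sd Log2 fold-change sd of non-DE genes (truncated below the
#'   threshold).
#' @slot fct Fold-change threshold separating DE from non-DE labels (log2).
#' @slot intergenic_len Width (bp) of the intergenic windows in which sites
#'   are planted; matches the scan window the truth table assumes.
#' @slot n_interactions Edges in the generated interaction file.
#' @seealso [fixtureSpec()], [generateFixture()]
#' @export
setClass("FixtureSpec",
         representation(seed = "integer", n_chromosomes = "integer",
                        n_genes = "integer", background = "BackgroundModel",
                        motif = "character", n_planted_sites = "integer",
                        region_probs = "numeric", de_fraction = "numeric",
                        enrichment_odds = "numeric", specific_word = "character",
                        fc_de_mean = "numeric", fc_de_sd = "numeric",
                        fc_null_sd = "numeric", fct = "numeric",
                        intergenic_len = "integer", n_interactions = "integer"))

setValidity("FixtureSpec", function(object) {
  if (abs(sum(object@region_probs) - 1) > 1e-9)
    return("region_probs must sum to 1")
  if (!identical(names(object@region_probs), .REGION_KINDS))
    return("region_probs must be named with the six region kinds in order")
  if (object@de_fraction < 0 || object@de_fraction > 1)
    return("de_fraction must be in [0,1]")
  if (object@enrichment_odds <= 0) return("enrichment_odds must be > 0")
  if (object@fct <= 0) return("fct must be > 0")
  TRUE
})
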