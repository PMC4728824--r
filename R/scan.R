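# Motif scanning over scan units: optimized path (Biostrings) and the
# plain window-by-window reference loop used as its oracle in the tests.

.emptyHits <- function() {
  data.frame(gene_id = character(0), transcript_id = character(0),
             chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), unit_offset = integer(0),
             atg_position = integer(0), sequence = character(0),
             region = character(0), width = integer(0),
             stringsAsFactors = FALSE)
}

# offsets (0-based) where patternText matches subject; windows containing N
# in the subject are rejected (Biostrings' subset rule would let pattern N
# match subject N otherwise)
.matchOffsets <- function(subject, patternText) {
  ml <- nchar(patternText)
  if (length(subject) < ml) return(integer(0))
  m <- Biostrings::matchPattern(Biostrings::DNAString(patternText), subject,
                                fixed = c(pattern = FALSE, subject = TRUE))
  st <- BiocGenerics::start(m)
  if (length(st)) {
    has_n <- grepl("N", as.character(m), fixed = TRUE)
    st <- st[!has_n]
  }
  st - 1L
}

.hitsFromOffsets <- function(unit, offsets, ml, strand_label) {
  if (length(offsets) == 0L) return(.emptyHits())
  offsets <- sort(offsets)
  g1 <- unitOffsetToGenomic(unit, offsets)
  g2 <- unitOffsetToGenomic(unit, offsets + ml - 1L)
  words <- vapply(offsets, function(o)
    as.character(Biostrings::subseq(unit@sequence, o + 1L, o + ml)), "")
  data.frame(gene_id = unit@gene_id, transcript_id = unit@transcript_id,
             chrom = unit@chrom, start = pmin(g1, g2), end = pmax(g1, g2),
             strand = strand_label, unit_offset = offsets,
             atg_position = atgRelativePosition(unit, offsets),
             sequence = words,
             region = vapply(offsets, function(o)
               .regionLabels(unit, o, ml), ""),
             width = ml, stringsAsFactors = FALSE)
}

#' Scan a unit for a motif
#'
#' Reports every unit offset whose window satisfies the pattern's allowed
#' sets. \code{strand_mode = "reverse"} scans with the reverse-complement
#' pattern and labels hits \code{reverse}; \code{"both"} scans both and
#' reports each match separately, so a palindromic site yields two hits,
#' one per strand. Overlapping matches are all reported; windows containing
#' \code{N} in the genome never match. The reported \code{sequence} is the
#' window as it reads on the gene strand; \code{atg_position} is the signed
#' position of the window's 5'-most base.
#'
#' @param unit A [ScanUnit-class].
#' @param pattern A [MotifPattern-class].
#' @return A hits \code{data.frame} (possibly empty): \code{gene_id},
#'   \code{transcript_id}, \code{chrom}, \code{start}, \code{end} (genomic,
#'   1-based closed), \code{strand} (\code{forward}/\code{reverse} relative
#'   to the gene strand), \code{unit_offset}, \code{atg_position},
#'   \code{sequence}, \code{region} (one or two \code{|}-joined kinds when
#'   spanning a boundary), \code{width}.
#' @examples
#' # see the package vignette for an end-to-end example
#' @export
scanUnit <- function(unit, pattern) {
  stopifnot(is(unit, "ScanUnit"), is(pattern, "MotifPattern"))
  ml <- nchar(pattern@text)
  res <- list()
  if (pattern@strand_mode %in% c("forward", "both"))
    res[[length(res) + 1L]] <-
      .hitsFromOffsets(unit, .matchOffsets(unit@sequence, pattern@text), ml,
                       "forward")
  if (pattern@strand_mode %in% c("reverse", "both"))
    res[[length(res) + 1L]] <-
      .hitsFromOffsets(unit,
                       .matchOffsets(unit@sequence, .revcompText(pattern@text)),
                       ml, "reverse")
  out <- do.call(rbind, res)
  if (is.null(out)) out <- .emptyHits()
  out <- out[order(out$unit_offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @describeIn scanUnit Reference implementation: the plainest possible
#'   window-by-window set-membership loop, kept independent of the
#'   optimized path and used as its oracle in the test suite.
#' @export
scanUnitNaive <- function(unit, pattern) {
  stopifnot(is(unit, "ScanUnit"), is(pattern, "MotifPattern"))
  ml <- nchar(pattern@text)
  chars <- strsplit(as.character(unit@sequence), "", fixed = TRUE)[[1L]]
  loop <- function(allowed) {
    n <- length(chars)
    if (n < ml) return(integer(0))
    found <- integer(0)
    for (s in seq_len(n - ml + 1L)) {
      ok <- TRUE
      for (j in seq_len(ml)) {
        if (!chars[s + j - 1L] %in% allowed[[j]]) { ok <- FALSE; break }
      }
      if (ok) found <- c(found, s - 1L)
    }
    found
  }
  res <- list()
  if (pattern@strand_mode %in% c("forward", "both"))
    res[[length(res) + 1L]] <-
      .hitsFromOffsets(unit, loop(pattern@allowed), ml, "forward")
  if (pattern@strand_mode %in% c("reverse", "both"))
    res[[length(res) + 1L]] <-
      .hitsFromOffsets(unit, loop(reverseComplementPattern(pattern)@allowed),
                       ml, "reverse")
  out <- do.call(rbind, res)
  if (is.null(out)) out <- .emptyHits()
  out <- out[order(out$unit_offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a bare sequence for a motif
#'
#' Convenience wrapper for scanning sequence that is not tied to a gene
#' model (used by the fixture generator and the null-calibration
#' simulations).
#'
#' @param sequence A \code{DNAString} or single character string.
#' @param pattern A [MotifPattern-class]; its \code{strand_mode} decides
#'   which orientations are scanned.
#' @return \code{data.frame} with \code{offset} (0-based) and \code{strand}.
#' @export
scanSequence <- function(sequence, pattern) {
  stopifnot(is(pattern, "MotifPattern"))
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  res <- list()
  if (pattern@strand_mode %in% c("forward", "both")) {
    o <- .matchOffsets(sequence, pattern@text)
    res[[length(res) + 1L]] <- data.frame(offset = o,
                                          strand = rep("forward", length(o)))
  }
  if (pattern@strand_mode %in% c("reverse", "both")) {
    o <- .matchOffsets(sequence, .revcompText(pattern@text))
    res[[length(res) + 1L]] <- data.frame(offset = o,
                                          strand = rep("reverse", length(o)))
  }
  out <- do.call(rbind, res)
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Contain/Devoid annotation filters
#'
#' A gene passes \emph{Contain} if the substring occurs (case-insensitive)
#' in its name, description or annotation text, and passes \emph{Devoid} if
#' the substring does not. With both criteria set, \code{mode = "and"}
#' requires both conditions and \code{mode = "or"} either. Hits of
#' non-passing genes are removed.
#'
#' @param hits Hits \code{data.frame} from [scanUnit()].
#' @param geneSet The [GeneModelSet-class] supplying annotation text.
#' @param contain,devoid Optional substrings; at least one must be given.
#' @param mode \code{"and"} or \code{"or"} (relevant when both are set).
#' @return The filtered hits \code{data.frame}.
#' @export
applyFilters <- function(hits, geneSet, contain = NULL, devoid = NULL,
                         mode = c("and", "or")) {
  mode <- match.arg(mode)
  stopifnot(is(geneSet, "GeneModelSet"))
  if (is.null(contain) && is.null(devoid))
    stop("at least one of contain/devoid must be set")
  if (nrow(hits) == 0L) return(hits)
  ids <- unique(hits$gene_id)
  txt <- vapply(ids, function(id) {
    g <- getGene(geneSet, id)
    tolower(paste(stats::na.omit(c(g@name, g@description, g@annotation)),
                  collapse = " "))
  }, "")
  pass <- rep(TRUE, length(ids))
  has <- function(needle) grepl(tolower(needle), txt, fixed = TRUE)
  if (!is.null(contain) && !is.null(devoid)) {
    pass <- if (mode == "and") has(contain) & !has(devoid)
            else has(contain) | !has(devoid)
  } else if (!is.null(contain)) {
    pass <- has(contain)
  } else {
    pass <- !has(devoid)
  }
  keep <- hits$gene_id %in% ids[pass]
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
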