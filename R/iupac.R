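# IUPAC degeneracy machinery shared by the motif engine and fixtures.

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# set (sorted, collapsed) -> code
.SET_TO_CODE <- local({
  keys <- vapply(.IUPAC_SETS, function(s) paste(sort(s), collapse = ""), "")
  stats::setNames(names(.IUPAC_SETS), keys)
})

# complement of every IUPAC code (R<->Y, K<->M, S/W self, B<->V, D<->H, N self)
.IUPAC_FROM <- "ACGTRYKMSWBVDHN"
.IUPAC_TO   <- "TGCAYRMKSWVBHDN"

.revcompText <- function(x) {
  comp <- chartr(.IUPAC_FROM, .IUPAC_TO, toupper(x))
  vapply(comp, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""),
    "", USE.NAMES = FALSE)
}

#' Compile an IUPAC-degenerate motif
#'
#' Turns a motif string over the 15-letter IUPAC nucleotide alphabet into a
#' [MotifPattern-class] with explicit per-position allowed-base sets
#' (R=A/G, Y=C/T, S=C/G, W=A/T, K=G/T, M=A/C, B=C/G/T, D=A/G/T, H=A/C/T,
#' V=A/C/G, N=A/C/G/T). Matching is case-insensitive; genome \code{N} bases
#' never satisfy any code, \code{N} in the pattern included.
#'
#' @param text Motif string (case-insensitive).
#' @param strandMode \code{"forward"}, \code{"reverse"} or \code{"both"},
#'   relative to the gene strand of the scanned unit.
#' @return A [MotifPattern-class].
#' @examples
#' compileIupac("GGWCCAC")
#' @export
compileIupac <- function(text, strandMode = c("forward", "reverse", "both")) {
  strandMode <- match.arg(strandMode)
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("motif text must be a single nonempty string")
  up <- toupper(text)
  chars <- strsplit(up, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% names(.IUPAC_SETS))
  if (length(bad))
    stop(sprintf("invalid IUPAC character '%s' at position %d",
                 chars[bad[1L]], bad[1L]))
  new("MotifPattern", text = up, allowed = .IUPAC_SETS[chars],
      strand_mode = strandMode)
}

#' Reverse-complement a compiled motif
#'
#' Reverses position order and complements every allowed set; degenerate
#' codes map to their standard complements (R to Y, K to M, S and W to
#' themselves, B to V, D to H, N to N). Applying it twice is the identity.
#'
#' @param pattern A [MotifPattern-class].
#' @return A [MotifPattern-class] with the same \code{strand_mode}.
#' @examples
#' motifText(reverseComplementPattern(compileIupac("ATCCG")))  # "CGGAT"
#' @export
reverseComplementPattern <- function(pattern) {
  stopifnot(is(pattern, "MotifPattern"))
  compileIupac(.revcompText(pattern@text), strandMode = pattern@strand_mode)
}

#' Enumerate the concrete words a motif matches
#'
#' Expands the per-position allowed sets into every concrete A/C/G/T word
#' compatible with the pattern ("all the motifs derived from the PWM" when
#' the pattern came from [pwmToPattern()]).
#'
#' @param pattern A [MotifPattern-class].
#' @param max_words Safety cap on the expansion size.
#' @return Character vector of words, lexicographic order.
#' @examples
#' expandPattern(compileIupac("GGW"))
#' @export
expandPattern <- function(pattern, max_words = 65536L) {
  stopifnot(is(pattern, "MotifPattern"))
  n <- prod(lengths(pattern@allowed))
  if (n > max_words)
    stop(sprintf("pattern expands to %d words (cap %d)", n, max_words))
  g <- expand.grid(rev(lapply(pattern@allowed, sort)),
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  sort(do.call(paste0, rev(g)))
}
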