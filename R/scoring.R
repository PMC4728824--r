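# Per-locus scoring: background motif probability, expected counts,
# Motif Score and the cumulative-binomial p-value.

#' The default Arabidopsis background model
#'
#' Genome nucleotide frequencies A = T = 0.32, C = G = 0.18.
#'
#' @return A [BackgroundModel-class].
#' @export
defaultBackground <- function() {
  new("BackgroundModel",
      freqs = c(A = 0.32, C = 0.18, G = 0.18, T = 0.32))
}

#' Construct a background model
#'
#' @param A,C,G,T Nucleotide frequencies, summing to 1.
#' @return A [BackgroundModel-class].
#' @export
backgroundModel <- function(A, C, G, T) {
  new("BackgroundModel", freqs = c(A = A, C = C, G = G, T = T))
}

#' @describeIn backgroundModel Frequency accessor.
#' @param bg A [BackgroundModel-class].
#' @export
backgroundFreqs <- function(bg) {
  stopifnot(is(bg, "BackgroundModel"))
  bg@freqs
}

#' Background probability of a motif (M_P)
#'
#' The probability of observing the motif at a fixed position under the
#' background model: the product over positions of the summed background
#' frequencies of the allowed bases. For a concrete motif this reduces to
#' the plain per-nucleotide product (e.g. ATCCG under the default model is
#' 0.32 x 0.32 x 0.18 x 0.18 x 0.18).
#'
#' @param pattern A [MotifPattern-class].
#' @param bg A [BackgroundModel-class].
#' @return Probability in \code{[0, 1]}.
#' @export
motifBackgroundProb <- function(pattern, bg = defaultBackground()) {
  stopifnot(is(pattern, "MotifPattern"), is(bg, "BackgroundModel"))
  prod(vapply(pattern@allowed, function(s) sum(bg@freqs[s]), 0))
}

#' Possible matching positions (T)
#'
#' \code{T = 2 * (R_L - M_L + 1)} when the region is at least as long as
#' the motif, else 0; the factor 2 accounts for the two strands.
#'
#' @param R_L Region (scan unit) length in bp.
#' @param M_L Motif length in bp.
#' @return Integer count of possible positions (vectorized).
#' @export
possiblePositions <- function(R_L, M_L) {
  stopifnot(all(R_L >= 1), all(M_L >= 1))
  ifelse(R_L >= M_L, 2 * (R_L - M_L + 1), 0)
}

#' Motif Score
#'
#' \code{MS = V_PWM * B_O * ln(B_O / B_E)}: the observed:expected site-count
#' term weighted by the PWM binding probability (1 for plain IUPAC
#' searches). Negative when fewer sites are observed than expected.
#'
#' @param V_PWM Binding probability weight in \code{[0, 1]}.
#' @param B_O Observed site count (>= 1).
#' @param B_E Expected site count (> 0), i.e. \code{M_P * T}.
#' @return The score (vectorized).
#' @export
motifScore <- function(V_PWM, B_O, B_E) {
  stopifnot(all(B_O >= 1), all(B_E > 0), all(V_PWM >= 0), all(V_PWM <= 1))
  V_PWM * B_O * log(B_O / B_E)
}

#' Cumulative binomial p-value for motif abundance
#'
#' Probability of observing at least \code{n} motifs among \code{T}
#' possible positions each matching with probability \code{M_P}:
#' \code{1 - sum_{i<n} C(T,i) M_P^i (1-M_P)^(T-i)}, evaluated via the
#' binomial survival function so it is stable for very large \code{T}.
#'
#' @param n Observed motif count(s), \code{0 <= n <= T}.
#' @param T_pos Possible matching positions.
#' @param M_P Motif background probability.
#' @return p-value(s) in \code{[0, 1]}.
#' @export
binomialPvalue <- function(n, T_pos, M_P) {
  stopifnot(all(n >= 0), all(M_P >= 0), all(M_P <= 1))
  if (any(n > T_pos)) stop("n must not exceed the number of positions T")
  stats::pbinom(n - 1, size = T_pos, prob = M_P, lower.tail = FALSE)
}

#' Significance stars for a p-value
#'
#' \code{***} below 0.001, \code{**} below 0.01, \code{*} below 0.05,
#' \code{ns} otherwise.
#'
#' @param p p-value(s) in \code{[0, 1]}.
#' @return Character vector of \code{ns}/\code{*}/\code{**}/\code{***}.
#' @export
significanceStars <- function(p) {
  stopifnot(all(p >= 0), all(p <= 1))
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Score one locus
#'
#' Assembles the per-locus score report from the hits of one gene's scan
#' unit(s). \code{B_O} (and the binomial \code{n}) is the number of
#' distinct genomic positions hit, pooling both strands and collapsing
#' duplicates across isoforms: the binomial model counts positions, and
#' \code{T} already carries the factor 2 for strands, so a both-strand
#' palindromic pair at one position is a single success (slightly
#' conservative). \code{T} uses the \code{R_L} of the locus's longest scan
#' unit.
#'
#' @param units A [ScanUnit-class] or list of them (the isoforms of one
#'   gene).
#' @param hits Hits \code{data.frame} produced by scanning those units.
#' @param pattern The scanned [MotifPattern-class].
#' @param bg A [BackgroundModel-class].
#' @param V_PWM Locus-level PWM weight (1 for plain IUPAC searches).
#' @return One-row \code{data.frame} with \code{gene_id},
#'   \code{transcript_id}, \code{motif}, \code{B_O}, \code{B_E}, \code{n},
#'   \code{T}, \code{M_P}, \code{V_PWM}, \code{R_L}, \code{MS},
#'   \code{p_value}, \code{significance}; \code{NULL} when there are no
#'   hits.
#' @export
scoreLocus <- function(units, hits, pattern, bg = defaultBackground(),
                       V_PWM = 1) {
  if (is(units, "ScanUnit")) units <- list(units)
  stopifnot(all(vapply(units, is, TRUE, "ScanUnit")),
            is(pattern, "MotifPattern"))
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  rl <- vapply(units, unitLength, 0L)
  longest <- which.max(rl)
  R_L <- rl[longest]
  M_L <- motifLength(pattern)
  B_O <- nrow(unique(hits[, c("chrom", "start", "end")]))
  T_pos <- possiblePositions(R_L, M_L)
  M_P <- motifBackgroundProb(pattern, bg)
  B_E <- M_P * T_pos
  p <- binomialPvalue(B_O, T_pos, M_P)
  data.frame(gene_id = units[[longest]]@gene_id,
             transcript_id = units[[longest]]@transcript_id,
             motif = pattern@text, B_O = B_O, B_E = B_E, n = B_O, T = T_pos,
             M_P = M_P, V_PWM = V_PWM, R_L = R_L,
             MS = motifScore(V_PWM, B_O, B_E), p_value = p,
             significance = significanceStars(p), stringsAsFactors = FALSE)
}
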