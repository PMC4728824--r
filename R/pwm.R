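# Position weight matrices: file IO, per-window binding probability and
# reduction to an IUPAC pattern for scanning/word enumeration.

#' Construct a PWM from a matrix
#'
#' @param mat 4 x L numeric matrix, rows in A/C/G/T order (rownames optional;
#'   they are set). Columns are positions. Probability columns must sum to
#'   1; a count matrix whose columns all sum to the same total is
#'   normalized column-wise.
#' @return A [MotifPWM-class].
#' @export
newPWM <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stop("PWM must have 4 rows (A, C, G, T)")
  rownames(mat) <- c("A", "C", "G", "T")
  cs <- colSums(mat)
  if (all(abs(cs - 1) <= 1e-6)) {
    mat <- sweep(mat, 2L, cs, "/")           # remove rounding slack
  } else if (all(cs > 0) && max(abs(cs - cs[1L])) <= 1e-6) {
    mat <- sweep(mat, 2L, cs, "/")           # common-total count matrix
  } else {
    stop("PWM columns must sum to 1 (probabilities) or to a common total",
         " (counts)")
  }
  new("MotifPWM", mat = mat)
}

#' Read a PWM from a whitespace-delimited text file
#'
#' Expects 4 labelled rows (A/C/G/T, any order) by L columns of
#' probabilities, or a count matrix whose columns share a common total
#' (normalized on load). Lines starting with \code{#} are ignored.
#'
#' @param path File path.
#' @return A [MotifPWM-class].
#' @export
readPWM <- function(path) {
  if (!file.exists(path)) stop("PWM file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  labels <- toupper(as.character(tab[[1L]]))
  if (!setequal(labels, c("A", "C", "G", "T")))
    stop("PWM rows must be labelled A, C, G, T")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  if (anyNA(m)) stop("non-numeric PWM entries in ", path)
  newPWM(m[match(c("A", "C", "G", "T"), labels), , drop = FALSE])
}

#' @describeIn newPWM Number of PWM columns (positions).
#' @param pwm A [MotifPWM-class].
#' @export
pwmLength <- function(pwm) {
  stopifnot(is(pwm, "MotifPWM"))
  ncol(pwm@mat)
}

#' @describeIn newPWM Per-column argmax base string (ties broken A<C<G<T).
#' @export
pwmConsensus <- function(pwm) {
  stopifnot(is(pwm, "MotifPWM"))
  paste(rownames(pwm@mat)[apply(pwm@mat, 2L, which.max)], collapse = "")
}

#' PWM binding probability of a concrete window
#'
#' The probability that the transcription factor binds this exact sequence:
#' the product over positions of the column probability of the observed
#' base (the V_PWM weight of the scoring formulas).
#'
#' @param pwm A [MotifPWM-class].
#' @param window Concrete A/C/G/T string of length \code{pwmLength(pwm)}.
#' @param normalize If \code{TRUE}, divide by the consensus-word
#'   probability so the best possible window scores 1.
#' @return Probability in \code{[0, 1]}.
#' @examples
#' p <- newPWM(matrix(c(.5, .5, 0, 0, 0, 0, .5, .5), nrow = 4))
#' pwmMatchProb(p, "AG")  # 0.25
#' @export
pwmMatchProb <- function(pwm, window, normalize = FALSE) {
  stopifnot(is(pwm, "MotifPWM"))
  chars <- strsplit(toupper(window), "", fixed = TRUE)[[1L]]
  if (length(chars) != pwmLength(pwm))
    stop(sprintf("window length %d != PWM length %d", length(chars),
                 pwmLength(pwm)))
  rows <- match(chars, rownames(pwm@mat))
  if (anyNA(rows)) stop("window must contain only A/C/G/T")
  v <- prod(pwm@mat[cbind(rows, seq_along(rows))])
  if (normalize) {
    best <- prod(apply(pwm@mat, 2L, max))
    v <- if (best > 0) v / best else 0
  }
  v
}

#' Reduce a PWM to an IUPAC pattern
#'
#' The per-position allowed set is the bases whose column probability is at
#' least \code{min_prob}. The resulting pattern defines both the scan and
#' the enumeration "all the motifs derived from the PWM" used by the
#' Binding Score counts.
#'
#' @param pwm A [MotifPWM-class].
#' @param min_prob Probability floor in \code{(0, 1]} (default 0.05).
#' @param strandMode Passed to [compileIupac()].
#' @return A [MotifPattern-class].
#' @export
pwmToPattern <- function(pwm, min_prob = 0.05,
                         strandMode = c("forward", "reverse", "both")) {
  stopifnot(is(pwm, "MotifPWM"))
  if (min_prob <= 0 || min_prob > 1) stop("min_prob must be in (0, 1]")
  codes <- vapply(seq_len(pwmLength(pwm)), function(j) {
    bases <- rownames(pwm@mat)[pwm@mat[, j] >= min_prob]
    if (length(bases) == 0L)
      stop(sprintf(paste0("PWM column %d has no base with probability >= ",
                          "%g; lower min_prob"), j, min_prob))
    unname(.SET_TO_CODE[paste(sort(bases), collapse = "")])
  }, "")
  compileIupac(paste(codes, collapse = ""), strandMode = match.arg(strandMode))
}

#' @describeIn compileIupac Motif text accessor.
#' @param pattern A [MotifPattern-class].
#' @export
motifText <- function(pattern) {
  stopifnot(is(pattern, "MotifPattern"))
  pattern@text
}

#' @describeIn compileIupac Motif length in bp (the M_L of the formulas).
#' @export
motifLength <- function(pattern) {
  stopifnot(is(pattern, "MotifPattern"))
  nchar(pattern@text)
}
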