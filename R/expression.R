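# Expression integration: fold-change thresholding, Binding Score,
# chi-squared enrichment and primary/secondary target classification.

#' Load an expression fold-change table
#'
#' Two tab-delimited columns: gene id and fold change. A header row is
#' auto-detected (non-numeric second field) and skipped.
#'
#' @param tsv_path File path.
#' @return Named numeric vector of fold changes, names = gene ids.
#' @export
loadExpression <- function(tsv_path) {
  if (!file.exists(tsv_path)) stop("expression file not found: ", tsv_path)
  lines <- readLines(tsv_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty expression file: ", tsv_path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad_shape <- which(lengths(parts) < 2L)
  if (length(bad_shape))
    stop("expression row ", bad_shape[1L], " does not have 2 tab-delimited",
         " fields")
  ids <- vapply(parts, `[`, "", 1L)
  vals <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (is.na(vals[1L])) {           # header row
    ids <- ids[-1L]; vals <- vals[-1L]
    if (length(ids) == 0L) stop("expression file has a header but no data")
  }
  bad <- which(is.na(vals))
  if (length(bad))
    stop("non-numeric fold change for gene(s): ",
         paste(ids[bad], collapse = ", "))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate gene id(s) in expression file: ",
         paste(unique(dup), collapse = ", "))
  stats::setNames(vals, ids)
}

#' Fold-change threshold test
#'
#' On the \code{log2} scale a gene is above threshold when
#' \code{|fc| >= FCT}. On the \code{linear} scale both directions count:
#' \code{max(fc, 1/fc) >= FCT} for \code{fc > 0} (a 0.25-fold gene is
#' 4-fold down).
#'
#' @param fc Fold change(s).
#' @param FCT Positive threshold.
#' @param scale \code{"log2"} (default) or \code{"linear"}.
#' @return Logical vector.
#' @export
isAboveThreshold <- function(fc, FCT, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  stopifnot(FCT > 0)
  if (scale == "log2") return(abs(fc) >= FCT)
  if (any(fc <= 0)) stop("linear fold changes must be > 0")
  pmax(fc, 1 / fc) >= FCT
}

#' Binding Score of one locus
#'
#' \code{BS = sum_i V_PWM(i) * B_FC_Spec(w_i) * ln((B_FC_Spec(w_i) /
#' B_Tot_Spec(w_i)) / (B_FC / B_Tot))}, summed over the locus's motif
#' instances \code{i} with concrete word \code{w_i}. \code{B_FC} /
#' \code{B_Tot} are the above-threshold and total genome-wide site counts
#' over all words derived from the pattern; the \code{Spec} counts are the
#' same quantities for the instance's specific word. Any term whose inner
#' ratio involves a zero count contributes 0 (the information-less limit of
#' the undefined expression).
#'
#' @param V_PWM Per-instance PWM weights (recycled).
#' @param B_FC_Spec,B_Tot_Spec Per-instance specific-word counts.
#' @param B_FC,B_Tot Scalar all-words counts.
#' @return The summed score; 0 for an empty instance list.
#' @export
bindingScore <- function(V_PWM, B_FC_Spec, B_Tot_Spec, B_FC, B_Tot) {
  k <- length(B_FC_Spec)
  if (k == 0L) return(0)
  V_PWM <- rep_len(V_PWM, k)
  ok <- B_FC_Spec > 0 & B_Tot_Spec > 0 & B_FC > 0 & B_Tot > 0
  terms <- numeric(k)
  terms[ok] <- V_PWM[ok] * B_FC_Spec[ok] *
    log((B_FC_Spec[ok] / B_Tot_Spec[ok]) / (B_FC / B_Tot))
  sum(terms)
}

#' Chi-squared enrichment of the specific word among DE genes
#'
#' Tests whether genes carrying the specific word's sites are
#' differentially expressed more often than genes carrying only other
#' words derived from the pattern. The 2 x 2 table (1 df, no continuity
#' correction) is \code{[[DE & spec, spec - DE & spec], [DE & rest,
#' rest - DE & rest]]} where \code{rest = all - spec}, so the two groups
#' are disjoint. With \code{include_specific_in_all = TRUE} the second row
#' keeps the specific-word genes inside the "all" group instead.
#'
#' @param genes_with_sites_all Genes with at least one site of any word.
#' @param genes_with_sites_and_DE_all Of those, the DE ones.
#' @param genes_with_sites_spec Genes with at least one specific-word site.
#' @param genes_with_sites_and_DE_spec Of those, the DE ones.
#' @param include_specific_in_all Keep the specific genes inside the
#'   comparison group (default \code{FALSE}).
#' @return List with \code{stat}, \code{p}, \code{df}, \code{table} and
#'   \code{computed} (\code{FALSE} with a \code{reason} when any expected
#'   cell is 0).
#' @export
chiSquareEnrichment <- function(genes_with_sites_all,
                                genes_with_sites_and_DE_all,
                                genes_with_sites_spec,
                                genes_with_sites_and_DE_spec,
                                include_specific_in_all = FALSE) {
  if (genes_with_sites_and_DE_all > genes_with_sites_all ||
      genes_with_sites_and_DE_spec > genes_with_sites_spec ||
      genes_with_sites_spec > genes_with_sites_all ||
      genes_with_sites_and_DE_spec > genes_with_sites_and_DE_all)
    stop("inconsistent counts: DE-and-sites cannot exceed sites, and spec",
         " counts cannot exceed all counts")
  if (include_specific_in_all) {
    r2_de <- genes_with_sites_and_DE_all
    r2_n <- genes_with_sites_all
  } else {
    r2_de <- genes_with_sites_and_DE_all - genes_with_sites_and_DE_spec
    r2_n <- genes_with_sites_all - genes_with_sites_spec
  }
  tab <- rbind(
    spec = c(DE = genes_with_sites_and_DE_spec,
             notDE = genes_with_sites_spec - genes_with_sites_and_DE_spec),
    rest = c(DE = r2_de, notDE = r2_n - r2_de))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0) || any(!is.finite(expected)))
    return(list(stat = NA_real_, p = NA_real_, df = 1L, table = tab,
                computed = FALSE, reason = "zero expected cell"))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(stat = unname(ct$statistic), p = unname(ct$p.value), df = 1L,
       table = tab, computed = TRUE)
}

#' Classify primary/secondary/unchanged targets
#'
#' A differentially expressed gene with at least one binding site in the
#' selected regions is a \emph{primary} target (directly bound); a DE gene
#' without sites is \emph{secondary}; genes below the threshold are
#' \emph{unchanged}. Genes with sites but no expression record are
#' \code{unchanged} and flagged.
#'
#' @param gene_ids Gene ids to classify.
#' @param n_sites Site count per gene (same length).
#' @param expr Named fold-change vector from [loadExpression()].
#' @param FCT,scale Passed to [isAboveThreshold()].
#' @return \code{data.frame}: \code{gene_id}, \code{fold_change},
#'   \code{n_sites}, \code{target_class}, \code{flag}.
#' @export
classifyTargets <- function(gene_ids, n_sites, expr, FCT = 1,
                            scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  stopifnot(length(gene_ids) == length(n_sites))
  fc <- unname(expr[gene_ids])
  have <- !is.na(fc)
  de <- rep(FALSE, length(gene_ids))
  de[have] <- isAboveThreshold(fc[have], FCT, scale)
  cls <- ifelse(de & n_sites > 0, "primary",
                ifelse(de, "secondary", "unchanged"))
  data.frame(gene_id = gene_ids, fold_change = fc, n_sites = n_sites,
             target_class = cls,
             flag = ifelse(have, "", "no expression data"),
             stringsAsFactors = FALSE)
}

#' Per-gene Binding Score report
#'
#' Integrates a genome-wide scan with an expression table: computes the
#' four count symbols per concrete word (above-threshold and total site
#' counts, specific word vs all words of the pattern), the per-gene Binding
#' Score, the global chi-squared enrichment of a chosen specific word, and
#' the target classification.
#'
#' Sites count per occurrence ("site-weighted"): a binding site is above
#' the threshold when the gene holding it is. For reverse-strand hits the
#' word is reverse-complemented so all instances are counted in the motif
#' orientation.
#'
#' @param hits Genome-wide hits \code{data.frame} from scanning every gene
#'   (columns as produced by [scanUnit()]; an optional \code{V_PWM} column
#'   supplies per-hit weights, default 1).
#' @param expr Named fold-change vector from [loadExpression()].
#' @param FCT,scale Passed to [isAboveThreshold()].
#' @param specific_word Word for the chi-squared test; default the most
#'   frequent word in \code{hits}.
#' @param include_specific_in_all Passed to [chiSquareEnrichment()].
#' @return \code{data.frame} with one row per gene appearing in
#'   \code{hits} or \code{expr}: \code{gene_id}, \code{n_sites},
#'   \code{fold_change}, \code{regions}, \code{BS}, \code{target_class},
#'   \code{flag}; the chi-squared result, the count symbols and the
#'   specific word are attached as attribute \code{"enrichment"}.
#' @export
bindingScoreReport <- function(hits, expr, FCT = 1,
                               scale = c("log2", "linear"),
                               specific_word = NULL,
                               include_specific_in_all = FALSE) {
  scale <- match.arg(scale)
  has_hits <- !is.null(hits) && nrow(hits) > 0L
  if (has_hits) {
    word <- ifelse(hits$strand == "reverse", .revcompText(hits$sequence),
                   hits$sequence)
    vpwm <- if ("V_PWM" %in% names(hits)) hits$V_PWM else rep(1, nrow(hits))
    gene_fc <- expr[hits$gene_id]
    site_de <- rep(FALSE, nrow(hits))
    known <- !is.na(gene_fc)
    site_de[known] <- isAboveThreshold(gene_fc[known], FCT, scale)
    B_Tot <- nrow(hits)
    B_FC <- sum(site_de)
    B_Tot_word <- table(word)
    B_FC_word <- table(factor(word[site_de], levels = names(B_Tot_word)))
    if (is.null(specific_word))
      specific_word <- names(B_Tot_word)[which.max(B_Tot_word)]
  } else {
    word <- character(0); vpwm <- numeric(0); site_de <- logical(0)
    B_Tot <- 0L; B_FC <- 0L
    B_Tot_word <- table(character(0)); B_FC_word <- B_Tot_word
    if (is.null(specific_word)) specific_word <- NA_character_
  }

  gene_ids <- sort(unique(c(if (has_hits) hits$gene_id, names(expr))))
  n_sites <- if (has_hits)
    as.integer(table(factor(hits$gene_id, levels = gene_ids)))
  else integer(length(gene_ids))
  regions <- vapply(gene_ids, function(g) {
    if (!has_hits) return("")
    r <- unique(unlist(strsplit(hits$region[hits$gene_id == g], "|",
                                fixed = TRUE)))
    paste(.REGION_KINDS[.REGION_KINDS %in% r], collapse = ",")
  }, "")
  BS <- vapply(gene_ids, function(g) {
    if (!has_hits) return(0)
    i <- which(hits$gene_id == g)
    if (length(i) == 0L) return(0)
    w <- word[i]
    bindingScore(vpwm[i],
                 as.numeric(B_FC_word[w]), as.numeric(B_Tot_word[w]),
                 B_FC, B_Tot)
  }, 0)

  cls <- classifyTargets(gene_ids, n_sites, expr, FCT, scale)
  out <- data.frame(gene_id = gene_ids, n_sites = n_sites,
                    fold_change = cls$fold_change, regions = regions,
                    BS = BS, target_class = cls$target_class,
                    flag = cls$flag, stringsAsFactors = FALSE)
  rownames(out) <- NULL

  de_genes <- names(expr)[isAboveThreshold(expr, FCT, scale)]
  if (has_hits) {
    genes_of_word <- function(w) unique(hits$gene_id[word == w])
    g_all <- unique(hits$gene_id)
    g_spec <- if (!is.na(specific_word)) genes_of_word(specific_word)
              else character(0)
    enr <- chiSquareEnrichment(
      length(g_all), sum(g_all %in% de_genes),
      length(g_spec), sum(g_spec %in% de_genes),
      include_specific_in_all = include_specific_in_all)
  } else {
    enr <- list(stat = NA_real_, p = NA_real_, df = 1L, computed = FALSE,
                reason = "no sites")
  }
  attr(out, "enrichment") <- c(enr, list(
    specific_word = specific_word, B_Tot = B_Tot, B_FC = B_FC,
    B_Tot_Spec = if (has_hits && !is.na(specific_word) &&
                     specific_word %in% names(B_Tot_word))
      as.integer(B_Tot_word[specific_word]) else 0L,
    B_FC_Spec = if (has_hits && !is.na(specific_word) &&
                    specific_word %in% names(B_FC_word))
      as.integer(B_FC_word[specific_word]) else 0L))
  out
}
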