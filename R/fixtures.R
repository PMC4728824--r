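# Deterministic synthetic fixtures: background-sampled genomes with
# parametric gene structures, planted motif sites and DE labels.

#' Construct a FixtureSpec
#'
#' All arguments have defaults describing a small but complete study
#' condition: a single ~45 kb chromosome of 50 genes with 20 planted sites
#' of a 7 bp motif spread over all six region kinds, 30% DE genes and no
#' enrichment (null design). See [FixtureSpec-class] for the meaning of
#' each parameter.
#'
#' @param seed,n_chromosomes,n_genes,background,motif,n_planted_sites
#'   See [FixtureSpec-class].
#' @param region_probs,de_fraction,enrichment_odds,specific_word See
#'   [FixtureSpec-class].
#' @param fc_de_mean,fc_de_sd,fc_null_sd,fct,intergenic_len,n_interactions
#'   See [FixtureSpec-class].
#' @return A [FixtureSpec-class].
#' @export
fixtureSpec <- function(seed = 1L, n_chromosomes = 1L, n_genes = 50L,
                        background = defaultBackground(),
                        motif = "GGTWCAC", n_planted_sites = 20L,
                        region_probs = stats::setNames(rep(1 / 6, 6),
                                                       regionKinds()),
                        de_fraction = 0.3, enrichment_odds = 1,
                        specific_word = "", fc_de_mean = 2.5,
                        fc_de_sd = 0.5, fc_null_sd = 0.25, fct = 1,
                        intergenic_len = 100L, n_interactions = 40L) {
  new("FixtureSpec", seed = as.integer(seed),
      n_chromosomes = as.integer(n_chromosomes),
      n_genes = as.integer(n_genes), background = background,
      motif = toupper(motif), n_planted_sites = as.integer(n_planted_sites),
      region_probs = region_probs, de_fraction = de_fraction,
      enrichment_odds = enrichment_odds, specific_word = specific_word,
      fc_de_mean = fc_de_mean, fc_de_sd = fc_de_sd, fc_null_sd = fc_null_sd,
      fct = fct, intergenic_len = as.integer(intergenic_len),
      n_interactions = as.integer(n_interactions))
}

.specificWord <- function(spec) {
  if (nzchar(spec@specific_word)) toupper(spec@specific_word)
  else expandPattern(compileIupac(spec@motif))[1L]
}

# largest-remainder quotas: every kind with positive probability is
# represented once n is large enough, and counts are deterministic
.regionQuotas <- function(probs, n) {
  raw <- probs * n
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    o <- order(raw - counts, decreasing = TRUE)
    counts[o[seq_len(left)]] <- counts[o[seq_len(left)]] + 1
  }
  as.integer(counts)
}

# DE labels, fold changes and site->(gene, kind, word) assignments; the
# statistical core shared by simulateEnrichment() and generateFixture().
# Assumes set.seed() was already called.
.simulateStructure <- function(spec) {
  n <- spec@n_genes
  gene_ids <- sprintf("SYNG%03d", seq_len(n))
  de <- stats::runif(n) < spec@de_fraction
  fc <- numeric(n)
  if (any(de)) {
    v <- abs(stats::rnorm(sum(de), spec@fc_de_mean, spec@fc_de_sd))
    while (any(v < spec@fct))
      v[v < spec@fct] <- abs(stats::rnorm(sum(v < spec@fct),
                                          spec@fc_de_mean, spec@fc_de_sd))
    fc[de] <- v * sample(c(-1, 1), sum(de), replace = TRUE)
  }
  if (any(!de)) {
    v <- stats::rnorm(sum(!de), 0, spec@fc_null_sd)
    while (any(abs(v) >= spec@fct))
      v[abs(v) >= spec@fct] <- stats::rnorm(sum(abs(v) >= spec@fct), 0,
                                            spec@fc_null_sd)
    fc[!de] <- v
  }

  pattern <- compileIupac(spec@motif)
  spec_word <- .specificWord(spec)
  ns <- spec@n_planted_sites
  kinds <- rep(regionKinds(), .regionQuotas(spec@region_probs, ns))
  kinds <- sample(kinds)
  words <- vapply(seq_len(ns), function(i)
    paste(vapply(pattern@allowed, function(s) sample(s, 1L), ""),
          collapse = ""), "")
  site_gene <- integer(ns)
  for (i in seq_len(ns)) {
    w <- if (words[i] == spec_word)
      ifelse(de, spec@enrichment_odds, 1) else rep(1, n)
    site_gene[i] <- sample.int(n, 1L, prob = w)
  }
  list(genes = data.frame(gene_id = gene_ids, de = de, fold_change = fc,
                          stringsAsFactors = FALSE),
       sites = if (ns > 0L)
         data.frame(site_id = seq_len(ns), gene_id = gene_ids[site_gene],
                    kind = kinds, word = words, stringsAsFactors = FALSE)
       else data.frame(site_id = integer(0), gene_id = character(0),
                       kind = character(0), word = character(0)),
       specific_word = spec_word)
}

#' Simulate the site/DE count structure of a fixture
#'
#' The statistical layer of the generator without sequence realization:
#' DE labels, fold changes, and planted-site assignments (gene, region
#' kind, concrete word), with \code{enrichment_odds} applied to
#' specific-word sites. Used for the many-replicate calibration of the
#' chi-squared enrichment test and the Binding Score, where only the count
#' structure matters; [generateFixture()] realizes the identical structure
#' as sequence files.
#'
#' @param spec A [FixtureSpec-class]; \code{spec@seed} fully determines the
#'   output.
#' @return List with \code{genes} (gene_id, de, fold_change), \code{sites}
#'   (site_id, gene_id, kind, word) and \code{specific_word}.
#' @export
simulateEnrichment <- function(spec) {
  stopifnot(is(spec, "FixtureSpec"))
  set.seed(spec@seed)
  .simulateStructure(spec)
}

.GENE_DESCRIPTIONS <- c("protein kinase", "receptor-like kinase",
                        "MYB-family transcription factor",
                        "ABC transporter", "glycosyl hydrolase",
                        "unknown protein", "cytochrome P450",
                        "pectin methylesterase")
.BIOCHEM_METHODS <- c("Yeast Two-Hybrid", "Pull-Down",
                      "Affinity Capture-MS", "Co-Immunoprecipitation",
                      "Far Western Blotting", "Split-Reporter Assay")

#' Generate a synthetic fixture dataset
#'
#' Realizes a [FixtureSpec-class] as files: a background-sampled genome
#' FASTA, a GFF3 with parametric gene structures (5' UTR, 1-3 coding exons
#' with introns, 3' UTR, both strands), an expression fold-change TSV, an
#' interactions TSV, and truth tables listing every planted site (gene,
#' region, ATG-relative position, strand, genomic interval, word) and
#' every DE label.
#'
#' Planted sites are written at recorded positions; background windows that
#' would spuriously match the motif (either orientation) are resampled
#' until the genome contains exactly the planted occurrences, so truth
#' counts are exact rather than statistical. Intergenic sites are planted
#' within \code{intergenic_len} bp of their gene and gaps between genes
#' are at least 220 bp, so with matching scan flank lengths each planted
#' site falls in exactly one gene's scan unit. Running twice with the same
#' spec produces byte-identical files.
#'
#' @param spec A [FixtureSpec-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with file \code{paths}, the \code{sites} and
#'   \code{genes} truth tables, and \code{specific_word}.
#' @export
generateFixture <- function(spec, dir) {
  stopifnot(is(spec, "FixtureSpec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(spec@seed)
  struct <- .simulateStructure(spec)
  n <- spec@n_genes
  ml <- nchar(spec@motif)
  if (spec@intergenic_len < ml)
    stop("intergenic_len shorter than the motif: sites cannot fit")

  # --- gene structures (gene-strand region lengths) -----------------------
  strand <- sample(c("+", "-"), n, replace = TRUE)
  utr5 <- sample(40:80, n, replace = TRUE)
  utr3 <- sample(30:60, n, replace = TRUE)
  # every synthetic gene is multi-exon so all six region kinds exist
  n_cds <- sample(2:3, n, replace = TRUE)
  cds_lens <- lapply(n_cds, function(k) sample(60:120, k, replace = TRUE))
  intron_lens <- lapply(n_cds, function(k)
    if (k > 1L) sample(60:120, k - 1L, replace = TRUE) else integer(0))
  gaps <- sample(220:400, n, replace = TRUE)

  per_chrom <- ceiling(n / spec@n_chromosomes)
  chrom_of <- paste0("chr", ceiling(seq_len(n) / per_chrom))

  # --- genomic layout -----------------------------------------------------
  gene_regions <- vector("list", n)   # data.frame kind/start/end, ascending
  gene_tx <- matrix(0L, n, 2L)        # tx start/end
  cursor <- stats::setNames(rep(0L, spec@n_chromosomes),
                            paste0("chr", seq_len(spec@n_chromosomes)))
  for (i in seq_len(n)) {
    ch <- chrom_of[i]
    cursor[ch] <- cursor[ch] + gaps[i]
    # gene-strand order of genic regions
    kinds5to3 <- c("utr5",
                   as.vector(rbind(rep("exon_cds", n_cds[i]),
                                   c(rep("intron", n_cds[i] - 1L), NA)))[
                     seq_len(2L * n_cds[i] - 1L)],
                   "utr3")
    lens5to3 <- c(utr5[i],
                  as.vector(rbind(cds_lens[[i]],
                                  c(intron_lens[[i]], NA)))[
                    seq_len(2L * n_cds[i] - 1L)],
                  utr3[i])
    if (strand[i] == "-") { kinds5to3 <- rev(kinds5to3)
                            lens5to3 <- rev(lens5to3) }
    s <- cursor[ch] + 1L
    ends <- cursor[ch] + cumsum(lens5to3)
    starts <- c(s, ends[-length(ends)] + 1L)
    gene_regions[[i]] <- data.frame(kind = kinds5to3, start = starts,
                                    end = ends, stringsAsFactors = FALSE)
    gene_tx[i, ] <- c(starts[1L], ends[length(ends)])
    cursor[ch] <- ends[length(ends)]
  }
  chrom_len <- cursor + 300L
  names(chrom_len) <- names(cursor)

  # --- place planted sites ------------------------------------------------
  sites <- struct$sites
  ns <- nrow(sites)
  placed <- data.frame(chrom = character(ns), gstart = integer(ns),
                       gend = integer(ns), atg_position = integer(ns),
                       stringsAsFactors = FALSE)
  occupied <- list()  # per chromosome: matrix of intervals
  overlaps <- function(ch, s, e) {
    occ <- occupied[[ch]]
    !is.null(occ) && any(occ[, 1L] <= e & occ[, 2L] >= s)
  }
  for (j in seq_len(ns)) {
    gi <- match(sites$gene_id[j], struct$genes$gene_id)
    ch <- chrom_of[gi]
    reg <- gene_regions[[gi]]
    kind <- sites$kind[j]
    minus <- strand[gi] == "-"
    if (kind == "intergenic5") {
      iv <- if (minus) c(gene_tx[gi, 2L] + 1L,
                         gene_tx[gi, 2L] + spec@intergenic_len)
            else c(gene_tx[gi, 1L] - spec@intergenic_len,
                   gene_tx[gi, 1L] - 1L)
      cand <- matrix(iv, 1L)
    } else if (kind == "intergenic3") {
      iv <- if (minus) c(gene_tx[gi, 1L] - spec@intergenic_len,
                         gene_tx[gi, 1L] - 1L)
            else c(gene_tx[gi, 2L] + 1L, gene_tx[gi, 2L] + spec@intergenic_len)
      cand <- matrix(iv, 1L)
    } else {
      rr <- reg[reg$kind == kind, , drop = FALSE]
      if (nrow(rr) == 0L)
        stop("gene ", sites$gene_id[j], " has no ", kind,
             " region to plant in")
      cand <- cbind(rr$start, rr$end)
    }
    ok <- FALSE
    for (try in seq_len(200L)) {
      r <- cand[sample.int(nrow(cand), 1L), ]
      if (r[2L] - r[1L] + 1L < ml) next
      off <- sample.int(r[2L] - r[1L] + 2L - ml, 1L) - 1L
      s0 <- if (minus) r[2L] - off - ml + 1L else r[1L] + off
      e0 <- s0 + ml - 1L
      if (s0 < 1L || e0 > chrom_len[ch]) next
      if (overlaps(ch, s0, e0)) next
      occupied[[ch]] <- rbind(occupied[[ch]], c(s0, e0))
      placed$chrom[j] <- ch; placed$gstart[j] <- s0; placed$gend[j] <- e0
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place site ", j, " without overlap")
    # ATG-relative position of the site's gene-strand 5'-most base
    cds <- reg[reg$kind == "exon_cds", , drop = FALSE]
    atg <- if (minus) max(cds$end) else min(cds$start)
    g5 <- if (minus) placed$gend[j] else placed$gstart[j]
    d <- if (minus) atg - g5 else g5 - atg
    placed$atg_position[j] <- if (d >= 0L) d + 1L else d
  }

  # --- sequence: background + planted words, then scrub spurious ----------
  bg <- backgroundFreqs(spec@background)
  seqs <- lapply(names(chrom_len), function(ch)
    sample(c("A", "C", "G", "T"), chrom_len[ch], replace = TRUE, prob = bg))
  names(seqs) <- names(chrom_len)
  for (j in seq_len(ns)) {
    gi <- match(sites$gene_id[j], struct$genes$gene_id)
    w <- if (strand[gi] == "-") .revcompText(sites$word[j]) else sites$word[j]
    seqs[[placed$chrom[j]]][placed$gstart[j]:placed$gend[j]] <-
      strsplit(w, "", fixed = TRUE)[[1L]]
  }
  pat_both <- compileIupac(spec@motif, strandMode = "both")
  for (ch in names(seqs)) {
    keep <- placed$gstart[placed$chrom == ch]
    planted_pos <- unlist(Map(seq.int,
                              placed$gstart[placed$chrom == ch],
                              placed$gend[placed$chrom == ch]))
    for (iter in seq_len(100L)) {
      m <- scanSequence(paste(seqs[[ch]], collapse = ""), pat_both)
      spurious <- m[!(m$offset + 1L) %in% keep, , drop = FALSE]
      if (nrow(spurious) == 0L) break
      if (iter == 100L) stop("could not scrub spurious matches on ", ch)
      for (o in spurious$offset) {
        pos <- setdiff((o + 1L):(o + ml), planted_pos)
        seqs[[ch]][pos] <- sample(c("A", "C", "G", "T"), length(pos),
                                  replace = TRUE, prob = bg)
      }
    }
  }

  # --- annotation text ----------------------------------------------------
  desc <- sample(.GENE_DESCRIPTIONS, n, replace = TRUE)
  has_ec <- seq_len(n) %% 5L == 0L
  ec <- ifelse(has_ec,
               sprintf("EC:%d.%d.%d.%d", sample(1:6, n, replace = TRUE),
                       sample(1:9, n, replace = TRUE),
                       sample(1:9, n, replace = TRUE),
                       sample(1:99, n, replace = TRUE)), "")

  # --- write files --------------------------------------------------------
  paths <- list(fasta = file.path(dir, "genome.fa"),
                gff3 = file.path(dir, "genes.gff3"),
                expression = file.path(dir, "expression.tsv"),
                interactions = file.path(dir, "interactions.tsv"),
                truth_sites = file.path(dir, "truth_sites.tsv"),
                truth_genes = file.path(dir, "truth_genes.tsv"))

  dss <- DNAStringSet(vapply(seqs, paste, "", collapse = ""))
  names(dss) <- names(seqs)
  Biostrings::writeXStringSet(dss, paths$fasta, width = 70L)

  gff <- c("##gff-version 3")
  for (i in seq_len(n)) {
    gid <- struct$genes$gene_id[i]
    ch <- chrom_of[i]
    reg <- gene_regions[[i]]
    attrs <- sprintf("ID=%s;Name=%s;description=%s%s", gid,
                     paste0(gid, "p"), desc[i],
                     ifelse(nzchar(ec[i]), paste0(";ec_number=", ec[i]), ""))
    gff <- c(gff, paste(ch, "synth", "gene", gene_tx[i, 1L], gene_tx[i, 2L],
                        ".", strand[i], ".", attrs, sep = "\t"))
    tid <- paste0(gid, ".1")
    gff <- c(gff, paste(ch, "synth", "mRNA", gene_tx[i, 1L], gene_tx[i, 2L],
                        ".", strand[i], ".",
                        sprintf("ID=%s;Parent=%s", tid, gid), sep = "\t"))
    feat <- function(type, s, e, phase = ".")
      paste(ch, "synth", type, s, e, ".", strand[i], phase,
            sprintf("ID=%s.%s.%d;Parent=%s", tid, type, s, tid), sep = "\t")
    rows <- character(0)
    for (k in seq_len(nrow(reg))) {
      type <- switch(reg$kind[k], utr5 = "five_prime_UTR", utr3 =
                     "three_prime_UTR", exon_cds = "CDS", intron = NA)
      if (!is.na(type))
        rows <- c(rows, feat(type, reg$start[k], reg$end[k],
                             if (type == "CDS") "0" else "."))
    }
    # exons: genic regions minus introns, merged where contiguous
    genic <- reg[reg$kind != "intron", , drop = FALSE]
    ex_s <- integer(0); ex_e <- integer(0)
    for (k in seq_len(nrow(genic))) {
      if (length(ex_e) && genic$start[k] == ex_e[length(ex_e)] + 1L) {
        ex_e[length(ex_e)] <- genic$end[k]
      } else {
        ex_s <- c(ex_s, genic$start[k]); ex_e <- c(ex_e, genic$end[k])
      }
    }
    for (k in seq_along(ex_s))
      rows <- c(rows, feat("exon", ex_s[k], ex_e[k]))
    gff <- c(gff, rows)
  }
  writeLines(gff, paths$gff3)

  writeLines(sprintf("%s\t%.4f", struct$genes$gene_id,
                     struct$genes$fold_change), paths$expression)

  ni <- spec@n_interactions
  if (ni > 0L && n >= 2L) {
    ia <- sample(struct$genes$gene_id, ni, replace = TRUE)
    ib <- sample(struct$genes$gene_id, ni, replace = TRUE)
    fix <- ia == ib
    while (any(fix)) {
      ib[fix] <- sample(struct$genes$gene_id, sum(fix), replace = TRUE)
      fix <- ia == ib
    }
    ev <- sample(c("biochemical", "computational"), ni, replace = TRUE)
    me <- ifelse(ev == "biochemical",
                 sample(.BIOCHEM_METHODS, ni, replace = TRUE), "in silico")
    writeLines(sprintf("%s\t%s\t%s\t%s", ia, ib, ev, me),
               paths$interactions)
  } else {
    writeLines(character(0), paths$interactions)
  }

  truth_sites <- cbind(sites,
                       transcript_id = paste0(sites$gene_id, ".1"),
                       chrom = placed$chrom, start = placed$gstart,
                       end = placed$gend,
                       gene_strand = strand[match(sites$gene_id,
                                                  struct$genes$gene_id)],
                       atg_position = placed$atg_position,
                       stringsAsFactors = FALSE)
  utils::write.table(truth_sites, paths$truth_sites, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(struct$genes, paths$truth_genes, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  invisible(list(paths = paths, sites = truth_sites, genes = struct$genes,
                 specific_word = struct$specific_word, spec = spec))
}

#' Summarize enrichment statistics of a simulated structure
#'
#' Computes, from the count structure returned by [simulateEnrichment()],
#' the specific-word chi-squared enrichment ([chiSquareEnrichment()]) and
#' the mean per-locus Binding Score over loci carrying sites, using the
#' simulation's own DE labels. This is the quantity pair the calibration
#' analyses track across replicates.
#'
#' @param struct Result of [simulateEnrichment()].
#' @return List with \code{chi2} (the [chiSquareEnrichment()] result) and
#'   \code{mean_BS}.
#' @export
summarizeEnrichment <- function(struct) {
  de_of <- stats::setNames(struct$genes$de, struct$genes$gene_id)
  s <- struct$sites
  if (nrow(s) == 0L)
    return(list(chi2 = list(stat = NA_real_, p = NA_real_,
                            computed = FALSE, reason = "no sites"),
                mean_BS = NA_real_))
  w_tot <- table(s$word)
  w_fc <- table(factor(s$word[de_of[s$gene_id]], levels = names(w_tot)))
  b_tot <- nrow(s)
  b_fc <- sum(de_of[s$gene_id])
  per_gene <- split(s$word, s$gene_id)
  mean_bs <- mean(vapply(per_gene, function(w)
    bindingScore(1, as.numeric(w_fc[w]), as.numeric(w_tot[w]),
                 b_fc, b_tot), 0))
  g_all <- unique(s$gene_id)
  g_spec <- unique(s$gene_id[s$word == struct$specific_word])
  chi2 <- chiSquareEnrichment(length(g_all), sum(de_of[g_all]),
                              length(g_spec), sum(de_of[g_spec]))
  list(chi2 = chi2, mean_BS = mean_bs)
}
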