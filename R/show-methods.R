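setMethod("show", "GenomeIndex", function(object) {
  lens <- chromosomeLengths(object)
  cat(sprintf("GenomeIndex: %d sequence(s), %d bp total\n",
              length(lens), sum(lens)))
  for (i in seq_len(min(5L, length(lens))))
    cat(sprintf("  %s: %d bp\n", names(lens)[i], lens[i]))
  if (length(lens) > 5L) cat("  ...\n")
})

setMethod("show", "GeneModelSet", function(object) {
  cat(sprintf("GeneModelSet: %d gene(s) on %d sequence(s)\n",
              length(object@genes), length(object@genome@sequences)))
})

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel %s (%s%s), %d transcript(s)\n", object@gene_id,
              object@chromosome, object@strand, length(object@transcripts)))
})

setMethod("show", "ScanUnit", function(object) {
  cat(sprintf("ScanUnit %s/%s (%s%s): R_L = %d bp over %d segment(s)\n",
              object@gene_id, object@transcript_id, object@chrom,
              object@strand, unitLength(object), nrow(object@segments)))
  if (nrow(object@segments))
    cat("  regions:", paste(object@segments$kind, collapse = " + "), "\n")
})

setMethod("show", "MotifPattern", function(object) {
  cat(sprintf("MotifPattern '%s' (M_L = %d, strand_mode = %s)\n",
              object@text, nchar(object@text), object@strand_mode))
})

setMethod("show", "MotifPWM", function(object) {
  cat(sprintf("MotifPWM: %d position(s), consensus %s\n",
              pwmLength(object), pwmConsensus(object)))
})

setMethod("show", "BackgroundModel", function(object) {
  cat("BackgroundModel:",
      paste(sprintf("%s=%.3g", names(object@freqs), object@freqs),
            collapse = " "), "\n")
})

setMethod("show", "InteractionStore", function(object) {
  e <- object@edges
  cat(sprintf("InteractionStore: %d edge(s) (%d biochemical, %d computational)\n",
              nrow(e), sum(e$evidence == "biochemical"),
              sum(e$evidence == "computational")))
})

setMethod("show", "Neighborhood", function(object) {
  cat(sprintf("Neighborhood of %s (depth %d): %d node(s), %d edge(s)\n",
              object@root, object@depth, length(object@nodes),
              nrow(object@edges)))
})

setMethod("show", "FixtureSpec", function(object) {
  cat(sprintf(paste0("FixtureSpec: seed %d, %d gene(s) on %d chromosome(s),",
                     " motif %s, %d planted site(s), de_fraction %.2f,",
                     " enrichment_odds %.2f\n"),
              object@seed, object@n_genes, object@n_chromosomes,
              object@motif, object@n_planted_sites, object@de_fraction,
              object@enrichment_odds))
})
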