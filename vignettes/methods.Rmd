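---
title: "MotifTargets: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MotifTargets: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MotifTargets)
```

This vignette is the package's own account of what it computes and why
the open design decisions were taken the way they were. The README shows
the end-to-end workflow; here we concentrate on the model.

## The region model and coordinates

Every locus is partitioned, per transcript, into six region classes: 5'
intergenic flank, 5' UTR, coding exons, introns, 3' UTR and 3' intergenic
flank. Genomic coordinates are 1-based closed intervals in the GFF3 frame;
scan-unit offsets are 0-based half-open internally; all user-facing
positions are ATG-relative signed integers with no zero (the A of the
start codon is +1, the base 5' of it is −1). The ATG-relative frame is the
*unspliced* gene-strand axis, so a position inside an intron is simply its
distance from the ATG along the chromosome, and 5'-flank positions are
negative — the convention promoter biologists use when they write "a
W-box at −250".

Introns are always derived as the gaps between consecutive exons of a
transcript and never read from GFF3 `intron` features; GFF3 dialects
disagree on whether intron features are present, and deriving them makes
the partition deterministic. Transcripts without annotated UTRs get no UTR
regions — their coding exons abut the intergenic flanks directly — and
transcripts without annotated CDS treat their exons as coding sequence,
with the transcript's 5' end standing in for the ATG.

Intergenic flanks are computed per request, not stored: they extend
outward from the transcript's outermost annotated base by the requested
length, truncated at the nearest flanking gene's *coding* sequence (its
UTR does not stop the flank) or the chromosome end. A blank length takes
the whole gap between genes. Where annotations place neighbouring loci so
close that the gap is zero or negative, the flank is empty rather than an
error — real annotations contain overlapping loci. The anchor of the flank
is configurable (`flankFrom`): the default measures from the transcript's
outermost base; `"cds"` measures from the gene's own CDS extent, which
folds the gene's own UTRs into the flank. Annotation conventions differ on
which of the two a "promoter window" means, so both are offered and the
choice is recorded in every output header.

Selected regions are concatenated without separators into a single
gene-strand-oriented scan unit (reverse-complemented for minus-strand
genes), so a motif lying across a region boundary — say the last 3 bp of
the 5' UTR and the first 4 bp of the CDS — is found and labelled with both
regions.

## Matching semantics

IUPAC degeneracy follows the standard 15-letter code. Matching is
case-insensitive on both sides. Genome `N` bases never match any pattern
letter, *including* pattern `N`: unknown sequence must not inflate site
counts, and an `N`-run would otherwise match everything. Overlapping
occurrences are all reported, and in `strandMode = "both"` a palindromic
site yields two hits, one per strand, because the results table reports
matches, not positions (the scoring layer dedupes; see below).

The production scanner delegates the inner loop to
`Biostrings::matchPattern` with a fixed subject; `scanUnitNaive()` is a
deliberately plain window-by-window loop over the allowed-sets, kept
independent of the optimized path, and the test suite checks the two are
identical on hundreds of randomized units and patterns (lengths 0–500,
patterns 1–12, `N`-containing sequence, palindromes, multi-segment
boundary configurations).

## PWM handling

A PWM is a 4 × L column-stochastic matrix. Two distinct uses must not be
conflated:

* `V_PWM` — the probability that the factor binds one concrete word: the
  product over positions of the column probability of the observed base.
  It is the raw product, not normalized to the consensus, because it is
  used as an absolute probability weight in the scores; a
  consensus-normalized variant is available behind
  `normalize_vpwm = TRUE`.
* the *scan pattern* — scanning with a PWM means scanning with the IUPAC
  pattern whose per-position allowed set is the bases with column
  probability at least `min_prob` (default 0.05). The same reduction
  defines "all the words derived from the PWM" for the Binding Score
  counts. A per-position probability floor is deterministic, cheap, and
  the threshold is recorded in output metadata. Every reported window
  carries its `V_PWM`, so no hit with positive probability inside the
  floor is silently dropped; windows below the floor at some position are
  regarded as non-sites rather than low-probability sites.

PWM files may contain probabilities (columns summing to 1) or counts
(columns summing to a common total, normalized column-wise on load).
Consensus ties break alphabetically (A < C < G < T).

## The binomial abundance model

For a locus whose scan unit has length `R_L` and a motif of length `M_L`,
the number of possible matching positions is `T = 2(R_L − M_L + 1)` — the
factor 2 counts the two strands — and the expected site count is
`B_E = M_P · T`, with `M_P` the product over motif positions of the summed
background frequencies of the allowed bases. For a concrete motif this is
the plain product of per-nucleotide frequencies; for a degenerate motif,
summing the allowed bases first makes `M_P` exactly the total probability
of the compatible words (the test suite verifies this identity by
exhaustive enumeration for short motifs). The default background is the
Arabidopsis genome composition A = T = 0.32, C = G = 0.18, overridable.

The p-value is the probability of at least `n` sites among `T`
independent Bernoulli trials with success probability `M_P`, computed via
the binomial survival function (`pbinom(..., lower.tail = FALSE)`), which
is stable for `T` up to 10⁸ and far beyond the cancellation range of the
textbook `1 − Σ` form.

Three deliberate choices:

* **`T`, `B_O` and the p-value are per-locus quantities** (the scan unit
  of the gene), not genome-wide: the results table presents per-gene
  p-values, which would all be meaningless against a genome-wide `T`.
  When several regions are selected, `T` uses the concatenated unit
  length, matching where the scan actually ran.
* **`B_O` counts distinct genomic positions**, pooling strands and
  collapsing duplicates across isoforms. The binomial model counts
  position trials and `T` already carries the strand factor; counting a
  both-strand palindromic pair as two successes at one position would
  overcount. Counting positions is slightly conservative (a palindromic
  match is one success against two counted trials) and we accept that.
  For multi-isoform loci, `T` uses the longest isoform's unit.
* **Windows are treated as independent**, ignoring overlap dependence
  between neighbouring windows and motif self-overlap. A compound-Poisson
  clump correction would change p-values for self-overlapping motifs;
  this model knowingly omits it, as the per-locus counts involved are
  small.

Significance stars bin the p-value at 0.05 / 0.01 / 0.001; the thresholds
are a presentation choice, not part of the model.

## Binding Score and enrichment test

The Binding Score of a locus sums, over its motif instances, the term
`V_PWM · B_FC_Spec · ln((B_FC_Spec/B_Tot_Spec)/(B_FC/B_Tot))`, where the
counts are genome-wide under the same scan configuration: total sites and
sites in above-threshold genes, for all pattern-derived words (`B_FC`,
`B_Tot`) and for the instance's specific word (`…_Spec`). Decisions taken
where the formulation was open:

* "Sites above the fold-change threshold" is read **site-weighted**: a
  site counts when the gene holding it is above threshold, matching the
  symbol's description as an occurrence count.
* The inner `B_FC_Spec` factor uses the **genome-wide** specific-word
  count, per the symbol definitions, so the term is the word's global
  enrichment weighted by its global above-threshold abundance.
* Any term whose inner ratio touches a zero count contributes 0 — the
  information-less limit — rather than ±∞.
* Reverse-strand instances are counted in motif orientation (their
  reverse complement), so a word and its genomic mirror are one word.

The chi-squared test (2 × 2, 1 df, no continuity correction) compares DE
frequency between genes carrying the specific word and genes carrying
**only the remaining** pattern-derived words. Keeping the two groups
disjoint avoids counting the specific-word genes on both sides; the
inclusive reading is available via `include_specific_in_all = TRUE`. When
any expected cell is zero the test is flagged as not computed rather than
reporting a degenerate statistic.

Fold changes default to the log2 scale with threshold `FCT = 1`
(two-fold), since both NGS and array pipelines commonly emit log2 ratios;
`scale = "linear"` treats a 0.25-fold gene as 4-fold down via
`max(fc, 1/fc) ≥ FCT`. Target classes: *primary* = above threshold with
at least one site in the selected regions; *secondary* = above threshold
without sites; *unchanged* otherwise; genes with sites but no expression
record are flagged and left unchanged.

## The synthetic-data generator

`generateFixture()` realizes a parametric study condition: a
background-sampled genome (i.i.d. draws from the background model) with
50 genes by default, every gene multi-exon (5' UTR 40–80 bp, 2–3 coding
exons of 60–120 bp with 60–120 bp introns, 3' UTR 30–60 bp, random
strand, inter-gene gaps 220–400 bp), 20 planted sites of a 7 bp motif
(`GGTWCAC`, chosen non-self-overlapping so occurrences cannot clump), a
30% DE fraction with log2 fold changes drawn N(±2.5, 0.5) for DE genes
and N(0, 0.25) truncated below the threshold otherwise, and an
interaction file. Everything is a deterministic function of the seed, and
re-running produces byte-identical files.

Design points worth knowing when interpreting test results:

* **Exact truth counts.** Background sequence occasionally recreates the
  motif by chance; the generator scans both orientations and resamples
  any non-planted matching window until exactly the planted occurrences
  remain. Recovery tests are therefore exact, not statistical.
* **Quota region allocation.** Site region kinds are allocated by
  largest-remainder quotas over `site_region_distribution` instead of
  i.i.d. draws, so all six kinds are represented at n = 20 and recovery
  can be checked per kind.
* **One unit per site.** Intergenic sites are planted within
  `intergenic_len` (100 bp) of their gene and gaps are at least 220 bp,
  so with matching scan flank lengths every planted site falls in exactly
  one gene's unit. (A site in a shared full-gap window is legitimately
  reported for both flanking genes; the truth table assumes the windowed
  scan.)
* **Word-specific enrichment.** `enrichment_odds` biases the planting of
  *specific-word* sites toward DE genes; sibling words plant neutrally.
  Enriching all words equally would leave the specific-vs-rest
  chi-squared at its null and the Binding Score centered at zero — the
  test contrasts the specific word against the rest, so only
  word-differential enrichment is detectable, and that is also the
  biologically meaningful signal (the factor binds its actual word).
* **Two layers, one code path.** The statistical layer (DE labels, fold
  changes, site-to-gene assignment, words) is exposed separately as
  `simulateEnrichment()`; `generateFixture()` realizes the identical
  structure as sequence files. Many-replicate calibrations use the
  statistical layer, since sequence synthesis adds nothing to a test of
  the count statistics.

What the generator does **not** emulate: realistic intron/intergenic
length distributions, nucleotide composition heterogeneity (isochores,
CpG effects), alternative isoforms (fixtures are single-isoform; isoform
handling is tested on hand-built annotations), overlapping genes, or any
dependence between expression magnitude and site count beyond the planted
odds ratio. Passing against fixtures shows the machinery is correct under
the stated model, not that the binomial or chi-squared models are
well-specified for any particular real genome.

## Calibration conditions and problem sizes

The enrichment calibration simulates 200 genes with 120 planted sites and
a 30% DE fraction — chosen so the 2 × 2 table's expected cells are in the
tens, where the 1-df chi-squared approximation without continuity
correction is trustworthy. The null condition (odds 1) runs 2,000
replicates and checks the rejection rate at α = 0.05 stays in
[0.03, 0.07]; the power condition (odds 4) runs 200 replicates and checks
the median p-value falls below 0.05 with positive mean Binding Score.
Scanner equivalence uses 500 randomized unit/pattern cases; the binomial
oracle grid covers T ≤ 200 at three match probabilities with a
direct-summation reference built from `lchoose` (log-space factors, so
tiny tails stay out of the subnormal range). The null-count check scans
1,000 background-sampled 300 bp units and compares the mean both-strand
hit count to `B_E` within three standard errors.

## Numerical and degenerate-input conventions

* A motif longer than its unit yields an empty result, not an error;
  `T = 0` in that case.
* A locus with zero observed sites gets no score report: `MS` is
  undefined at `B_O = 0` and the table reports matches.
* Requesting an intergenic flank past the chromosome start clamps to
  position 1.
* Duplicate interaction listings in either orientation collapse to one
  undirected edge with methods merged (sorted, `;`-joined); neighborhood
  expansion is breadth-first with lexicographic ordering, so outputs are
  deterministic.
* Output files carry `#` provenance headers (tool version, full
  configuration, input MD5 checksums) and fixed numeric formats (scores
  to 4 decimals, p-values in 3-significant-digit scientific notation), so
  identical inputs give byte-identical outputs.

## Known limitations

Plain windowed scanning is adequate at the intended scale (a desk-sized
genome and one motif per run); there is no index structure for repeated
scans. The binomial model's independence assumption is knowingly wrong
for self-overlapping motifs. No multiple-testing correction is applied
across loci — the per-locus p-values are descriptive, as in the classic
promoter-scanning workflow this package reimplements in library form; a
Benjamini–Hochberg step downstream of the exported table is one line of R
for users who want it.
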