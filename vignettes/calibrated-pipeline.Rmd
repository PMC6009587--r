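---
title: "Spike-in calibrated analysis of HDAC-regulated transcription"
author: "hetcal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-in calibrated analysis of HDAC-regulated transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Why calibration

Perturbations of class I/II histone deacetylases (HDACs) — for example,
treating fission yeast with trichostatin A (TSA) — can move the expression
of the majority of genes in the same direction.  Every normalization that
anchors on the target counts themselves (library size, TMM,
median-of-ratios) assumes most genes are unchanged; under a genuine global
shift that assumption rescales the shift away and can invert the sign of
the answer.  The experimental remedy is an internal standard added at a
controlled amount:

* a lysate of a second species (*S. cerevisiae*) mixed into the target
  (*S. pombe*) lysate at a fixed 50:1 ratio before library preparation,
  for RNA-seq, NET-seq and ChIP-seq; or
* ERCC synthetic RNAs added at a fixed volume per microgram of total RNA,
  for the RNA-seq used to annotate cryptic unstable transcripts (CUTs).

Reads are aligned to both genomes; reads present in both alignments are
discarded wholesale, and the surviving spike reads yield per-sample size
factors.  Everything downstream — fold changes, coverage tracks, CUT
enrichment — divides by those factors, so cross-condition comparisons are
made on the spike scale.

## Pipeline and assumptions

1. **Read preparation** (`qualityFilter`, `loadAlignments`,
   `disambiguate`, `trimToPol2`).  Reads below mean Phred 20 or shorter
   than 20 nt are dropped.  RNA-seq keeps only properly-paired primary
   alignments, merged into fragment intervals; NET-seq and ChIP-seq keep
   primary mapped single-end records.  Disambiguation is at read-id level:
   a read aligned in both genomes is removed from both, regardless of
   position or score.  NET-seq fragments are reduced to their 3′-terminal
   base — the nucleotide in the Pol II active centre — the rightmost base
   of a plus-strand fragment, the leftmost of a minus-strand one.  In
   GRanges (1-based closed) terms this is `resize(frags, 1, fix = "end")`;
   the equivalent half-open statement is that `[s, e)` maps to `e − 1` on
   plus and `s` on minus.  All conversions to on-disk conventions (GFF3
   and SAM 1-based, bedGraph 0-based half-open) are confined to the I/O
   layer and handled by rtracklayer/Rsamtools.

2. **Calibration** (`countSpike`, `spikeSizeFactors`, `chipSizeFactors`,
   `h3Normalize`).  Factors are spike counts divided by their geometric
   mean, so the factors of any comparison group multiply to 1.  The
   geometric-mean anchor is a convention choice — the upstream protocol
   specifies manual normalization without an anchor — made because it is
   symmetric across samples and keeps factors comparable between schemes.
   Scheme per assay: total unique spike reads (ChIP IP and input),
   spike ribosomal-protein-gene signal (NET-seq), ERCC signal (CUT
   RNA-seq).  ChIP factors are IP/input spike ratios: the input correction
   could in principle be a difference rather than a ratio, the source
   protocol does not say; the ratio reading is used because it makes the
   factor invariant to jointly rescaling a sample's IP and input, and the
   choice is recorded in the object's metadata.

3. **Tracks** (`makeCoverage`, `metagene`, `replicateCorrelation`,
   bedGraph I/O).  Fragment mode adds `1/s_k` per covered base; position
   mode adds `weight/s_k` at single bases, so track mass times the factor
   equals fragment-bp or read count exactly.  RNA coverage is
   strand-specific (stranded library chemistry); ChIP coverage is
   unstranded.  The H3K14ac/H3 ratio uses a pseudocount (default 1
   normalized unit) and masks positions whose H3 falls below the 5th
   percentile of nonzero H3 — masking, not inflating, because a ratio over
   vanishing H3 is noise.  The TSS metagene window is −75..+300 bp, the
   window in which H3K14ac peaks at gene 5′ ends; the same window is
   reused for gene-level acetylation summaries so that box-plot style
   comparisons and the metagene agree by construction.  Replicate QC is a
   Spearman matrix over 50-bp bins (bin size is a free parameter; 50 bp
   suits genomes of a few hundred kb).

4. **Differential expression** (`countFeatures`, `nbTest`, `bhAdjust`,
   `classifyDE`, `concordance`).  Counting is ≥1 bp overlap under a
   strand rule (sense / antisense / ignore); a fragment overlapping k
   features counts for each — union counting, the simplest rule that
   never discards signal; it slightly inflates counts at overlapping
   annotation, which the toy annotation avoids by construction.  The NB
   test takes the size factors as *given*: per-feature dispersion by
   moments on normalized counts (the Poisson term `μ·mean(1/s)` removed),
   a robust linear trend `α(μ) = a0 + a1/μ` fitted by Huber regression,
   linear shrinkage of the per-feature estimate toward the trend with
   prior weight 10 pseudo-df (at 2 + 2 replicates the residual df is 2,
   so the trend dominates — deliberate, since a df-2 moment estimate is
   essentially noise), and a Wald test of the group log-ratio with
   `Var(m_g) = Σ_j (s_j m + α s_j² m²)/ (Σ_j s_j)²`.  A prior count of
   0.5 per normalized library keeps fold changes finite at zero counts.
   This is a re-implementation in the spirit of established NB machinery,
   not a numerical clone of any package; its calibration is checked by
   simulation (null fraction of p < 0.05 within [3%, 7%] at 5,000
   features, dispersion 0.05, 2 vs 2) and against the exact conditional
   binomial in the Poisson limit.  Benjamini–Hochberg is the plain
   step-up, tested for exact equality against an independent brute-force
   implementation.  Classification: `up` iff `log2FC ≥ 1` and `q < 0.05`.
   The two-fold rule is printed upstream; the significance cut for the
   two-fold classes is not, so the CUT threshold 0.05 is reused and
   exposed as an argument.  Cross-assay concordance is the fraction of
   features called ≥2-fold in the first assay that receive the same class
   in the second.

5. **CUT annotation** (`segmentTrack`, `callCuts`, `classifyOverlap`).
   The original segmentation algorithm is specified only by citation
   upstream; hetcal uses a transparent zero-inflation-aware segmenter
   behind a small interface so an alternative can be swapped in: pooled
   per-base normalized coverage (mean across samples, all genotypes, so
   mutant-only transcripts are seen), `log2(x+1)` transform (the +1 floor
   is what keeps the log finite on the zero-inflated baseline), running
   mean of half-width 25 bp, maximal runs above threshold, sub-threshold
   gaps ≤ 50 bp merged, segments < 100 bp dropped.  Segmentation is per
   strand (the libraries are stranded; the upstream text does not state
   this explicitly).  Replicates are pooled for boundary detection and
   kept separate for testing.  Calling criteria are the printed ones and
   their boundary behaviour is enforced literally: length ≥ 200 nt
   (length exactly 200 passes), fold strictly > 2 (exactly 2 fails), BH
   q strictly < 0.05 (exactly 0.05 fails); the criteria are re-asserted
   on every returned object.  Overlap classes use the priority
   sense-mRNA > antisense-mRNA > ncRNA > intergenic.

6. **Worked numeric checks** (`prtDeletions`, `intervalLengths`,
   `atgToGenome`, `mixingRatioEstimate`).  The five deletion intervals
   tiled across the 5′ region of the *prt* lncRNA upstream of *pho1* are
   stored in the signed "ATG = 1" convention (no position 0); their
   common length, 189 bp, is exact integer arithmetic.  The sixth
   interval (−630 to −441) could not be constructed upstream and is
   excluded by construction.  The ATG-to-genome converter is unit-tested
   because an off-by-one in this convention fails silently.  The
   mixing-ratio harness reports `|unique target| / |unique spike|` with a
   Wilson interval on the spike fraction.

## What the simulator emulates — and what it does not

`simConfig()` defaults *are* the study conditions: mixing ratio 50 (the
50:1 lysate protocol), NB dispersion 0.05, planted CUTs of 250–1500 nt
stabilized 4-fold in rrp6Δ, TSA response of 70% down at 3-fold and 6% up
at 4-fold (mirroring the strong genome-wide decrease, thousands down
versus a few hundred up, that calibration reveals), 20% of TSA-responsive
genes changing at the RNA level only (invisible to NET-seq, which sets the
planted RNA/NET concordance at ~80%), and H3K14ac islands at −50..+250
around mRNA TSSs gaining 3-fold on TSA-up genes.  The two-genome reference
is gene-dense with non-overlapping features per strand, flagged
ribosomal-protein genes and ERCC-like contigs on the spike side, and one
shared 600-bp sequence cassette copied into both genomes so that a
configurable fraction of reads (default 2%) is *genuinely* ambiguous
rather than flagged as such.

Sampling is two-stage, by design: the species split
(target / spike / ambiguous) is multinomial at the expected mass ratio —
the lysate mixing ratio is a controlled physical quantity, so species
totals carry only read-sampling (binomial) error — while within-species
allocation uses gamma-weighted multinomial sampling, which makes
per-feature counts negative-binomial at the configured dispersion to a
very good approximation.  Independent per-feature NB draws would instead
overdisperse the species totals and break the binomial-error recovery of
the mixing ratio; the two-stage scheme satisfies both properties at once.
NET-seq reads are placed so that the 3′ end *is* the sampled Pol II
position; RNA-seq is properly-paired with truncated-normal fragment
lengths (mean 200, sd 40 — the fragment-length distribution after
alkaline fragmentation is not constrained by the upstream text, so it is
configurable); ChIP fragments are drawn from a piecewise-constant per-bp
intensity (uniform background, acetylation islands), with input simulated
as uniform coverage — the simplest testable null, since input structure
is not described upstream.

Not emulated: realistic sequence composition (codon bias, introns),
base-call errors (qualities are uniform Phred 40), platform chemistry
differences, alignment itself (ground-truth SAM is emitted directly, so
mapping ambiguity beyond the shared cassette does not arise).  Passing
tests therefore validate the *pipeline arithmetic and statistics* under a
faithful generative model, not robustness to alignment artefacts or
sequence-dependent bias in real libraries.

## Numerical choices and degenerate inputs

* Coverage with fractional weights can leave ±1e−12-scale residue from
  the rolling sum; values are clamped at zero and the class validator
  tolerates −1e−9.
* Spearman ties are mid-ranked (the `cor` default); a zero-variance
  sample yields `NA` against the others with a warning, never silent NaN
  propagation, and the diagonal stays 1.
* A zero spike count is a hard error naming the sample — there is no
  sensible imputation for a failed calibration.
* `bhAdjust` evaluates `m·p/rank` in exactly that order so it is
  bit-identical to the brute-force oracle.
* The Wald p is clamped to (0, 1]; identical groups give p = 1 exactly.
* Segments are deterministic given tracks; ties at the threshold resolve
  to "above" (`>=`).
* `atgToGenome` rejects position 0; interval length |end − start| is
  exact on either side of the anchor and across it.

## Problem sizes

The suite and the acceptance script run on toy genomes of 200 kb (target)
plus 70 kb (spike incl. ERCC contigs), 147 target features, libraries of
2×10^4–3×10^5 reads, and 5,000-feature count-level simulations — sizes
chosen so a complete run takes about a minute on one core while every
statistical check retains power (e.g. 84 planted down-shifted genes for
the calibration contrast, 12 planted CUTs for precision/recall).

## Known limitations

* Linear shrinkage of dispersion underestimates genuinely
  outlier-dispersed features; with 2 + 2 replicates this is the price of
  stability, and such features are anti-conservatively tested.
* Union counting double-counts fragments spanning overlapping features;
  harmless on the non-overlapping toy annotation, visible on dense real
  annotation (an alternative `unique` mode would discard multi-overlap
  fragments).
* The segmenter's threshold and smoothing are not taken from the upstream
  study (they are not printed there); defaults are exposed in
  `segmenterConfig()` and labelled accordingly.
* Concordance compares hard class labels; a soft (fold-change sign)
  variant would be less conservative near the threshold.
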