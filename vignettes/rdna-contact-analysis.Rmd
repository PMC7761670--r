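---
title: "Whole-genome 4C contact analysis for an rDNA viewpoint: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-genome 4C contact analysis for an rDNA viewpoint: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnaContacts)
```

## The analysis problem

Circular chromosome conformation capture (4C) anchored at the ribosomal
DNA cluster reports every genomic locus that contacts the nucleolus
organizer. After alignment, the data for one sample reduce to a coverage
track: genomic intervals with read counts. `rdnaContacts` takes such
tracks (two biological replicates per condition, here an untreated
control and a heat-shock treatment) and carries them through contact
calling, gene assignment, differential analysis, annotation, and the
resampling statistics that decide whether the observed patterns could
have arisen by chance.

All internal coordinates are 0-based half-open; conversions to and from
the 1-based closed conventions of GTF/GFF3/wiggle happen only inside the
readers and writers, so no off-by-one can drift through the pipeline.
Chromosome names are matched by exact string equality: silent "chr"
aliasing hides real data errors.

## Contact calling

1. **Replicate intersection.** Reads belong to the same contact when the
   replicate records overlap by at least one nucleotide. Each overlapping
   record pair yields one output record covering the *intersection* of
   the two intervals, valued at the arithmetic mean of the two replicate
   values. Records without a partner are dropped. When one record of
   replicate 1 overlaps several records of replicate 2, each pair
   produces its own output record; abutting outputs are merged only when
   their values are equal, so no averaging cascade is invented beyond the
   pairwise mean. The intersection (rather than the union) is the
   conservative choice and the natural one given that contacts are later
   treated as ±2.5 kb-resolution sites.
2. **Repeat filtering.** A record is removed iff it lies entirely inside
   a *single* repeat record (the semantics of
   `bedtools intersect -v -f 1.0`). Partial overlaps are retained
   unmodified. Union coverage by two abutting repeats does not remove a
   record.
3. **Thresholding.** Records with mean reads ≥ 100 are kept; the
   boundary is inclusive ("100 or more"). Averaged values stay real
   through this step; rounding (half-up) happens only where counts enter
   the count model.
4. **Extension.** A six-cutter 4C design resolves contacts to about
   ±2.5 kb, so each record is widened by 2,500 bp on both sides (clamped
   at chromosome ends) before gene assignment. Extended intervals may
   overlap; they are no longer a valid coverage track and are typed
   accordingly.

Gene assignment mirrors multi-overlap feature counting: an extended
contact contributes its full read value to *every* gene body it overlaps
by at least one base. Genes with ≥ 100 assigned reads form the
contact-gene list, sorted by descending reads with lexicographic
tie-breaks for determinism. Whether per-contact thresholding should
precede gene selection is left as two independent switches
(`contact_read_threshold`, `gene_read_threshold`), since analyses exist
in both styles; the default applies both at 100.

## Replicate concordance

Coverage is tiled into 50-bp bins, apportioned by overlap fraction, and
RPKM-normalized with the bait-bearing chromosome excluded from the
library-size denominator (bait-proximal mapping would otherwise dominate
the normalization; the bins themselves are kept, and a flag can drop
them from the correlation too). Pearson or Spearman coefficients are
computed on untransformed bin values; any log1p transform is treated
purely as a scatterplot rendering choice. Outlier removal drops bins
exceeding median + 200·MAD per sample — with one guard: on sparse 4C
coverage most bins are zero, the median and MAD collapse to 0, and the
rule would discard everything, so a zero MAD disables outlier removal
for that sample.

## Differential analysis

Both differential 4C contacts and differential expression restricted to
the contact-gene list use the same two-condition negative-binomial Wald
test on integer count matrices:

* **Normalization** by median-of-ratios size factors.
* **Dispersion** by per-gene method of moments on normalized counts
  within each condition, `alpha = max(0, (s^2 - mu) / mu^2)`, averaged
  over conditions (variance parameterization `mu + alpha * mu^2`). At
  the default 2-vs-2 design this raw estimate has 2 residual degrees of
  freedom and is far too noisy for a calibrated test: plugging it in
  gives a null type-I fraction near 0.18 at p < 0.05. `diff_counts`
  therefore shrinks per-gene estimates toward their across-gene mean
  with weight `df / (df + prior_df)` (default `prior_df = 10`), the
  moderation idea used throughout this field's count-model packages.
  Measured null type-I is then ≈ 0.06 and insensitive to `prior_df`
  over 5–20.
* **Wald statistic** on `log2((mu2 + eps)/(mu1 + eps))` with
  pseudo-count `eps = 0.5`, delta-method standard error
  `se^2 = (1/ln 2)^2 * sum_c (1/n_c) (1/(mu_c + eps) + alpha)`,
  two-sided normal p-values, Benjamini–Hochberg adjustment over tested
  genes. The pseudo-count appears in the SE denominator as well: a
  condition mean of exactly zero (a contact gained or lost wholesale)
  would otherwise give an infinite SE and make exactly the most
  interesting genes untestable. All-zero genes are emitted untested
  with p = padj = 1 and log2FC = 0.

This is a deliberate, testable approximation of the cited reference
workflow, not a re-implementation: the local-regression dispersion fit
and fold-change shrinkage of that workflow are out of scope, and exact
replication of its gene lists is not claimed.

## Annotation

Feature classes are assigned at the site midpoint with a fixed priority:
promoter > TTS > 5'UTR > 3'UTR > exon > intron > LTR repeat > other
repeat > intergenic — so every site receives exactly one class. Windows
are strand-aware: promoter `[TSS-1000, TSS+100)`, TTS
`[TES-100, TES+1000)` in the direction of transcription. The annotator
the study used publishes no parameter values, so these windows are
explicit configuration rather than hidden defaults.

Chromatin-state assignment uses the 50%-overlap rule: a site joins a
9-state segment class when at least half of its length lies in segments
of that state, accumulating across segments of the same state. At
fractions ≤ 0.5 two states can qualify; the larger overlap wins and ties
go to the lower label, a deterministic rule stated rather than left to
sort order.

## Resampling nulls

**Gene-list overlap.** The null spread of the overlap between two
fixed-size gene lists is estimated by repeatedly shuffling the universe
(Fisher–Yates) and taking the first *k* elements — computed as sampling
*k* without replacement, which is algorithmically identical to reading
the first *k* slots of an unbiased Fisher–Yates pass. At the study scale
(universe 17,748 names, k = 588, 100,000 shuffles) the estimated sd of
the overlap fraction is 0.007 (3 decimals), matching the hypergeometric
closed form `sd = sqrt(k p (1-p) (N-k)/(N-1)) / k` with `p = K/N`. The
closed-form *mean* of the overlap fraction at these parameters is
588/17748 ≈ 0.0331; a published mean of 0.0394 would instead correspond
to a universe of roughly 14,900 names, so only the spread — which is
consistent — is treated as the reproducible quantity. Empirical
p-values use add-one smoothing, `(1 + #{null ≥ observed}) / (n + 1)`,
and can never be zero.

**Chromatin-state enrichment.** Observed per-state site counts are
compared with counts recomputed under three segmentation shuffles:

* *(a) label shuffle* — coordinates untouched, labels permuted
  genome-wide; preserves the segmentation geometry exactly, so it is the
  default and also admits a fast path (the site–segment overlap
  structure is computed once and only labels are re-aggregated per
  shuffle).
* *(b) segment shuffle* — within each chromosome the (length, label)
  segment sequence is reordered uniformly and coordinates rebuilt
  cumulatively. The source description of this scheme ("leaves the order
  and amount of states intact") is internally contradictory with
  shuffling segments; reordering while preserving the per-chromosome
  (length, label) multiset is the reading implemented.
* *(c) coordinate-and-state shuffle* — all segments pooled genome-wide
  and dealt back by sequentially filling each chromosome's original
  total segment length. No truncation is applied: the final segment of a
  chromosome may overhang its original extent, because preserving the
  genome-wide (length, label) multiset exactly is the property the
  scheme exists for.

Per state, add-one empirical p-values for enrichment and depletion are
reported alongside a pooled two-proportion z test comparing the observed
assignment proportion with the aggregate null proportion.

## The synthetic study

The generator emulates the statistical structure the analysis assumes,
at desk scale: four 1-Mb autosome-like chromosomes plus a 0.3-Mb
bait-bearing chromosome whose distal 60 kb is the viewpoint (the rDNA
cluster sits near the X-chromosome end at full scale). All pipeline
constants (100 reads, ±2.5 kb, 50% overlap) remain meaningful at this
scale. Defaults: 200 non-overlapping genes with strands, exons and UTRs;
150 repeats; a 9-state segmentation tiling every chromosome with
log-uniform segment lengths of 1–30 kb.

Contact structure: 120 contact genes (60 retained, 20 lost, 20 gained
under heat shock, 20 up- and 20 down-regulated contacts at |log2FC| = 2),
each with 1–3 sites of ~150 bp within ±2.5 kb of the gene body, per-site
NB mean 200; 15 decoy sites planted wholly inside repeats (NB mean 300,
so they would survive thresholding if the containment filter failed);
300 sub-threshold background sites (NB mean 10) genome-wide. Replicate
concordance comes from a per-site lognormal latent factor
(`sdlog = 0.25`, unit mean) shared by all four samples, scaling the NB
mean (`alpha = 0.02`) — chosen so that binned-RPKM replicate Pearson
exceeds 0.95 while ≥ 95% of planted sites survive the 100-read
threshold; larger latent spread raises correlation but pushes weak sites
below threshold, and these defaults satisfy both. Because the factor is
shared across conditions as well, it cancels from fold changes, as
site-strength biases largely do in real 4C. Expression counts are NB
(`alpha = 0.05`, base means log-uniform 50–2,000) with 20 planted
|log2FC| = 2 genes among the contact genes.

Chromatin-state enrichment is planted by relabelling the segmentation
over each contact site: 70% of sites get state 1, the rest a uniform
other state, splitting segments at site boundaries so the annotation
keeps tiling. The truth manifest records contact genes and categories,
site coordinates and means, decoys, planted states, expression effects
and every seed.

What the generator does *not* emulate: restriction-fragment geometry and
ligation biochemistry, distance-decay of cis contacts around the bait,
mappability structure, and sequence-level effects. Passing recovery
tests therefore demonstrates that the pipeline's logic is correct under
its own model assumptions, not that real 4C libraries meet those
assumptions.

## Problem sizes and numerical choices

The test suite exercises: per-base brute-force oracles for the four
interval operations on 50 random two-chromosome genomes of ≤ 100 kb;
100 random segmentations for the three shuffle invariants; one default
synthetic study (seed 1) for end-to-end recovery with 1,000 enrichment
shuffles; 100 null runs at 200 shuffles each for enrichment
calibration; and 3 × 2,000-gene null matrices for type-I control. The
overlap null runs at the full study scale (100,000 shuffles) in a few
seconds.

Ties, rounding and degenerate inputs are decided explicitly: half-up
rounding for averaged counts entering the count model; inclusive
thresholds; lexicographic tie-breaks in gene lists; lower-label
tie-breaks in state assignment; empty tracks, all-zero genes and
bait-only coverage produce typed errors or flagged untested records
rather than silent results.

## Limitations

* The Wald test at 2 replicates per condition leans on moderated
  dispersions; its type-I control (~0.06 at nominal 0.05) is adequate
  for ranking but not exact.
* Scheme (c)'s chromosome-capacity handling is one defensible reading of
  an underspecified procedure; the overhang at chromosome ends slightly
  perturbs null assignment rates near boundaries.
* The metaprofile treats uncovered bases as missing, not zero; tracks
  that encode true zeros as gaps will read as sparser than they are.
* Feature classification is midpoint-based; sites straddling a feature
  boundary are classified by their centre only.
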