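---
title: "Mechanistic splicing-status inference: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic splicing-status inference: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The generative picture

In 3' tagged-end scRNA-seq, a captured molecule is primed by an oligo(dT)
primer either at its polyA tail or at an internal adenine repeat (A-SNR),
and the resulting cDNA is fragmented with a strong insert-length preference
of a few hundred bases. A sequenced read 2 is the 5' end of one such
fragment. `spliceprime` inverts this process: given where read 2 maps on a
transcript, every downstream priming site implies a candidate fragment, and
the product of two probabilities — the fragment-length density at the
implied length and the binding affinity of the priming window — scores how
plausible that candidate is. The spliced and unspliced forms of a gene
generally present different candidate sets (intronic A-SNRs only exist on
the unspliced form; exonic sites sit at different distances once introns are
spliced out), which is exactly the signal used to call the splicing status.

The model's assumptions, stated plainly:

* priming occurs at A-SNRs (detected as runs of >= 6 consecutive `A`s) or at
  the polyA tail, and nowhere else;
* fragment length is independent of the priming site and transcript, with
  support truncated to 1..1000 bp;
* the best (maximum-scoring) fragment is a sufficient summary — scores are
  not summed over candidate fragments;
* read 2 maps uniquely in transcript coordinates per candidate transcript;
  multi-gene ambiguity is handled by comparing per-gene maxima, not by
  reallocation.

## Components and their parameters

**spliceu reference.** Each annotated transcript contributes a spliced
record (exon concatenation) and an unspliced record (the genomic span of its
exons, key suffix `-U`). All sequences are stored mRNA-sense; all
coordinates are 0-based half-open internally, converted at the GTF boundary.

**Priming sites.** Internal sites are maximal A-runs of length >=
`min_arun` (default 6, no mismatch). Each carries a window of
`window_width` = 32 nt — the oligo(dT)/polyT length of the chemistry —
anchored at the first base of the run and right-padded with `A` beyond the
3' end. The anchor is not dictated by the biology (the primer can sit
anywhere on a long run); anchoring at the run start keeps the internal and
tail windows symmetric and is configurable. One tail site per record is
appended with an all-`A` window.

**Fragment-length model.** The empirical histogram over 1..1000 bp is
fitted with a cubic smoothing spline (`stats::smooth.spline`, penalty
`smoothing`), then clamped at zero and renormalized so the evaluator is a
valid discrete distribution. `smoothing = 0` is handled as the closed-form
interpolation limit (on the integer support the interpolating spline equals
the histogram). The default `smoothing = 1e-6` was calibrated once so the
training RMSE on the package's default synthetic generator is ~1e-4; a
smoothing value chosen "by eye" is not reproducible, a numeric default with
an override is. Lengths outside the support, and non-integer lengths, score
zero. The reference synthetic law is a discretized truncated normal with
mean 300 and sd 60 bp, matching the insert-size preference of these
libraries.

**Binding model.** A multilayer perceptron on one-hot encoded windows
(4 x 32 inputs; hidden layers 64 and 32 with rectifier activations; sigmoid
output; cross-entropy loss; mini-batch Adam, batch 256, default 12 epochs;
fully determined by one seed). The architecture is deliberately the
smallest that solves the planted-motif task cleanly. Positive training
windows pass an A-SNR pre-filter (>= 6-run with at most one mismatch) —
windows that could not plausibly have been primed are treated as label
noise and dropped. Background windows are sampled uniformly from the
genome *excluding* filter-passing windows; a purely random background would
contain primable sequence labelled negative, the false-negative noise the
pre-filter exists to avoid. 1000 examples per class are held out before
training and the held-out accuracy is stored in the model. The polyA-tail
window is assigned probability exactly 1 rather than a model prediction:
tail priming is the designed behaviour of the assay, and scoring it with a
classifier trained on internal windows would entangle the two priming
classes. A `tail_weight` multiplier (default 1, i.e. both priming classes
treated equally) exposes the tail-versus-internal preference as a tunable.

**Scorer.** For a hit at transcript position `x`, candidate sites must
start at or beyond `x + read2_len` (a fragment cannot be shorter than the
read it produced — the geometry forces this constraint) and imply
`d <= 1000`. The implied fragment ends at the A-run start for internal
sites and at the transcript 3' end for the tail; `d` is measured from `x`
to that end, consistent with the genomic-span definition used when fitting
the length model. Status calls: ambiguous when the spliced probability is
within `1e-9` of 0.5 or undefined (both scores zero — such reads are also
flagged `no_candidate` rather than dropped). Gene ties are exact
double-precision equalities of the per-gene maxima; tied reads get no gene
prediction.

## The synthetic data, and what it does not emulate

`generate_toy_reference()` builds multi-exon genes on both strands (default
20 genes, 3-5 exons of 150-400 bp, introns of 600-2500 bp) from random
sequence in which every background A- and T-homopolymer of length >= 6 is
scrubbed, then plants A-runs of 6-12 nt *in transcript sense* (genomic
T-runs on minus-strand genes) at known positions: 1.0 per kb of exon and
1.5 per kb of intron. The rates make introns modestly enriched for primable
sites, as in real pre-mRNA, while keeping exonic sites frequent enough that
spliced internally-primed fragments exist; every planted site is recorded
in a truth table.

The simulator draws (transcript, site, length) per requested
(gene, status) count, keeps fragments whose read 2 lies wholly inside one
annotated exon (rejection sampling with an attempt cap, interpreted per
(gene, status) pair so that impossible requests — e.g. no-fundamental reads
from a single-exon gene — terminate with a reported shortfall), and in
`no_fundamental` mode additionally rejects tail-primed fragments and
fragments whose read 1 shares read 2's exon. The selection effect this
rejection induces on the accepted fragment-length distribution is inherent
to the design and deliberately not corrected; on a single-site layout,
where the effect vanishes, accepted lengths reproduce the supplied law to
KS < 0.02. Fragments whose 5' end would precede the transcript start are
rejected and resampled. The substitution error model is i.i.d. uniform
per base — it does not emulate Illumina quality profiles, PCR duplication,
or UMI/barcode structure.

Passing tests on this generator demonstrate parameter recovery under the
model's own generative assumptions: planted motifs are sharp, genes do not
overlap (unless constructed to), expression is uniform across genes, and
mapping is emulated by coordinate projection rather than sequence
alignment. Real data adds mapping error, soft-clipping, non-uniform
priming chemistry, and annotation incompleteness that these tests do not
probe.

## Ground-truth labelling

The labeller classifies paired alignments whose read 2 is inside an
*annotated* exon (containment only in the unspliced span means read 2 is
intronic and by itself determinative, so the pair is skipped). Transcript
compatibility is explicit: every alignment block must map inside the
record's exon structure and the mapped pieces must form one contiguous
transcript interval, so alignment gaps must coincide exactly with the
record's introns. Pair compatibility (`T_pe`) additionally requires read 2
upstream of read 1 and an implied fragment length of at most `max_insert`
(default 1000, the fragment-length support). This cap is load-bearing:
without it the unspliced record, whose span contains any intra-genic pair,
would join every triple intersection and the all-spliced condition of the
e∧e′ rule could never hold. With it, the rule's >1000 nt exon-distance
guard and the cap are two sides of the same coin — a pair whose exons are
farther apart than the cap cannot be explained unspliced, and a pair whose
exons are closer (a short intron the fragment could span entirely) is left
unlabelled rather than guessed. The exon distance is measured gap-wise
(end of the 5'-most exon to start of the 3'-most). The e·e′ rule carries
no distance guard. Reads failing every rule are emitted as `skipped` with
a reason so evaluation denominators stay auditable. On clean
no-fundamental simulated data every emitted label equals the generative
truth; short-intron spliced fragments are skipped, not mislabelled.

## Evaluation

ROC/AUC takes spliced as the positive class (AUC is symmetric, so this is
presentational). The AUC is the rank (Mann-Whitney) statistic — equal to
the trapezoid area under the threshold-sweep curve — with tied pairs given
half credit; the half-credit convention is what makes the constant
baselines sit at exactly 0.5. Ambiguous predictions are excluded from the
ROC and reported as a separate count. The three baselines are constant 1,
constant 0, and class-conditional uniform scores shuffled across reads.
The multi-gene report excludes exact ties from the accuracy denominator
and reports them as a tie fraction.

## Problem sizes

The shipped tests and the acceptance script use: 20-gene references;
100 000 fragment lengths per spline sample; 20 000 windows per binding
class with 1000 held out per class; ~10 000 simulated reads per evaluation
set (5 000+ after no-fundamental filtering); 50 000 draws for the
distribution-fidelity check; 1000-read brute-force equivalence checks.
These sizes give stable estimates (binomial noise on an AUC from 5 000
reads is ~0.01) while a full run stays around a minute.

## Known limitations

* No aggregation of evidence across fragments of one UMI, and no
  EM-style reallocation of multi-gene reads; per-read calls only.
* Fragments longer than 1000 bp are outside the model by construction;
  spliced fragments whose paired reads straddle a long intron are likewise
  invisible to the length model's training contract.
* The binding model sees sequence only — no thermodynamics, no RNA
  structure, and no transfer across window widths.
* The scorer's max-only aggregation ignores the number of candidate
  fragments; a sum or expectation is a natural variant not implemented
  here.
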