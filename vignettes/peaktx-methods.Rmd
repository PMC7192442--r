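---
title: "Classifying open chromatin regions by nascent transcription: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying open chromatin regions by nascent transcription: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

ATAC-seq measures chromatin accessibility cheaply and from few cells, but
accessibility is not transcription: only a fraction of open chromatin
regions (OCRs) harbor RNA polymerase activity.  Nascent run-on assays
(GRO-seq/PRO-seq) measure that activity directly but are laborious and
expensive.  `peaktx` asks how much of the nascent signal is already latent
in ATAC-seq: it trains a classifier that, given only an OCR's ATAC coverage
and its underlying genomic sequence, predicts whether the OCR overlaps a
region of active or bidirectional transcription called from matched nascent
data.

The classification unit is the OCR: the union of replicate MACS2 peak
intervals for one cell type.  An OCR is labeled *positive* when its
interval overlaps, by at least one base, an active-transcription segment
(FStitch-style calls) or a bidirectional-transcript call (Tfit-style
calls), both consumed as BED input; otherwise *negative*.  On real data
roughly 29% of OCRs come out positive, so the synthetic generator plants
that prevalence by default.

## Coordinates and corpus construction

All on-disk formats (BED, narrowPeak, bedGraph) are 0-based half-open; in
memory every interval lives in a `GRanges` (1-based closed), converted at
each file boundary.  We chose the Bioconductor container over raw 0-based
arithmetic because `GenomicRanges`/`IRanges` are the field's standard
interval algebra; overlap semantics are unaffected — an overlap is an
intersection of at least 1 bp, and intervals that merely touch do not
overlap under either convention.

Corpus construction per cell type:

1. blacklist filtering drops any replicate peak overlapping an excluded
   region (whole-record removal, before the union — with whole-record drops
   the order only matters if a blacklist region bridges two peaks);
2. replicate peaks are unioned into disjoint OCR intervals;
3. each replicate's coverage is normalized to reads per million using its
   declared total mapped reads, then the replicates are averaged per
   nucleotide with a fixed denominator (a replicate with no coverage at a
   position contributes zero, it is not skipped);
4. every OCR gets a fixed 1 kbp evaluation window centered on its midpoint
   (`floor((start+end)/2)` in 0-based coordinates; floor keeps the rule
   deterministic and a 1 bp shift is immaterial at this width).  Windows
   are centered on the combined interval, not on any single replicate's
   summit, because the union destroys summit provenance.  Near-origin
   windows are shifted right to keep the width; windows past a contig end
   are padded downstream.

Labels and TSS flags are computed against the OCR interval, not the
window: the window exists to give the model flanking context, the label
belongs to the peak.

## The hybrid encoding

Each window becomes a pair of parallel length-1000 vectors: the token
index of the reference base at each position (a 16-symbol vocabulary:
one padding token plus the 15 IUPAC codes, case-folded, with non-IUPAC
characters mapped to `N`) and the per-million-normalized ATAC depth at
that position.  Positions past the contig end get the padding token and
zero signal.  The signal is used raw: per-million normalization is the
only transform, with no log or per-window rescaling, keeping the
magnitude information that distinguishes strong from weak peaks.

Sequence is always read from the plus strand.  We add no
reverse-complement augmentation because the recurrent layer is
bidirectional — reading the window in both directions is the model's own
mechanism for orientation invariance.

## The classifier

The per-position input is the learned embedding of the base (dimension
50, trained jointly with the classifier from random initialization)
concatenated with the scalar signal, i.e. 51 features per position.  The
51 rather than 50 total is a deliberate resolution of an ambiguity in how
the stacked representation is counted; the embedding dimension itself is
the tuned value 50.  A gated recurrent unit (GRU) layer runs over the
1000 positions in each direction with 100 hidden units per direction;
the final forward and reverse states are concatenated (200 features),
passed through dropout (rate 0.1 — applied at this single point so the
parameter has one meaning) and a sigmoid output unit.

Training minimizes binary cross-entropy with Adam at learning rate 1e-4.
Embedding 50, hidden 100, dropout 0.1 and learning rate 1e-4 are the
selected values from a grid over embeddings {15, 50, 100}, dropout
{0.1, 0.2, 0.3}, learning rates {0.001, 0.0005, 0.0001} and hidden sizes
{100, 200, 350, 500}; all remain settable in `model_config()`.  The
epoch cap and early stopping on validation AUC (patience 5; training
also stops once validation ranking is perfect, since AUC cannot improve
further) are field-standard defaults, exposed in the same place.  No
class weighting is applied despite the ~29% prevalence; weighted F1 is
the reported metric instead.

Two defaults deserve their rationale.  *Initialization* follows Keras
GRU conventions — Glorot-uniform input weights, orthogonal recurrent
weights, zero biases — plus a +1 bias on the update gate.  Orthogonal
recurrence preserves state norm across the 1000 positions and the carry
bias starts the network remembering rather than forgetting; without
both, gradients from mid-window positions cannot reach the final-state
readout and learning at the tuned rate of 1e-4 is impractically slow.
*Batch size* defaults to 16: on corpora of a few thousand windows,
larger batches leave Adam too few updates per epoch at that learning
rate, while 16 converges within a handful of epochs at essentially the
same wall time per epoch.

The implementation is a from-scratch bidirectional GRU in
RcppArmadillo, in single precision, with one seeded Mersenne Twister
driving initialization, shuffling and dropout, so a fixed
`model_config(seed=)` reproduces training bit for bit on the same build.
Two numerical choices matter: gate activations use a polynomial
approximation of `exp` (relative error ~1e-7), and the floating-point
environment flushes subnormals to zero during training — backpropagation
through 1000 timesteps otherwise drives gradient magnitudes below the
normalized float range, where they carry no information but make BLAS
calls dramatically slower.  Predictions are batch-size independent to
within float round-off (~1e-7).

### The baseline

The deliberately naive reference classifier ignores shape and sequence
entirely: fit Gaussian kernel density estimates (Scott's rule bandwidth,
`sd * n^(-1/5)`) to the mean window signal of training positives and
negatives, score an OCR by the odds ratio `(f_pos + eps)/(f_neg + eps)`
with `eps = 1e-12`, and call positive when the ratio exceeds 1 (ties go
to the majority negative class).  Its evaluation uses a seeded uniform
random 10% OCR hold-out, unstratified.

## Leakage-free evaluation (LOOT)

Cell-type generalization is measured with leave-one-out training: hold
one cell type out entirely, train on chromosomes chr1–chr11 of every
other cell type except a dedicated validation cell type, validate on the
validation cell type's chr1–chr11 (its remaining OCRs are discarded), and
test on the held-out cell type's chr12–chr22, chrX, chrY.  Because OCRs
at the same locus recur across cell types, splitting by chromosome as
well as by cell type guarantees no test window overlaps any training
window; the test suite re-checks this with a brute-force all-pairs
interval scan.  Chromosome matching is exact-string against the
configured list; anything else (chrM, scaffolds) is dropped at read time
with a logged count.

Metrics: ROC-AUC computed as the Mann–Whitney concordance probability
(ties count one half), and weighted F1 — per-class F1 averaged with
class-support weights — at a probability threshold of 0.5 (the threshold
is configurable; AUC is threshold-free).  Error analysis partitions the
test set into TP/TN/FP/FN and reports per-class mean-signal histograms
and per-class meta-profiles (position-wise mean signal over the 1 kbp
windows, strand-separated for nascent coverage).

## The synthetic data generator

`synthetic_config()` defaults define the reference study conditions used
by the tests and the acceptance script: a 23-contig genome (chr1–chr22
plus chrX, 200 kb each — chrY is omitted from the default synthetic
genome for size and is configurable), four cell types (three for
training/testing, one for validation) with ~2,000 OCRs each, and 29%
positive prevalence.  OCR loci sit on a per-chromosome lattice with
jittered centers shared across cell types; each cell type possesses each
locus with probability 0.8, so loci are shared by varying numbers of
cell types (exercising the sharing analysis).  Label, motif and TSS
status are drawn at the locus level, so shared loci agree across cell
types.

The generator plants three recoverable signals that mirror what the
classifier exploits on real data:

* **width** — positive ATAC bumps are Gaussian with sd 150 bp versus
  60 bp for negatives (transcribed OCRs are wider);
* **sequence** — a fixed 8-mer motif written into the genome at 80% of
  positive centers (a literal motif, not a PWM: the simplest recoverable
  sequence signal);
* **bidirectionality** — strand-separated nascent bumps (sd 80 bp) offset
  ±120 bp from positive centers, plus-strand downstream and minus-strand
  upstream, reproducing the bidirectional meta-gene shape.

Amplitudes default to 50 (positive) and 30 (negative) raw reads with 20%
lognormal replicate jitter over a Poisson background of 0.1 reads/bp,
with declared library sizes near 10 million so normalized depths land in
a realistic reads-per-million range.  Transcription-call BEDs cover
exactly the positive OCR intervals; their boundary jitter defaults to 0
so label recovery through the full ingestion path is exact, and can be
raised to exercise labeling robustness.  Minus-strand nascent coverage is
written with negative values, exercising the sign-convention flag in the
bedGraph reader (the same data could equally be stored as a separate
positive-valued file; both are supported).

What the generator does *not* emulate: Tn5 insertion chemistry and
fragment-level read structure, realistic base composition or repeats,
copy-number and mappability artifacts, or disagreement between the two
transcription callers.  Passing the end-to-end tests therefore shows the
pipeline is correct and the model can recover planted width/sequence/
amplitude structure — it does not certify real-data performance, which
in the original setting varies substantially with data quality.

## Problem sizes and reproducibility

The bundled checks run the full pipeline at the default conditions
(~8,000 OCRs across four cell types; ~1,900 training windows after the
LOOT split) with training capped at 10 epochs and early stopping at
patience 3, which recovers the planted signal comfortably; unit tests use
a structurally identical dataset scaled to 14 × 30 kb contigs and ~120
OCRs per cell type.  `scripts/acceptance.R` reruns generation, corpus
construction, LOOT training, the permuted-label null control, the KDE
baseline, the accessibility-vs-transcription correlation and the
meta-peak width ratio from scratch, seeded from its `--seed` argument.

## Known limitations

* Training the GRU on real-genome scale corpora (hundreds of thousands of
  OCRs) is CPU-bound; the implementation is tuned but single-threaded.
* The embedding is trained jointly with the classifier; pre-training it
  separately on peak sequences is a plausible variant we did not adopt
  (joint training is simpler and sufficient for the planted signals).
* `sharing_categories()` reports raw per-OCR share counts and leaves the
  definition of "common" denominators to the caller.
* The KDE baseline assumes continuous mean signals; heavily discretized
  signals would make Scott's rule bandwidths unreliable.
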