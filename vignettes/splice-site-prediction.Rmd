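---
title: "Splice-site prediction with a convolutional network and hard-negative mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splice-site prediction with a convolutional network and hard-negative mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Donor sites (exon–intron junctions) and acceptor sites (intron–exon
junctions) are the anchors of gene structure. Almost all introns start with
`GT` and end with `AG`, but the converse fails in both directions: these
dimers are everywhere in genomic background, and a small fraction of real
introns use other dimers (GC–AG, AT–AC). Tools that first harvest all
GT/AG positions and then classify them inherit both problems — floods of
false positives and structural blindness to non-canonical junctions.

`splicescan` takes the direct, *ab initio* route: a three-class classifier
(donor / acceptor / non-splice-site) over fixed-length windows of raw
sequence, applied at every position of a long sequence by a sliding
window. A window is positive only when the junction sits exactly in its
middle, so calls are position-exact.

## Coordinates and windows

One convention is used everywhere: coordinates are 1-based; the *boundary*
of a junction is the last base before it, so the junction lies between
`boundary` and `boundary + 1`. For a window of even length $L$ centered on
a boundary $b$, the window covers $[b - L/2 + 1,\; b + L/2]$ and the
junction falls between window positions $L/2$ and $L/2 + 1$ (between 200
and 201 for $L = 400$). A donor is canonical iff the genome has `GT` at
$(b+1, b+2)$; an acceptor iff `AG` at $(b-1, b)$.

From a GTF annotation, every transcript with $k \ge 2$ exons (sorted by
start) contributes donors at the ends of exons $1..k-1$ and acceptors at
`start − 1` of exons $2..k$. Transcript-terminal boundaries (first exon
start, last exon end) are transcription start/termination sites, not
splice junctions, and are excluded — the underlying report does not state
its choice here, so we made the biologically defensible one. Sites shared
by alternative transcripts are collapsed. Only forward-strand transcripts
are processed by default; reverse-strand handling (mirrored roles,
reverse-complement dimers) is behind `include_reverse = TRUE`.

## The model

The network (`model_spec()`) is deliberately small:

* one 1-D convolution over the one-hot $L \times 4$ input — 50 kernels of
  width 9, stride 1, zero ("same") padding so the feature map stays
  $L \times 50$, then ReLU;
* flatten, a fully connected layer of 100 units with ReLU;
* dropout masking 30% of those units during training;
* a fully connected softmax output with 3 units (2 for the filter
  variants).

One-hot encoding maps `A,C,G,T` to the unit vectors and `N` to all zeros.
At $L = 400$ the model has exactly 2,002,253 trainable parameters
(`count_parameters()` gives the closed form; the built model is asserted
against it). Training (`train_config()`) is minibatch Adam at learning
rate $10^{-4}$, cross-entropy loss, 40 epochs, batch size 50 — no early
stopping and no schedule; the validation split is monitoring only.

Choices the architecture description leaves open, and what we did:

* **ReLU after the convolution** — applied (conventional); disable with
  `conv_relu = FALSE`.
* **Weight initialization** — Glorot-uniform, biases zero, from a single
  integer seed that also drives shuffling and dropout.
* **Dropout** — inverted dropout (activations scaled by $1/0.7$ at train
  time), so inference needs no rescaling and is deterministic.
* **Backend determinism** — the compiled core is single-threaded per call;
  repeated predictions are bitwise identical. BLAS summation order may
  differ between differently-shaped batches at the $10^{-15}$ level, which
  is why batch-invariance is asserted only up to that tolerance.

## Dataset construction

Positives are windows centered on annotated boundaries; the initial
negatives are windows centered at `floor((b_i + b_{i+1}) / 2)` for
adjacent annotated boundaries on the same sequence (midpoints that collide
with a boundary are excluded). Windows that would overrun a sequence end
are skipped, never padded — the model should never see fabricated context.
`build_initial_dataset()` samples `n_per_class` windows per class without
replacement, deterministically per seed.

Because almost every drawn positive is canonical, the positive set is then
rebalanced (`rebalance_positive_set()`) to a 10:1 canonical:non-canonical
ratio per positive class: all non-canonical windows are kept (optionally
capped) and canonical windows are subsampled to exactly ten times that
count. Subsampling canonical windows is the default because it introduces
no duplicated training rows; oversampling non-canonical windows with
replacement is available behind a flag. Splits are stratified by label:
10% test, then 20% of the remainder for validation.

## Hard-negative mining

A model trained on midpoint negatives collapses on real sequence: any
centered GT/AG tends to fire. The reconstruction loop
(`iterative_reconstruction()`) attacks this directly. Per iteration:

1. retrain from fresh weights on 90% of the current dataset (the other
   10% measures test accuracy on the current distribution);
2. scan one randomly chosen annotated gene; every position whose argmax
   class is donor/acceptor but is not an annotated boundary of that type
   becomes a new `non_splice` window (de-duplicated against the existing
   negatives);
3. measure the false-positive count on a gene region set aside in advance,
   which never contributes training windows.

Positives never change; negatives grow monotonically. "The FP count stops
decreasing" is operationalized as a patience window: stop after `patience`
(default 3) consecutive iterations that fail to undercut the best count
seen so far by more than `min_relative_decrease` (default 0). Fresh
re-initialization per iteration avoids dragging optimizer state across a
changing dataset; warm starting is a flag. Retraining is unweighted by
default (a per-class weight vector is available) since no reweighting is
part of the recipe.

Mined windows are labeled by center position with `match_tolerance = 0`:
a position one nucleotide off a true boundary *is* a false positive under
the center convention, and mining it is precisely what teaches the model
positional precision.

## Scanning, filtering, evaluation

`scan_sequence()` classifies every step-strided position whose window
fits, and is by construction equal to classifying each extracted window
independently (a property the tests assert exactly). The default
`min_score = 0` means argmax calls. Two optional binary filters
(`train_binary_filters()`) — same architecture, 2-unit output — separate
each positive class from its mined false positives and can veto calls
(`filter_calls()`, threshold 0.5); filtering never adds calls nor moves
boundaries.

Window-level evaluation reports accuracy plus one-vs-rest recall
$TP/(TP+FN)$, precision $TP/(TP+FP)$, their harmonic-mean F1, and
threshold-sweep ROC/PR curves with trapezoidal AUC, for donor and
acceptor separately. Localization on long sequences uses
`fp_at_recall()`: sweep the call threshold from high to low and report the
false-positive count at the most stringent threshold whose recall of
annotated sites reaches the target (1.0 and 0.8 are the conventional
targets); unreachable targets are reported as unattainable rather than 0.
Matching is position-exact by default (tolerance configurable); the
combined donor-and-acceptor count sums the per-type counts at each type's
own threshold.

## Attribution

Per-nucleotide contribution scores use gradient × input against an
all-zero reference, on the *pre-softmax* logit of the target class (the
softmax saturates and flattens gradients). For ReLU networks with a zero
baseline this equals the rescale-rule backpropagation of
reference-based attribution methods wherever no unit changes activation
state between reference and input; in the affine regime the scores sum
exactly to `logit(x) − logit(0)`, a property the tests verify. Profiles
(`average_profile()`) average the per-position channel sums over a window
set, restricted to the junction ± 10 nt (20 positions); `logo_matrix()`
reports column frequencies (N excluded per column) and information
content $2 + \sum_c p_c \log_2 p_c$ bits.

## The simulator

`simulate_genome()` emits a forward-strand, single-chromosome genome of
left-to-right genes with known structure, plus matching GTF and a
ground-truth site table that is definitionally consistent with extraction
from the emitted files (and tested as such across seeds, through the
files). Its ingredients:

* exon/intron/intergenic lengths from configurable distributions
  (log-normal defaults: exons ~120 nt, introns ~300 nt);
* background sequence from a configurable composition (default mildly
  AT-rich, 30/20/20/30);
* donor motifs written across each junction from a 9-column position
  probability matrix (exon −3..−1, intron +1..+6, `GT` fixed) resembling
  the textbook `MAG|GTRAGT` consensus, and acceptor motifs from a
  15-column matrix (intron −14..−1 plus one exonic base, `AG` fixed,
  pyrimidine-rich tract). The PWM values are hand-set and fixed in code —
  no published matrix is being reproduced, they only need to carry
  learnable signal;
* with probability `non_canonical_fraction`, an intron becomes GC–AG or
  AT–AC (both ends switched consistently), so non-canonical donors are
  about twice as frequent as non-canonical acceptors;
* `decoy_rate` plants dimer-bearing pseudo-motifs (the PWM flattened
  halfway toward uniform, consensus dimer kept) in intron/intergenic
  interiors. Without decoys the negative class is nearly trivial; with
  them the mining loop has genuine hard negatives to harvest;
* `alt_splicing` adds an exon-skipping second transcript per gene to
  exercise site de-duplication.

What the simulator does **not** emulate: chromatin or composition
heterogeneity (isochores), realistic human intron length tails, branch
points, overlapping genes, reverse-strand genes, sequencing N runs.
Passing the end-to-end checks therefore demonstrates that the machinery —
dataset construction, optimization, mining, scanning, evaluation — works
as specified on a learnable genome; it does not certify real-genome
accuracy figures.

## Study conditions and problem sizes

The packaged end-to-end checks and `scripts/acceptance.R` use two
simulations chosen as this package's own working scale:

* a ~210 kb genome of 40 genes × 27 exons (shorter exons/introns than the
  defaults), decoys on (1/kb), non-canonical fraction 1/11 — so that the
  10:1 rebalance sits at the composition's natural ratio; window length
  100; 1000 windows per class; 20 epochs. The set-aside gene is the one
  carrying the most planted non-canonical sites, so the recovery statistic
  has support; recovery is checked with the rebalanced-trained model
  (mining deliberately makes calling more conservative — non-canonical
  sensitivity is the rebalance's contribution, and early models are the
  sensitive ones);
* a sized-up genome (11 exons per gene, 16% non-canonical introns, ≥14,500
  junctions per type) for the construction counts at the published sizes:
  10,000 windows per class initially, and a rebalanced positive set capped
  at 1,000 non-canonical windows per class — hence exactly
  10 × 1000 + 1000 = 11,000 positives per class, 22,000 in total. The 16%
  intron rate makes ≥1,000 non-canonical *acceptor* draws a
  high-probability event (acceptors acquire non-canonical dimers only
  from AT–AC introns, i.e. at half the intron rate).

## Known limitations

* Reverse-strand scanning is not symmetric: the model is trained on
  forward-strand windows only; `include_reverse` affects site extraction,
  not the scanner.
* The iteration loop retrains from scratch each round; with many
  iterations this dominates runtime.
* Gradient × input is a first-order attribution; it is exact only in the
  affine regime and can understate saturated features.
* The fp-at-recall sweep uses only observed call scores as thresholds;
  with very coarse score distributions the reported threshold is the
  coarsest attaining the target.
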