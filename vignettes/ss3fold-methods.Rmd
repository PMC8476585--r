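---
title: "Alignment-free fold classification from secondary structure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free fold classification from secondary structure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Large enzyme superfamilies such as the glycosyltransferases (GTs) conserve
their three-dimensional fold far more strongly than their primary sequence.
Across the GT families only a handful of folds are known — the
single-Rossmann GT-A, the dual-Rossmann GT-B, the multi-transmembrane GT-C
and the lysozyme-like fold of the peptidoglycan polymerases — yet sequences
from different families often share no detectable similarity, so
alignment-based classification does not scale to the whole superfamily.

`ss3fold` classifies folds from the *secondary structure* alone: each
protein enters as a per-residue string over H (helix), E (strand), C
(coil/loop), as produced by any three-state predictor. On top of the
classifier the package provides per-residue interpretation maps, embedding
clustering, and an open-set detector that flags families whose secondary
structure cannot be reconstructed from any known fold — candidates for
genuinely novel folds.

## Input representation

A sequence of length $n$ is one-hot encoded into an $L_{max} \times 3$
matrix in fixed channel order (H, E, C); rows beyond $n$ are padding
$[0,0,0]$ and a boolean pad mask marks real residues. The channel order is
recorded in model metadata so checkpoints are self-describing. Padding is
appended at the end only; every masked operation in the network (bridge
pooling, global max pooling, reconstruction error) uses the pad mask, so
the two conventions "pad at the end" and "pad symmetrically" give identical
results by construction.

The fixed width is chosen from the data as $\mu + 3\sigma$ of the length
distribution (rounded half-up; `length_cutoff()`), the value used for the
reference GT dataset being 798. Sequences longer than the cutoff must be
trimmed to their domain of interest (`trim_to_domain()`, 1-based inclusive
coordinates as in structure tools); encoding never truncates silently.

Only hard three-state calls are accepted. Predictors also emit per-class
probabilities; a probability-matrix input would be a natural extension but
is deliberately out of scope so that the input contract stays trivial to
verify.

## Class balancing by coil mutation

Family sizes in real datasets are badly skewed. Training partitions are
balanced by the coil-mutation augmentation: a copy of a parent sequence has
$k = \max(1, \lfloor 0.05\,n \rfloor)$ positions, drawn uniformly without
replacement, set to C. A draw that changes nothing (all drawn positions
already C) is retried; an all-coil sequence is un-augmentable and is an
error rather than an endless loop. The floor-plus-minimum rule makes the
"at least one change" contract hold for arbitrarily short sequences.
Families above the target (default 2000) are uniformly subsampled. (A
divergence-aware selection of representatives for very large families is
sometimes preferred, but no standard algorithm exists for it; uniform
sampling is the assumption-free choice, and a user-supplied selector can
replace it.)
Augmentation is applied to training partitions only, never to evaluation
splits, and one balanced set is generated once per training partition
(re-augmenting per epoch is a config switch left off by default).

## The classifier

The network has two convolutional blocks and two heads:

* **Block 1** — three 1-D convolution layers (kernel sizes 3/7/15, filters
  256/512/512 by default), each followed by batch normalization, ReLU and
  an attention refinement. All convolutions are stride 1 with same padding
  and there is **no pooling anywhere in Block 1**, so every activation maps
  to a residue. (The reference architecture's description is internally
  inconsistent on this point — one passage lists a pooling layer, another
  rules pooling out for the first three layers; spatial interpretability
  requires the pooling-free reading, which is the one implemented.)
* **Bridge** — masked local average pooling (window 4, stride 4). A single
  *global* average pooling here would leave nothing for further
  convolutions to operate on, so the bridge is read as local downsampling.
* **Block 2** — three more convolution blocks (kernel 3, batch norm, ReLU,
  masked local max pooling of window 2), ended by masked per-channel
  *global* max pooling. The resulting fixed-length vector — one value per
  channel regardless of sequence length — is the sequence **embedding**.
* **Heads** — a shared dropout (rate 0.5) on the embedding feeds two fully
  connected softmax heads, one over folds and one over families. The loss
  is the unweighted sum of the two cross-entropies (no weighting is given
  in the reference description, and the tasks are on comparable scales).

Training uses Adam with learning rate $10^{-4}$ and L2 weight decay
$10^{-5}$ (the reference settings; scaled-down study sizes use a larger
rate, see below), with early stopping on validation fold accuracy
(patience 10 by default — no epoch count is published). All randomness
(initialization, shuffling, dropout) flows through one integer seed, so a
fixed seed reproduces training bit-for-bit in a single-threaded run.

### The attention refinement

Each Block 1 layer ends in a two-stage refinement: a *channel* gate
followed by a *spatial* gate. The spatial stage is a small convolution
(kernel 7) over the channel-average and channel-maximum maps with a sigmoid
gate per position. The channel stage is a two-layer bottleneck MLP applied
**position-wise** to each residue's channel vector.

The position-wise choice is deliberate and is the one place this
implementation departs from the standard convolutional-block-attention
recipe, which pools the channel descriptor over the whole sequence. A
sequence-global channel gate lets class identity reach every position
through the gate itself: the classifier then learns a delocalized shortcut
(planted-motif activation maps showed no localization at all), and
zeroing the input outside a window
changes activations arbitrarily far away. With the position-wise gate,
every Block 1 operation has a finite receptive field, the planted-motif
test localizes sharply, and activation maps remain attributable to
residues — which is the reason the attention exists in this architecture.

### Degenerate inputs

A fully padded input produces a zero embedding and finite logits (masked
max pooling over an empty set is defined as 0). Batch-norm uses running
statistics at inference, so predictions are deterministic and independent
of batch composition. Encoding at a width different from the model's
recorded `L_max` is an error for `predict()`; `embed_sequences()` accepts a
wider width, and embeddings are bitwise invariant to extra padding (this is
tested).

## Interpretation

### Grad-CAM

Per-residue class activation maps are taken at the post-attention feature
maps of any Block 1 layer: the per-channel weights are the spatial average
(over real residues) of the gradient of the target class's **contrastive
score** — its logit minus the mean of the other logits — and the map is the
rectified weighted channel sum, min-max normalized over real residues
(maximum exactly 1 unless the rectified map is identically zero). The
contrastive score, rather than the raw logit, is used because softmax
probabilities are invariant to components shared by all logits; those
shared components otherwise dominate the map and light up every strongly
activated region regardless of class relevance. Because Block 1 is
stride 1 throughout, no upsampling is needed.

Localization is validated by a planted-motif experiment: two archetypes
identical except for one strand run, with rigid element lengths so motif
positions are known exactly. Enrichment of layer-2 CAM over the motif is
assessed by a one-sided permutation test of position exchangeability
*within* each sequence (the across-sequence mean difference as the
statistic) — permuting the averaged profile instead would leave the null
dominated by the profile's own spatial autocorrelation and waste most of
the test's power.

Family-level maps average per-residue values across an external alignment
column map (`family_cam()`); unaligned residues are ignored, empty columns
carry NA, and the per-column consensus state is the majority state.

### Embedding clustering

`umap_scan()` reproduces the published reproducibility protocol: 2-D UMAP
for every combination of `n_neighbors` (5, 15, 20) and `min_dist`
(0.001, 0.01, 0.1, 0.5), three repeats each, with per-projection seeds
derived deterministically from one master seed. The backend is the Python
`umap-learn` implementation via a subprocess (there is no maintained R
implementation in this package's dependency footprint); `method = "pca"`
is a deterministic fallback. Projections are clustered with Gaussian
mixtures (`gmm_cluster()`, via mclust): the component count is chosen by
BIC over a configured range — the published analysis fixed counts per fold
manually, which does not transfer to new data — and each point's score is
its log-density under the fitted mixture, with points below a cutoff
(default: the 1st percentile of scores) left unassigned. Clusterings are
reported per projection; no consensus across the scan is computed, matching
how the scan is meant to be inspected.

## Open-set recognition

### Masked reconstruction error

The autoencoder reuses Block 1 of the trained classifier as a **frozen**
encoder (bit-identity of the encoder weights before and after decoder
training is asserted, not assumed). The decoder mirrors Block 1's kernels
in reverse (15/7/3) as stride-1 transposed convolutions with instance
normalization (per sequence and channel, over real residues), ReLU, and a
linear three-channel output. Only the decoder is trained, by minimizing

$$\mathrm{RE}(Y, \hat Y) \;=\; \frac{1}{n}\sum_{t\,\in\,\text{real}}
\lVert Y_t - \hat Y_t \rVert_2^2,$$

the squared error summed over the three channels and averaged over the $n$
real residues only. Channel errors are summed, not averaged, so one
mispredicted one-hot position contributes at most 2 — the scale on which
the published thresholds live; the convention is recorded in calibration
metadata so thresholds are never mixed across conventions. With no padding
this reduces exactly to the plain mean squared error (tested on random
pairs).

### Extreme-value calibration

Reconstruction errors of training sequences are small and right-skewed; a
type-I extreme value (Gumbel) distribution is fitted by maximum likelihood
and the fitted 0.95 and 0.99 quantiles are taken as the 95% and 99%
confidence upper limits, with the novelty threshold at their midpoint. The
published values on the reference GT data are 0.107 and 0.147, midpoint
0.127. "95% CI" is read as a one-sided fitted quantile — the published use
compares single values against *upper limits*; a two-sided reading
(0.975/0.995 quantiles) is available as a switch. On any new dataset all
thresholds are recomputed by the same procedure; the published numbers are
defaults for documentation, never hard-coded decisions.

### Fold assignment score

One autoencoder per known cluster (nine for the reference GT data: two
GT-A, three GT-B, three GT-C, one GT-lyso) yields, for a query family $a$
against cluster $b$:

$$\mathrm{FAS}_{ab} = \left(\frac{(\mathrm{OOC}_b - \mathrm{RE}_a)\,
(\mathrm{OOF}_b - \mathrm{OOC}_b)}{\mathrm{OOF}_b - \mathrm{RE}_b}
- \mathrm{thres}\right)\times 100,$$

where $\mathrm{RE}_a$ is the family's median error under cluster $b$'s
autoencoder, $\mathrm{RE}_b$ the cluster's own median, $\mathrm{OOC}_b$
the mean error of same-fold out-of-cluster sequences (for a single-cluster
fold: of a held-out 20% split of the cluster, unseen in training), and
$\mathrm{OOF}_b$ the mean error of different-fold sequences. The threshold
(default 0.014) absorbs baseline differences between clusters. The score
is affine and strictly decreasing in $\mathrm{RE}_a$ whenever
$\mathrm{OOF}_b > \mathrm{OOC}_b$; positive means assignable. A family's
$\mathrm{RE}_a$ is its median under *that cluster's* autoencoder (not the
main one): the score compares like with like, each cluster judging the
family through its own decoder. Autoencoder training caps each family at
200 sequences so very large families cannot dominate the decoders.

### Decision table

With $c_{95}, c_{99}$ the calibration limits, $m = (c_{95}+c_{99})/2$ the
midpoint and $w = c_{99}-c_{95}$ the interval width:

| median RE | best FAS | verdict | confidence |
|---|---|---|---|
| $< c_{95}$ | any | known (highest-FAS cluster) | high if mRE $< c_{95}-0.175w$ and FAS $> 1$, else medium |
| $[c_{95}, m)$ | $> 0$ | known | low |
| $[c_{95}, m)$ | $\le 0$ | variant of known folds | low, medium above $c_{95}+w/4$ |
| $\ge m$ | — | novel fold | low $< c_{99}$, medium $< c_{99}+w$, high $\ge c_{99}+w$ |

The published rules let confidence grow with the median error without
quantifying the tiers; expressing the tier boundaries in units of $w$
transfers them to any recalibrated dataset and reproduces the published
behaviour exactly under the reference calibration: the high-confidence
bound $c_{95}-0.175w$ equals 0.1, and the family with the highest published
median error (0.281) lands in the novel/high cell. Ties in the best FAS
are broken lexicographically with a warning; a positive FAS above the
novelty threshold is flagged as an anomaly rather than silently ignored.
Families with fewer than five sequences are flagged low-reliability, as
such calls are known to be fragile.

## The synthetic fold-grammar simulator

Every statistical claim in the test suite is exercised on synthetic data
from `sample_dataset()`, because the reference-scale dataset (44,620
predictor-annotated sequences) is external. The simulator emulates exactly
the structure the method assumes:

* a **fold archetype** is a grammar — an ordered template of H/E/C
  elements with per-element mean lengths and jitter. The three canonical
  training archetypes mimic the major GT folds at toy scale: a
  Rossmann-like β/α/β repeat, its doubled two-domain variant, and a
  membrane-like grammar of long helices and long loops. Further archetypes
  (and all held-out novel ones) are random grammars with no two adjacent
  elements in the same state;
* a **family** draws per-element length offsets and, per hypervariable
  slot, a fixed insertion motif (present in all members), so fold signal
  is carried by element order and length distributions, never by residue
  identity;
* a **sequence** adds per-element length jitter and per-position noise: a
  noised position always flips to a *different* state, so the realized
  mismatch against the family consensus equals the configured rate (a
  binomial oracle tested at 10,000 positions);
* element lengths are discretized normals truncated at 1 — simple,
  reproducible, and consistent with the blockiness of consensus secondary
  structure.

Defaults are the reference study conditions used throughout the tests: 3
training archetypes × 4 families × 150 sequences, width 256, 5% noise,
30% insertion rate, one held-out novel archetype, fixed seed. What the
simulator does **not** emulate: predictor-specific error structure
(real three-state predictions err systematically at element boundaries),
length distributions of real GT domains, homology between families, and
residue-level signal. A pass on synthetic data therefore demonstrates that
the machinery behaves as designed under its own assumptions — not that the
published accuracies transfer to any particular real dataset.

## Study sizes and numerical choices

The reference architecture (width 798, filters 256/512/512) is the
package default. The test suite and the acceptance script run the same
architecture at a reduced study size chosen to keep a complete
train/interpret/detect cycle comfortably reproducible on a single CPU:
width 256, Block 1 filters 8/16/16, Block 2 filters 16/16/16, batch 32,
learning rate $3\times10^{-3}$, at most 12–15 epochs — on the separable
synthetic grammars these settings converge within a few epochs, and the
open-set decoders (filters 32/24/16, 14 epochs, rate $3\times10^{-3}$)
reach the error separation reported by the acceptance script. At this
scale, twofold cross-validated fold accuracy exceeds 0.9 and the
reconstruction-error ranking separates novel archetypes with AUC above
0.9; the exact values for any seed are recomputed by
`scripts/acceptance.R`.

Other numerical decisions, collected: cutoff rounding is half-up; Gumbel
fitting maximizes the closed-form likelihood with BFGS from moment
estimates and rejects zero-variance samples; the bridge and max poolings
define an empty (fully padded) window as masked-out zero; batch-norm uses
running statistics at inference; `mclust`'s BIC picks the mixture size;
softmax rows are max-shifted; all stage seeds derive from one master seed
by a stage-name hash, so adding a stage never perturbs another stage's
draws.

## Known limitations

* Hard H/E/C calls only; no 8-state alphabet, no predictor probabilities,
  no amino-acid features.
* The classifier vocabulary is closed at training time; families absent
  from the labels table cannot be predicted, only scored by the open-set
  path.
* The decoder architecture beyond "mirrored kernels with instance
  normalization" is underdetermined by the reference description; the
  choice here is the smallest standard one, and reconstruction-error
  *scales* (hence calibrated thresholds) are specific to it.
* UMAP projections depend on a Python subprocess; clusterings are per
  projection and intentionally not aggregated across the parameter scan.
* Synthetic validation bounds what the tests can show about real data (see
  above); applying the package to real predictor output should start by
  re-running the calibration, never by reusing published thresholds.
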