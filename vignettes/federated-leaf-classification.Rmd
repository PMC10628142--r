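---
title: "Simulating federated learning for leaf-disease classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating federated learning for leaf-disease classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Automated crop-disease diagnosis from leaf photographs is usually trained
centrally: growers ship their images to one server, which fits a multiclass
classifier. Federated learning (FL) replaces that with a protocol in which
each grower (a *client*) trains on their own private images and shares only
model parameters with a central server. `fedleaf` simulates this protocol
end to end on one machine, so the questions that matter for deploying FL in
this setting — how the number of clients, the number of communication rounds
and the number of local epochs affect the final model — can be studied
reproducibly without any external data download.

## The protocol

One *communication round* has five phases:

1. **Initialization / broadcast** — the server sends the current global
   weights $W$ to every client.
2. **Local training** — client $k$ runs $E_c$ full passes of mini-batch SGD
   (batch size $B_c$, learning rate $L_R$, cross-entropy loss) over its
   private partition $P_k$.
3. **Parameter transfer** — each client returns only its updated weight
   vector $W_k$ and its sample count $n_k$; raw images never leave the
   client.
4. **Aggregation** — the server forms the new global weights by federated
   averaging (FedAvg), the sample-size-weighted mean
   $$W \leftarrow \sum_k \frac{n_k}{\sum_j n_j} W_k .$$
5. **Evaluation** — every client evaluates the *new* global model on its own
   private test shard; the per-client confusion matrices are recorded both
   averaged (mean over clients) and pooled (summed counts, then metrics).

The loop repeats for $R$ rounds. `run_federated_training()` implements
exactly this cycle; `client_update()` / `client_evaluate()` are the client
role and `fedavg()` the aggregation rule.

Two structural choices here were genuinely open and are worth stating:

* **Evaluation timing.** The global model is evaluated *after* aggregation
  in each round, so round $r$'s record describes the model produced by round
  $r$. Evaluating the pre-aggregation local models instead would describe
  $C$ different models and no curve of the global model.
* **Test-side data.** Each client evaluates "its own test data". The global
  stratified test split is itself dealt to clients by the same equal-random
  rule as the training pool, giving every client a private shard. Pooled
  metrics (from the summed confusion matrix) are designated the headline
  values; the mean over clients is retained for comparison. With near-equal
  shard sizes the two rarely differ by much, but pooling is the aggregation
  that corresponds to "all test images classified once".

## Data partitioning

`iid_partition(n, C, seed)` shuffles `1..n` uniformly and deals the result
contiguously. Exact equality of partition sizes is impossible when $C \nmid
n$; the minimal faithful relaxation is adopted: sizes differ by at most one,
with the first `n %% C` clients receiving the extra item. Partitions are
index sets over one shared array rather than copies — the contract is that
clients own disjoint *views* of the data. The training pool is split from
the raw data first (stratified by class) and then partitioned, so test data
are never seen by any client during training.

## The classifier

No deep-learning backend is assumed. The reference classifier `tiny_cnn` is
implemented in the package itself: two 3×3 convolution blocks (8 and 16
filters, ReLU, 2×2 max pooling), global average pooling, and a linear
softmax head. Convolutions are computed by the im2col construction — gather
each pixel's 3×3 neighborhood into a matrix and multiply — so both passes
are BLAS matrix products and a full desk-scale federated run takes seconds.
Backpropagation is verified against central finite differences in the test
suite (agreement to ~1e-9).

Choices the protocol description leaves open, fixed as follows and exposed
as configuration:

* **Optimizer**: plain SGD without momentum or weight decay — the protocol
  names only a local learning rate, and the simplest reading of "learning
  rate" is adopted ($L_R = 0.01$ by default).
* **Loss**: cross-entropy, the universal multiclass default.
* **Batch order**: a fresh seeded shuffle per epoch; the epoch seed is
  derived from the client seed, which is itself derived as
  `derive_seed(base_seed, round, client_id)`. One base seed therefore fixes
  the entire run while keeping rounds and clients decorrelated.
* **Weight transport**: `get_weights()`/`set_weights()` serialize all
  parameters into one flat vector with a layout manifest; two vectors are
  aggregation-compatible iff their layouts are identical. This is the only
  object clients and server exchange.

The seven large published architectures (ResNet50, DenseNet121, VGG16,
MobileNetV2, InceptionV3, ViT-B/16, ViT-B/32) are registered names in
`model_spec()`; building them raises an informative error naming the
missing backend. They share the weight-vector contract, so an adapter
backend would slot in without touching the server or client code.

## Preprocessing

Two operations, applied in this order:

1. **Resize** to the model's input shape (bilinear, via EBImage). The
   full-scale pipeline targets 224×224; the desk-scale default trains at
   32×32, where the synthetic classes remain comfortably separable.
2. **Standardization** $Z = (X - m)/\sigma$ per channel. $m$ and $\sigma$
   are the mean and *population* standard deviation over all pixels of the
   *training split only*, applied unchanged to test data — the point of the
   transform is that train and test share one distribution, and computing
   test-side statistics would leak the test set. `stats_source = "preset"`
   switches to the canonical pretrained-backbone constants
   (0.485/0.456/0.406, 0.229/0.224/0.225) for use with pretrained
   architectures.

A zero-variance channel is an error (σ must be positive), not silently
clamped.

## Evaluation metrics

All four measures derive from the K×K confusion matrix (rows true, columns
predicted):

* Accuracy = (TP+TN)/(TP+FP+TN+FN), which for K classes is trace/total;
* Precision = TP/(TP+FP) and Recall = TP/(TP+FN), per class one-vs-rest;
* F1 = 2·Precision·Recall/(Precision+Recall) per class.

Multiclass averaging is **macro** by default (unweighted mean over classes):
on balanced data macro F1 and accuracy nearly coincide, which matches how
the two are reported side by side in this literature; `"micro"` pooling is
available as a config switch. A class never predicted (undefined precision)
or absent from the truth (undefined recall) contributes 0 and triggers a
warning — degenerate classifiers should be visible, not hidden.

## The synthetic data generator

`make_dataset()` renders parametric leaf images: a dark background, an
elliptical leaf whose base hue is distinct per class, and a class-specific
lesion motif (spot count, radius, color and placement spread drawn from a
per-class table); the class named "healthy" carries no lesions. Within-class
variation comes from seeded jitter of leaf shape and lesion placement;
difficulty is controlled by a uniform pixel-noise amplitude in [0, 1].
Presets mirror the four public leaf collections commonly used in this
literature (grape, apple, corn with 4 classes, tomato with 10, one healthy
class each), at desk scale by default and approximately at published size
(grape 4062, apple 3161, corn 3852, tomato 18160 images) with
`scale = "published"`.

What the generator emulates: the statistical structure the pipeline depends
on — multiclass labels, one healthy class, visually discriminative disease
patterns, controllable difficulty, class-per-directory PNG layout. What it
does not: photographic texture, lighting and pose variation, intra-class
disease-severity gradation, label noise, class imbalance. Consequently,
passing tests demonstrate the *protocol* (partitioning, training,
aggregation, evaluation, reproducibility) is correct and that the pipeline
can learn separable classes; they say nothing about absolute accuracy
attainable on real photographs.

At `noise_level = 0` the classes are separable by a nearest-class-template
rule, which the test suite verifies with an independent nearest-centroid
oracle; accuracy under that oracle is non-increasing in the noise level.

## Problem sizes and numerical choices

The desk-scale study conditions used by the test suite and the acceptance
script: 4-class synthetic datasets at 32×32 with noise 0.1 and 150
images/class (600 images, 80/20 stratified split), trained with the
reference parameter grid — 3 clients, 10 rounds, 1 local epoch, batch 16,
learning rate 0.01. Under these conditions the federated tiny_cnn reaches
pooled test accuracy ≥ 0.95 (typically 1.0). The client-scaling comparison
uses 100 images/class with 3 vs 7 clients over 5 seeds. These sizes were
chosen as the smallest at which the qualitative behaviors of interest
(convergence within 10 rounds; no gain from splitting fixed data across
more clients) are stable across seeds.

Other numerical details:

* FedAvg uses sample-size weighting even though partitions are near-equal;
  with a ≤1-item imbalance the result is deliberately *not* identical to
  the plain mean.
* A single-client federated run is bit-equivalent to centralized training
  under the matched seed schedule — the core correctness property of the
  round loop, asserted to 1e-12 in the tests.
* Max-pooling ties route the gradient to the first matching position in
  scan order; with continuous activations ties are measure-zero.
* The split-then-partition order, the 0.2 test fraction, and last-round
  (rather than best-round) reporting are defaults; best-round values are
  recorded alongside.

## Limitations

Clients are simulated sequentially in one process; there is no transport
layer, no client dropout or partial participation, no non-IID partitioning,
and no privacy mechanism (secure aggregation, differential privacy) — the
simulation studies learning dynamics, not the systems or security layer.
Hyperparameters are taken as given rather than tuned.
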