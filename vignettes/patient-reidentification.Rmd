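---
title: "Siamese patient verification and re-identification for chest radiographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Siamese patient verification and re-identification for chest radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Public chest radiograph collections are anonymized by stripping patient
identifiers from the metadata, but the pixels themselves carry a biometric
signature: lung outlines, rib geometry, clavicles, cardiac silhouette.
`xrayid` implements the two attack models that make this measurable:

* **Patient verification** — given two frontal radiographs, output a score
  `y_hat` in [0, 1] for the hypothesis that both show the same patient.
* **Patient re-identification (retrieval)** — embed every image into a
  metric space and, for a query image, rank a gallery by Euclidean
  embedding distance so that same-patient images surface at the top.

Both models are siamese convolutional networks: twin branches that share
one parameter set. Weight sharing is structural in this package — there is
a single layer list, applied to both inputs — so the branches can never
diverge.

## Data model and pair construction

A `cohort` holds one record per radiograph (image id, patient id,
follow-up index, age, sex, AP/PA view, finding labels) plus a patient
index. Splits are always **patient-wise** (`patient_wise_split()`): all
images of a patient land in a single subset, so no identity leaks between
train, validation and test. Without an official assignment, patients are
shuffled by seed and partitioned by cumulative patient-count fractions —
the simplest deterministic reading of a random 70/10/20 split.

Verification training uses **offline mining**: all `choose(n, 2)`
same-patient pairs (the full positive universe) plus randomly drawn
cross-patient negatives. Each training sample is a triplet
`(x_m1, x_m2, y_m)` with `y_m = 1` exactly when the patient ids agree.
Pairs are unordered — the verification head is symmetric, so ordered
duplicates would only double-count — and stored with lexicographically
ordered ids. Negative sampling is without replacement (distinct pairs,
rejection sampling with deduplication). Two epoch regimes exist:

* **FTS** (fixed training set): negatives drawn once, reused every epoch;
* **RNP** (randomized negative pairs): negatives redrawn per epoch from
  `(seed, epoch)`, so a full run sees many more distinct negatives.

Positives are subsampled once per run and are identical in every epoch
under both regimes. Retrieval training instead uses **online mining**:
within each batch of 32 images, all pairs are enumerated, and the batch is
additionally paired against a cross-batch memory (below). Patients with a
single image are discarded from the retrieval *training* cohort (they can
never form a positive pair) but retained in evaluation cohorts.

## Architectures

Both models share a pluggable backbone. The default `"tiny"` backbone —
three stride-1 convolution blocks with 2x2 max pooling (total stride 8) —
is sized so the entire method trains in minutes on one CPU;
`"resnet-small"` is a residual-block variant behind the same contract. The
full-scale configuration in the reference setting is a 50-layer residual
network pretrained on natural images; pretrained weights are deliberately
not shipped, so that configuration requires external resources and is out
of desk scope.

**Verification head.** The backbone's classification layer is replaced by
a 128-neuron embedding layer. For the tiny backbone this layer reads the
*flattened* final feature map rather than a globally pooled vector: at
desk scale the identity signal is geometric, and global pooling would
discard exactly the spatial information that separates identities. The
merge computes `|sigmoid(z1) - sigmoid(z2)|`, one fully-connected layer
maps 128 -> 1 (no intermediate hidden layer), and a final sigmoid yields
`y_hat`. The embedding layer uses a reduced-gain initialization (half the
He standard deviation) so the pre-sigmoid embeddings start near unit scale
and the sigmoid merge is responsive from the first step.

**Retrieval head.** The backbone feature maps are pooled twice —
adaptive average pooling *and* adaptive max pooling, each to 5x5 — and
concatenated along channels. Concatenating two C-channel pooling outputs
yields 2C maps, and the following 1x1 convolution maps 2C -> 100 (for a
2048-channel backbone that is 4096 -> 100; the per-branch backbone width
is what the "reduction from 2048" refers to). The 2500 flattened values
pass through two fully-connected layers, 2500 -> 512 -> 128 — the head's
output width is fixed by design, the hidden width is a single geometric
reduction step, with a ReLU between the two layers. Because the pooling is
adaptive, one trained model evaluates galleries at any input resolution.

## Training

**Verification** minimizes the binary cross-entropy of `y_hat` with Adam
on mini-batches (Adam applied to mini-batches is how this package reads
"mini-batch SGD combined with adaptive moment estimation"). Validation AUC
is monitored each epoch — AUC, being the headline metric, is the natural
early-stopping monitor — and training stops after `patience = 5` epochs
without improvement, returning the best-validation weights.

**Retrieval** minimizes the contrastive loss
`y d^2 + (1 - y) max(0, m - d)^2` with margin `m = 1`. No 1/2 prefactor is
applied; the convention differing by that constant only rescales the
learning rate. Within each optimization step the positive-pair and
negative-pair losses are averaged separately and weighted equally
(balanced aggregation): positives are roughly 1% of the enumerated pairs,
and under a plain per-pair mean their attractive term is swamped by
negative repulsion, which at small scale stalls training in a
non-discriminative equilibrium. The reference optimizer is SGD — with
classical momentum 0.9 (the usual 1cycle companion) and a global
gradient-norm ceiling (`clip_norm`, default 1) that keeps the high-rate
segment of the schedule stable on unnormalized fully-connected layers —
with L2 weight decay `1e-5`, under a **1cycle** schedule evaluated after
every batch: a cosine rise from `lr_min = 0.0063` to `lr_max = 0.1584`
peaking at 30% of the cycle, then a cosine fall back to `lr_min`. The
bounds are the reference full-scale values; the peak is the kind of value
an `lr_range_test()` sweep suggests (steepest descent of the
exponentially smoothed loss). At desk scale, where the backbone starts
from random weights instead of natural-image pretraining,
`optimizer = "adam"` under the same 1cycle schedule (bounds 2e-4 / 2e-3)
is markedly more sample-efficient and is what the package's own
desk-scale runs use. Training runs in two phases, each with its own
cycle: head-only with the backbone frozen (reference 30 epochs; freezing
is enforced — the backbone parameters are asserted bit-identical at phase
end), then the full network (reference 50 epochs).

The **cross-batch memory** (`xbm_new()`, capacity 128) is a FIFO queue of
the most recent embeddings, labels and image ids: with batches of 32 it
holds exactly the last 4 batches. Each batch is mined against the memory
in addition to itself, multiplying the pair count per step; an image that
re-enters a batch is never paired against its own stale snapshot. Memory
entries are detached — no gradient flows into them — which is sound only
while embeddings drift slowly across adjacent iterations. That premise
holds for a pretrained backbone but fails for from-scratch desk-scale
training, where we measured the memory actively harming retrieval (stale
entries anchor the balanced loss); the desk-scale preset therefore trains
with `xbm_capacity = 0`, while the mechanism itself remains implemented
and contract-tested, and capacity 128 stays the reference default. The
memory is reset at each phase boundary, since the embedding space changes
abruptly when the backbone unfreezes.

## Evaluation

Verification: scores are thresholded at `t = 0.5` (a tie counts positive);
`confusion_metrics()` derives accuracy, specificity, recall, precision and
F1, reporting `NA` on zero denominators rather than failing. AUC uses the
rank-statistic formulation with mid-rank tie correction — chosen over
trapezoidal integration because it is exactly the pairwise-comparison
statistic, which makes the brute-force oracle equivalence in the test
suite an identity, not an approximation. Confidence intervals are
percentile bootstrap over resampled (score, label) pairs; resampling is at
the pair level, a documented caveat since pairs sharing an image are
dependent. Subgroup analyses (`subgroup_tpr()`) bin positive pairs by age
gap in years, by newly appearing finding labels (a pair introducing
several new findings contributes to each bin), or by projection-view
change; bins without positives are omitted.

Retrieval: every image queries the gallery of all others, ranked by raw
(un-normalized) Euclidean distance — an `l2_normalize` flag exists but
defaults to off, since the reference method specifies only "Euclidean
distance". Ties are broken by image id for determinism. `R` is the number
of relevant gallery entries; queries with `R = 0` are excluded from all
three metrics (the convention of the metric's source definition; the
excluded count is reported). `AP@R` sums `P@i * rel@i` over the first `R`
*ranks* — relevant items beyond rank R contribute zero — which is the
"precision at R" semantics; the alternative reading (precision at the
ranks of the first R relevant items wherever they sit) is available via
`domain = "relevant"`.

## Attention maps

`grad_cam_pair()` differentiates the *pre-sigmoid* verification logit
(standard practice for gradient-weighted class-activation maps; the
sigmoid would only rescale gradients) with respect to a chosen
convolutional layer's activations, averages the gradients channel-wise
into weights, and rectifies the weighted activation sum — one map per
branch, and swapping the inputs exactly swaps the maps.

## The phantom generator

`generate_cohort()` produces an identity-structured synthetic cohort so
every module is testable without any external download. Each patient is a
parametric thorax geometry (identity latent: lung ellipse axes, rib count,
spacing and curvature, heart ellipse, clavicle angle, diaphragm contour,
body silhouette) rendered once per follow-up under independently sampled
acquisition nuisance: windowing (display center/width), rotation, scale,
translation, additive Gaussian noise, AP-view mirror flips, an aging drift
(body scale and diaphragm elevation growing with the simulated year gap),
and persistent disease marks that alter pixels and finding labels jointly
— so the disease-change subgroup analysis has exact ground truth. Image
counts per patient follow `1 + Poisson(2.5)`, mimicking follow-up accrual
at an average of 3-4 images per patient. All randomness flows from one
root seed through named substreams, so any single image is reproducible in
isolation and a fixed configuration yields byte-identical outputs.

What the phantom emulates: the *structure* of the identification problem —
stable per-identity geometry under acquisition nuisance, follow-up drift,
view changes, disease progression, metadata dialect. What it does not
emulate: real anatomy, scanner physics, institutional preprocessing
fingerprints, or the label noise of text-mined findings. Passing the
desk-scale suites therefore demonstrates that the implementation learns
and measures what it should on a controlled identity signal; it does not
certify performance on real radiographs.

## Study sizes and numerical choices

The package's reference desk-scale study uses 200 phantom patients
(roughly 700 images) at 64 px — large enough that held-out patients are
genuinely unseen geometry, small enough for single-CPU runs. Two nuisance
conditions are defined once: the moderate default
(`phantom_config()`), under which raw-pixel nearest neighbour reaches
only ~0.5 Precision@1, and the low-nuisance parameter-recovery condition
(`phantom_config_low_nuisance()`), where identity is cleanly recoverable
and the training-recovery checks run. Verification training uses balanced
epochs of 1,000 pairs (RNP), batch 16 and Adam at 2e-3 with up to 8
epochs; retrieval training uses scaled cycles (3 head + 10 full epochs,
width-16 tiny backbone, Adam bounds 2e-4/2e-3, no memory). Degenerate
inputs are handled explicitly: scores exactly at
the threshold count positive; zero-denominator metrics report `NA`;
bootstrap replicates with one class are redrawn; distance ties break by
image id; `log` arguments are clamped at machine epsilon scale
(`bce_loss` at 1e-12).

## Known limitations

* The CNN engine is plain R + BLAS; it is exact (gradients verified
  against central differences) but not fast — full-scale training is out
  of scope by design.
* Bootstrap CIs resample pairs, not patients; dependence between pairs
  sharing an image narrows the intervals slightly.
* The phantom's nuisance model is independent across follow-ups except
  for aging and disease persistence; real acquisition artifacts correlate
  within institutions.
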