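# xrayid

Patient verification and re-identification for frontal chest radiographs
with siamese convolutional networks — a toolkit for auditing how much
biometric identity survives in "anonymized" chest X-ray collections.

Public chest X-ray datasets strip names and IDs from their metadata, but
the pixels still encode who the patient is: lung outlines, rib geometry,
clavicles, the cardiac silhouette. `xrayid` implements the two attack
models that quantify this risk, together with their full training and
evaluation machinery:

* **Verification** — a siamese network with shared-weight branches embeds
  two radiographs into 128-dimensional vectors `z1`, `z2`; the merge
  computes `|σ(z1) − σ(z2)|`, a fully-connected layer reduces it to one
  neuron, and a sigmoid yields the same-patient score
  `ŷ ∈ [0, 1]`. Trained with binary cross-entropy on balanced offline-mined
  image pairs `(x_m1, x_m2, y_m)`, with negatives either fixed (FTS) or
  randomized every epoch (RNP), and early stopping on validation AUC
  (patience 5).
* **Re-identification (retrieval)** — the same backbone with a
  metric-learning head (dual adaptive average+max pooling to 5×5, a 1×1
  convolution to 100 maps, two FC layers to 128 dimensions), trained with
  the contrastive loss `y·d² + (1−y)·max(0, m−d)²` (margin `m = 1`) over
  all within-batch pairs, optionally against a cross-batch memory (FIFO,
  capacity 128 = the last 4 batches), under a 1cycle learning-rate policy
  (reference bounds 0.0063 → 0.1584, selected via a learning-rate range
  test). A query image then ranks the gallery by Euclidean embedding
  distance.

Evaluation covers confusion-derived statistics (accuracy, specificity,
recall, precision, F1), rank-based ROC/AUC with percentile-bootstrap 95%
confidence intervals (10,000 replicates at full scale), subgroup
true-positive-rate analyses (age gap, disease change, view change),
the retrieval metrics mAP@R, R-Precision and Precision@1, and
gradient-weighted class-activation attention maps for both branches.

Everything runs at desk scale on one CPU via a built-in **synthetic
chest-phantom generator**: parametric thorax identities rendered under
acquisition nuisance (windowing, rotation/scale/translation, noise,
AP/PA mirror flips, aging drift, disease marks), with metadata written in
the dialect of the large public chest X-ray collections — so the whole
pipeline is exercised with no external download. Real collections in that
dialect load with the same reader.

## Worked example

```r
library(xrayid)

# 1. simulate a low-nuisance phantom cohort: 200 patients, ~700 images
cohort <- generate_cohort(phantom_config_low_nuisance(seed = 7),
                          "phantom_images")
split  <- patient_wise_split(cohort, c(0.7, 0.1, 0.2), seed = 7)

# 2. train the verification model (RNP pair mining, Adam, early stopping)
fit <- train_verifier(split, mining_config("RNP", n_s = 1000, seed = 7),
                      train_config(learning_rate = 2e-3, batch_size = 16,
                                   input_side = 64, max_epochs = 8,
                                   n_val_pairs = 400, seed = 7))

# 3. score balanced held-out-patient test pairs and report
pos    <- mine_positive_pairs(split$test)
pairs  <- assemble_epoch_pairs(split$test, pos,
                               mining_config("FTS", 360, seed = 18), 1)
tensor <- cohort_tensor(split$test, 64)
scores <- score_pairs(fit$model, tensor, pairs)
verification_report(scores, pairs$label, B = 2000, seed = 7)
#> <verification_report>
#>   AUC 0.9718 (95% CI 0.9544-0.9861)
#>   acc 0.9194  spec 0.9333  recall 0.9056  prec 0.9314  F1 0.9183  (t = 0.50)
#>   TP 163  FN 17  TN 168  FP 12

# 4. train the retrieval model and rank the held-out gallery
rfit <- train_retriever(split,
                        train_config(lr_min = 2e-4, lr_max = 2e-3,
                                     epochs_head = 3, epochs_full = 10,
                                     input_side = 64, optimizer = "adam",
                                     xbm_capacity = 0, seed = 7),
                        width = 16)
evaluate_retrieval(rfit$model, split$test, input_side = 64)
#> <retrieval_report> mAP@R 0.9559  R-Precision 0.9580  Precision@1 0.9664 (119 queries, 5 excluded)
```

The verification numbers say: on patients never seen in training, the
model separates same-patient from different-patient image pairs with an
AUC of about 0.97, and at the 0.5 threshold it recalls 91% of
same-patient pairs at 93% precision. The retrieval numbers say: for 97%
of query images the nearest gallery neighbour by embedding distance is
the same patient, and on average ~96% of each query's top-R slots are
filled correctly. (Your exact values will vary slightly with the seed and
BLAS; these were printed by the code above.)

A shell entry point wrapping the same pipeline ships at
`inst/scripts/xrayid` (tasks: simulate, split, mine, train-verify,
eval-verify, train-retrieve, eval-retrieve, explain; YAML configuration
with CLI overrides).

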