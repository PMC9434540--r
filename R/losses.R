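# Loss functions for the two training objectives.

#' Binary cross-entropy loss
#'
#' `-(y * log(y_hat) + (1 - y) * log(1 - y_hat))`, with `y_hat` clamped to
#' `(eps, 1 - eps)` so the loss stays finite at saturated predictions.
#'
#' @param y_hat Predicted scores in `[0, 1]` (vectorized).
#' @param y Binary labels (0/1).
#' @param eps Clamping constant.
#' @return Non-negative per-sample losses.
#' @export
bce_loss <- function(y_hat, y, eps = 1e-12) {
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' Contrastive loss on embedding pairs
#'
#' With `d` the Euclidean distance between the embeddings:
#' `y * d^2 + (1 - y) * max(0, m - d)^2`. Positive pairs are pulled
#' together quadratically; negative pairs contribute only while their
#' distance is below the margin `m`. No 1/2 prefactor is applied (the
#' convention differing by a constant factor only rescales the learning
#' rate).
#'
#' @param z1,z2 Embedding vectors, or matrices with one embedding per
#'   column.
#' @param y Binary label(s): 1 = same identity, 0 = different.
#' @param margin Margin `m` (> 0, default 1).
#' @return Non-negative per-pair losses.
#' @export
contrastive_loss <- function(z1, z2, y, margin = 1) {
  assert_that(margin > 0, "margin must be positive")
  z1 <- as.matrix(z1); z2 <- as.matrix(z2)
  d <- sqrt(colSums((z1 - z2)^2))
  y * d^2 + (1 - y) * pmax(0, margin - d)^2
}

# Gradient of the mean contrastive loss with respect to z1 (z2 receives the
# negated value for intra-batch pairs). d = distance vector, diff = z1 - z2.
contrastive_grad_z1 <- function(diff, d, y, margin) {
  scale <- ifelse(y == 1, 2,
                  ifelse(d < margin & d > 0, -2 * (margin - d) / d, 0))
  sweep(diff, 2, scale, `*`)
}
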