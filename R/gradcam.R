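# Gradient-weighted class-activation maps for the verification siamese
# network: which image regions drive the identity-similarity score.

find_layer <- function(net, layer_name) {
  for (l in seq_along(net)) {
    if (identical(net[[l]]$name, layer_name)) return(l)
  }
  stop("unknown layer: ", layer_name, call. = FALSE)
}

#' Named convolutional layers of a model
#' @param model A siamese model.
#' @return Character vector of layer names usable with [grad_cam_pair()].
#' @export
conv_layer_names <- function(model) {
  nm <- vapply(model$net, function(ly) {
    if (ly$type %in% c("conv", "res") && !is.null(ly$name)) ly$name
    else NA_character_
  }, "")
  nm[!is.na(nm)]
}

#' Attention maps for one verification pair
#'
#' Computes the gradient of the pre-sigmoid verification logit with
#' respect to the chosen convolutional layer's activations, averages the
#' gradients channel-wise into weights, forms the weighted activation sum
#' and rectifies it — one attention map per branch. Swapping the two
#' inputs exactly swaps the two maps.
#'
#' @param model A [siamese_verifier()] (typically `verifier_fit$model`).
#' @param x1,x2 Prepared inputs (`side x side x 3` arrays).
#' @param layer_name Name of a convolutional layer in the shared backbone
#'   (see [conv_layer_names()]); default the first convolution.
#' @return List of two objects of class `attention_map` (fields `values`,
#'   a non-negative matrix at the layer's spatial size; `layer_name`;
#'   `branch`), plus the pair's `score`.
#' @export
grad_cam_pair <- function(model, x1, x2, layer_name = "conv1") {
  li <- find_layer(model$net, layer_name)
  x1 <- as_input_batch(x1); x2 <- as_input_batch(x2)
  fw1 <- net_forward(model$net, x1, grad = TRUE, want_acts = TRUE)
  fw2 <- net_forward(model$net, x2, grad = TRUE, want_acts = TRUE)
  z1 <- fw1$out; z2 <- fw2$out
  s1 <- sigmoid(z1); s2 <- sigmoid(z2)
  sgn <- sign(s1 - s2)
  da <- t(model$head$W)           # d logit / d |s1 - s2|
  dz1 <- da * sgn * s1 * (1 - s1)
  dz2 <- -da * sgn * s2 * (1 - s2)
  one_map <- function(fw, dz, branch) {
    bw <- net_backward(model$net, fw$caches, dz, stop_at = li,
                       want_dacts = TRUE)
    A <- fw$acts[[li]]                     # (h, w, C, 1)
    dA <- bw$dacts[[li]]
    C <- dim(A)[3]
    w <- apply(dA[, , , 1, drop = FALSE], 3, mean)
    m <- matrix(0, dim(A)[1], dim(A)[2])
    for (ch in seq_len(C)) m <- m + w[ch] * A[, , ch, 1]
    structure(list(values = pmax(m, 0), layer_name = layer_name,
                   branch = branch),
              class = "attention_map")
  }
  score <- verification_score(model, z1, z2)$score
  list(first = one_map(fw1, dz1, "first"),
       second = one_map(fw2, dz2, "second"),
       score = score)
}

#' Upsample an attention map and render it as a heatmap PNG
#'
#' Presentation-only: the map is bilinearly upsampled to the image size,
#' normalized to `[0, 1]` and alpha-blended over the grayscale image.
#'
#' @param map An `attention_map`.
#' @param pixels The underlying image grid (`[0, 255]` matrix).
#' @param path Output PNG path.
#' @param alpha Overlay opacity.
#' @return `path`, invisibly.
#' @export
write_attention_overlay <- function(map, pixels, path, alpha = 0.4) {
  side <- nrow(pixels)
  up <- EBImage::resize(map$values, w = side, h = side)
  rng <- range(up)
  up <- if (diff(rng) > 0) (up - rng[1]) / diff(rng) else up * 0
  base <- pixels / 255
  rgb <- array(0, c(side, ncol(pixels), 3))
  rgb[, , 1] <- pmin(1, base * (1 - alpha) + alpha * up)
  rgb[, , 2] <- base * (1 - alpha)
  rgb[, , 3] <- pmin(1, base * (1 - alpha) + alpha * (1 - up))
  png::writePNG(rgb, path)
  invisible(path)
}
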