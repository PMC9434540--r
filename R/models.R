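# Siamese architectures. Both tasks share the same twin-branch contract:
# each branch is the SAME parameter set (weight sharing is structural, not
# a copy), mapping a prepared input to a 128-dimensional identity
# embedding. The verification model adds a merge head (absolute difference
# of sigmoid activations, one fully-connected neuron, sigmoid); the
# retrieval model replaces the classification head by a dual adaptive
# pooling block feeding a metric-learning embedding.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Build a convolutional backbone
#'
#' Two families are provided behind one contract: `"tiny"`, three
#' convolution/pool blocks sized so the whole pipeline trains in minutes on
#' one CPU, and `"resnet-small"`, a residual-block variant of the same
#' stride. Both reduce the spatial resolution by a factor of 8; the first
#' convolution layer is named `"conv1"` for attention-map extraction.
#'
#' @param name `"tiny"` or `"resnet-small"`.
#' @param width Base channel width (default 8).
#' @return List with `layers` and `feature_channels`.
#' @keywords internal
build_backbone <- function(name = c("tiny", "resnet-small"), width = 8L) {
  name <- match.arg(name)
  w <- as.integer(width)
  if (name == "tiny") {
    layers <- list(
      layer_conv(3L, w, name = "conv1"),
      layer_simple("relu"), layer_simple("pool2"),
      layer_conv(w, 2L * w, name = "conv2"),
      layer_simple("relu"), layer_simple("pool2"),
      layer_conv(2L * w, 4L * w, name = "conv3"),
      layer_simple("relu"), layer_simple("pool2")
    )
    fc <- 4L * w
  } else {
    layers <- list(
      layer_conv(3L, w, name = "conv1"),
      layer_simple("relu"), layer_simple("pool2"),
      layer_res(w, name = "res1"),
      layer_simple("pool2"),
      layer_conv(w, 2L * w, name = "conv2"),
      layer_simple("relu"),
      layer_res(2L * w, name = "res2"),
      layer_simple("pool2")
    )
    fc <- 2L * w
  }
  list(layers = layers, feature_channels = fc)
}

#' Construct the verification siamese network
#'
#' Twin branches (shared parameters) embed each prepared input into a
#' 128-dimensional vector z; the merge computes the absolute difference of
#' the sigmoid activations of the two embeddings, one fully-connected layer
#' reduces it to a single neuron, and a final sigmoid yields the score
#' `y_hat` in `[0, 1]`.
#'
#' @param backbone `"tiny"` (default) or `"resnet-small"`.
#' @param width Backbone base width.
#' @param embed_dim Embedding dimension (128).
#' @param input_side Expected input side length (must be divisible by 8).
#' @param seed Seed for weight initialization.
#' @return Object of class `siamese_verifier`.
#' @export
siamese_verifier <- function(backbone = "tiny", width = 8L,
                             embed_dim = 128L, input_side = 64L, seed = 1) {
  assert_that(input_side %% 8 == 0, "input_side must be divisible by 8")
  with_seed(mix_seed(seed, 11L), {
    bb <- build_backbone(backbone, width)
    # the backbone's classification layer is replaced by a 128-neuron
    # embedding layer reading the flattened final feature map, so spatial
    # anatomy (lung outline, rib positions) stays visible to the embedding
    feat_side <- input_side %/% 8L
    fc_embed <- layer_fc(feat_side * feat_side * bb$feature_channels,
                         embed_dim, name = "fc_embed")
    # reduced-gain init: keeps the pre-sigmoid embeddings near unit scale
    # so the sigmoid merge starts in its responsive range
    fc_embed$W <- fc_embed$W * 0.5
    net <- c(bb$layers, list(layer_simple("flatten"), fc_embed))
    head <- layer_fc(embed_dim, 1L, name = "fc_out")
    structure(
      list(net = net, head = head, backbone_len = length(bb$layers),
           spec = list(backbone = backbone, width = width,
                       embed_dim = embed_dim, input_side = input_side,
                       feature_channels = bb$feature_channels)),
      class = "siamese_verifier")
  })
}

#' Construct the retrieval siamese network
#'
#' The classification head is replaced by: adaptive average pooling AND
#' adaptive max pooling of the backbone feature maps to `5 x 5`, channel
#' concatenation (doubling the map count), a `1 x 1` convolution reducing
#' to 100 maps, flattening (2500 values) and two successive fully-connected
#' layers producing the 128-dimensional embedding. Adaptive pooling makes
#' the head input size independent of the image resolution, so one model
#' evaluates galleries at any input side.
#'
#' @inheritParams siamese_verifier
#' @param pool_side Adaptive pooling output side (5).
#' @param reduce_maps Feature maps after the `1 x 1` convolution (100).
#' @param hidden Width of the first fully-connected layer (512).
#' @return Object of class `siamese_retriever`.
#' @export
siamese_retriever <- function(backbone = "tiny", width = 8L,
                              pool_side = 5L, reduce_maps = 100L,
                              hidden = 512L, embed_dim = 128L, seed = 1) {
  with_seed(mix_seed(seed, 12L), {
    bb <- build_backbone(backbone, width)
    flat <- pool_side * pool_side * reduce_maps
    fc2 <- layer_fc(hidden, embed_dim, name = "fc2")
    # reduced-gain init: pairwise embedding distances start at the order
    # of the contrastive margin instead of far outside it, so the first
    # optimization steps are well-scaled
    fc2$W <- fc2$W * 0.1
    net <- c(bb$layers,
             list(layer_simple("dualpool", o = as.integer(pool_side)),
                  layer_conv(2L * bb$feature_channels, reduce_maps, k = 1L,
                             pad = 0L, name = "conv_reduce"),
                  layer_simple("relu"),
                  layer_simple("flatten"),
                  layer_fc(flat, hidden, name = "fc1"),
                  layer_simple("relu"),
                  fc2))
    structure(
      list(net = net, backbone_len = length(bb$layers),
           spec = list(backbone = backbone, width = width,
                       pool_side = pool_side, reduce_maps = reduce_maps,
                       hidden = hidden, embed_dim = embed_dim,
                       feature_channels = bb$feature_channels)),
      class = "siamese_retriever")
  })
}

as_input_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 3) {
    dim(x) <- c(d, 1L)
  } else if (length(d) != 4) {
    stop("input must be a (side, side, 3) array or a batch thereof",
         call. = FALSE)
  }
  assert_that(dim(x)[3] == 3, "input must have 3 channels")
  x
}

#' Embed inputs with the verification branch
#'
#' @param model A [siamese_verifier()].
#' @param x Prepared input array `(side, side, 3)` or batch
#'   `(side, side, 3, n)` from [prepare_model_input()].
#' @return Matrix `embed_dim x n` of pre-activation embeddings z.
#' @export
embed_verification <- function(model, x) {
  x <- as_input_batch(x)
  assert_that(dim(x)[1] == model$spec$input_side &&
                dim(x)[2] == model$spec$input_side,
              sprintf("input side must be %d", model$spec$input_side))
  net_forward(model$net, x, grad = FALSE)$out
}

#' Merge two embeddings into a verification score
#'
#' Computes `y_hat = sigmoid(FC(|sigmoid(z1) - sigmoid(z2)|))`. Exactly
#' symmetric in its two arguments.
#'
#' @param model A `siamese_verifier` (its merge head is used).
#' @param z1,z2 Embedding vectors (length `embed_dim`) or matrices
#'   (`embed_dim x n`).
#' @return List with `score` (in `[0, 1]`) and pre-sigmoid `logit`, each of
#'   length n.
#' @export
verification_score <- function(model, z1, z2) {
  z1 <- as.matrix(z1); z2 <- as.matrix(z2)
  assert_that(nrow(z1) == model$spec$embed_dim &&
                nrow(z2) == model$spec$embed_dim,
              sprintf("embeddings must have dimension %d",
                      model$spec$embed_dim))
  a <- abs(sigmoid(z1) - sigmoid(z2))
  logit <- as.vector(model$head$W %*% a + model$head$b)
  list(score = sigmoid(logit), logit = logit)
}

#' Score image pairs with a verification model
#'
#' @param model A `siamese_verifier`.
#' @param tensor Output of [cohort_tensor()] covering all ids in `pairs`.
#' @param pairs A `pair_set`.
#' @param batch_size Images per forward batch.
#' @return Numeric vector of scores aligned to `pairs`.
#' @export
score_pairs <- function(model, tensor, pairs, batch_size = 64L) {
  idx <- match(c(pairs$first_id, pairs$second_id), tensor$ids)
  assert_that(!anyNA(idx), "pairs reference ids missing from tensor")
  n <- length(idx)
  z <- matrix(0, model$spec$embed_dim, n)
  for (s in seq(1L, n, batch_size)) {
    e <- min(s + batch_size - 1L, n)
    z[, s:e] <- embed_verification(model,
                                   tensor$x[, , , idx[s:e], drop = FALSE])
  }
  m <- nrow(pairs)
  verification_score(model, z[, seq_len(m), drop = FALSE],
                     z[, m + seq_len(m), drop = FALSE])$score
}

#' Embed inputs with the retrieval branch
#'
#' @param model A [siamese_retriever()].
#' @param x Prepared input array or batch; any side length >= 8 is
#'   accepted thanks to adaptive pooling.
#' @return Matrix `embed_dim x n` of embeddings.
#' @export
embed_retrieval <- function(model, x) {
  x <- as_input_batch(x)
  assert_that(dim(x)[1] >= 8 && dim(x)[2] >= 8,
              "input smaller than the backbone stride")
  net_forward(model$net, x, grad = FALSE)$out
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry an explicit schema version and the constructor spec so
#' that loading validates compatibility.
#'
#' @param model A `siamese_verifier` or `siamese_retriever`.
#' @param path File path (`.rds`).
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  saveRDS(list(schema_version = 1L, class = class(model)[1],
               model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  assert_that(identical(ck$schema_version, 1L),
              "unsupported checkpoint schema version")
  ck$model
}
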