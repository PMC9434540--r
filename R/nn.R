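# Minimal convolutional-network engine.
#
# Activations are numeric arrays of dimension (H, W, C, N); vector-valued
# activations are matrices (D, N). Convolutions use stride 1 with "same"
# padding and are computed through an im2col lowering so that the inner
# loop is a single BLAS matrix product; down-sampling is done by explicit
# 2x2 max-pooling layers. All layers implement an exact backward pass so
# that both siamese branches can be trained end-to-end and attention maps
# can be extracted from intermediate gradients.

# Stride-1 "same" convolution computed as a sum of k*k shifted-slice
# matrix products: the input is transposed once to channels-first
# (C, Hp, Wp, N) and, for each kernel offset (a, b), the corresponding
# weight block multiplies the shifted spatial slice. This keeps the inner
# loop in BLAS without materializing an im2col matrix. The weight matrix
# W is (cout, k*k*cin) with columns ordered (kernel row, kernel col,
# channel), kernel row fastest.
wcol_idx <- function(a, b, k, C) a + (b - 1L) * k + (seq_len(C) - 1L) * k * k

conv_forward <- function(X, W, b, k, pad, grad = TRUE) {
  d <- dim(X)
  H <- d[1]; Wd <- d[2]; C <- d[3]; n <- d[4]
  Xpp <- aperm(X, c(3, 1, 2, 4))          # (C, H, W, N)
  if (pad > 0L) {
    tmp <- array(0, c(C, H + 2L * pad, Wd + 2L * pad, n))
    tmp[, pad + seq_len(H), pad + seq_len(Wd), ] <- Xpp
    Xpp <- tmp
  }
  cout <- nrow(W)
  HWn <- H * Wd * n
  Ym <- matrix(b, cout, HWn)
  for (a in seq_len(k)) for (bb in seq_len(k)) {
    Xs <- Xpp[, a - 1L + seq_len(H), bb - 1L + seq_len(Wd), ,
              drop = FALSE]
    Ym <- Ym + W[, wcol_idx(a, bb, k, C), drop = FALSE] %*%
      matrix(Xs, C, HWn)
  }
  Ya <- aperm(array(Ym, c(cout, H, Wd, n)), c(2, 3, 1, 4))
  cache <- if (grad) list(Xpp = Xpp, dims = d, k = k, pad = pad) else NULL
  list(out = Ya, cache = cache)
}

conv_backward <- function(dY, W, cache, need_dx = TRUE) {
  d <- cache$dims
  H <- d[1]; Wd <- d[2]; C <- d[3]; n <- d[4]
  k <- cache$k; pad <- cache$pad
  cout <- nrow(W)
  HWn <- H * Wd * n
  dYm <- matrix(aperm(dY, c(3, 1, 2, 4)), nrow = cout)
  db <- rowSums(dYm)
  dW <- matrix(0, cout, k * k * C)
  dXpp <- if (need_dx) array(0, dim(cache$Xpp)) else NULL
  ri <- seq_len(H); ci <- seq_len(Wd)
  for (a in seq_len(k)) for (bb in seq_len(k)) {
    cols <- wcol_idx(a, bb, k, C)
    Xs <- matrix(cache$Xpp[, a - 1L + ri, bb - 1L + ci, , drop = FALSE],
                 C, HWn)
    dW[, cols] <- dW[, cols] + tcrossprod(dYm, Xs)
    if (need_dx) {
      dXs <- crossprod(W[, cols, drop = FALSE], dYm)
      dXpp[, a - 1L + ri, bb - 1L + ci, ] <-
        dXpp[, a - 1L + ri, bb - 1L + ci, , drop = FALSE] +
        array(dXs, c(C, H, Wd, n))
    }
  }
  if (!need_dx) return(list(dX = NULL, dW = dW, db = db))
  if (pad > 0L) {
    dXpp <- dXpp[, pad + ri, pad + ci, , drop = FALSE]
  }
  list(dX = aperm(dXpp, c(2, 3, 1, 4)), dW = dW, db = db)
}

maxpool2_forward <- function(X, grad = TRUE) {
  d <- dim(X)
  stopifnot(d[1] %% 2 == 0, d[2] %% 2 == 0)
  io <- seq(1L, d[1], 2L); jo <- seq(1L, d[2], 2L)
  x11 <- X[io, jo, , , drop = FALSE]
  x21 <- X[io + 1L, jo, , , drop = FALSE]
  x12 <- X[io, jo + 1L, , , drop = FALSE]
  x22 <- X[io + 1L, jo + 1L, , , drop = FALSE]
  M <- array(pmax(x11, x21, x12, x22), dim(x11))
  cache <- if (grad) list(x11 = x11, x21 = x21, x12 = x12, x22 = x22,
                          M = M, dims = d) else NULL
  list(out = M, cache = cache)
}

maxpool2_backward <- function(dY, cache) {
  d <- cache$dims
  M <- cache$M
  m11 <- cache$x11 == M
  m21 <- (cache$x21 == M) & !m11
  m12 <- (cache$x12 == M) & !m11 & !m21
  m22 <- !m11 & !m21 & !m12
  io <- seq(1L, d[1], 2L); jo <- seq(1L, d[2], 2L)
  dX <- array(0, d)
  dX[io, jo, , ] <- dY * m11
  dX[io + 1L, jo, , ] <- dY * m21
  dX[io, jo + 1L, , ] <- dY * m12
  dX[io + 1L, jo + 1L, , ] <- dY * m22
  dX
}

adaptive_bins <- function(n, o) {
  lapply(seq_len(o), function(i) {
    (floor((i - 1) * n / o) + 1L):ceiling(i * n / o)
  })
}

# Dual adaptive pooling: average- and max-pool the (H, W) grid to (o, o)
# and concatenate along channels -> (o, o, 2C, N). On a constant feature
# map the two halves coincide.
dualpool_forward <- function(X, o, grad = TRUE) {
  d <- dim(X)
  C <- d[3]; n <- d[4]
  rb <- adaptive_bins(d[1], o)
  cb <- adaptive_bins(d[2], o)
  Y <- array(0, c(o, o, 2L * C, n))
  for (i in seq_len(o)) for (j in seq_len(o)) {
    sub <- X[rb[[i]], cb[[j]], , , drop = FALSE]
    len <- length(rb[[i]]) * length(cb[[j]])
    m2 <- matrix(sub, nrow = len)
    Y[i, j, seq_len(C), ] <- colMeans(m2)
    mx <- m2[1, ]
    if (len > 1) for (r in 2:len) mx <- pmax(mx, m2[r, ])
    Y[i, j, C + seq_len(C), ] <- mx
  }
  cache <- if (grad) list(X = X, o = o, rb = rb, cb = cb) else NULL
  list(out = Y, cache = cache)
}

dualpool_backward <- function(dY, cache) {
  X <- cache$X
  d <- dim(X)
  C <- d[3]; n <- d[4]
  o <- cache$o
  dX <- array(0, d)
  for (i in seq_len(o)) for (j in seq_len(o)) {
    ri <- cache$rb[[i]]; cj <- cache$cb[[j]]
    len <- length(ri) * length(cj)
    sub <- matrix(X[ri, cj, , , drop = FALSE], nrow = len)
    davg <- as.vector(dY[i, j, seq_len(C), ])
    dmax <- as.vector(dY[i, j, C + seq_len(C), ])
    mx <- sub[1, ]
    if (len > 1) for (r in 2:len) mx <- pmax(mx, sub[r, ])
    ties <- sub == rep(mx, each = len)
    cnt <- colSums(ties)
    g <- matrix(rep(davg / len, each = len), nrow = len) +
      ties * rep(dmax / cnt, each = len)
    dX[ri, cj, , ] <- dX[ri, cj, , ] + array(g, c(length(ri), length(cj), C, n))
  }
  dX
}

gap_forward <- function(X, grad = TRUE) {
  d <- dim(X)
  HW <- d[1] * d[2]
  Y <- matrix(colMeans(matrix(X, nrow = HW)), nrow = d[3])
  list(out = Y, cache = if (grad) list(dims = d) else NULL)
}

gap_backward <- function(dY, cache) {
  d <- cache$dims
  HW <- d[1] * d[2]
  array(rep(as.vector(dY) / HW, each = HW), d)
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

layer_conv <- function(cin, cout, k = 3L, pad = (k - 1L) %/% 2L,
                       name = NULL) {
  list(type = "conv", k = as.integer(k), pad = as.integer(pad),
       cin = cin, cout = cout, name = name,
       W = he_init(cout, k * k * cin, k * k * cin),
       b = numeric(cout))
}

layer_res <- function(c, k = 3L, name = NULL) {
  list(type = "res", k = as.integer(k), pad = (as.integer(k) - 1L) %/% 2L,
       c = c, name = name,
       W1 = he_init(c, k * k * c, k * k * c), b1 = numeric(c),
       W2 = he_init(c, k * k * c, k * k * c), b2 = numeric(c))
}

layer_fc <- function(din, dout, name = NULL) {
  list(type = "fc", din = din, dout = dout, name = name,
       W = he_init(dout, din, din), b = numeric(dout))
}

layer_simple <- function(type, name = NULL, ...) {
  c(list(type = type, name = name), list(...))
}

# Forward pass through a layer list. Returns the final output, per-layer
# backward caches (NULL when grad = FALSE) and, if want_acts, every layer's
# output activation.
net_forward <- function(net, X, grad = TRUE, want_acts = FALSE) {
  caches <- vector("list", length(net))
  acts <- if (want_acts) vector("list", length(net)) else NULL
  for (l in seq_along(net)) {
    ly <- net[[l]]
    r <- switch(ly$type,
      conv = conv_forward(X, ly$W, ly$b, ly$k, ly$pad, grad = grad),
      relu = {
        mask <- X > 0
        list(out = X * mask, cache = if (grad) list(mask = mask) else NULL)
      },
      pool2 = maxpool2_forward(X, grad = grad),
      dualpool = dualpool_forward(X, ly$o, grad = grad),
      gap = gap_forward(X, grad = grad),
      flatten = {
        d <- dim(X)
        list(out = matrix(X, nrow = prod(d[1:3]), ncol = d[4]),
             cache = if (grad) list(dims = d) else NULL)
      },
      fc = list(out = ly$W %*% X + ly$b,
                cache = if (grad) list(X = X) else NULL),
      res = {
        r1 <- conv_forward(X, ly$W1, ly$b1, ly$k, ly$pad, grad = grad)
        mask1 <- r1$out > 0
        h1 <- r1$out * mask1
        r2 <- conv_forward(h1, ly$W2, ly$b2, ly$k, ly$pad, grad = grad)
        s <- r2$out + X
        mask_out <- s > 0
        list(out = s * mask_out,
             cache = if (grad) list(c1 = r1$cache, c2 = r2$cache,
                                    mask1 = mask1, mask_out = mask_out)
                     else NULL)
      },
      stop("unknown layer type: ", ly$type)
    )
    X <- r$out
    caches[[l]] <- r$cache
    if (want_acts) acts[[l]] <- X
  }
  list(out = X, caches = caches, acts = acts)
}

# Backward pass. `stop_at` skips gradient propagation below that layer
# index (used to freeze the backbone cheaply). Returns parameter gradients
# parallel to `net` and, if want_dacts, the gradient arriving at each
# layer's OUTPUT.
net_backward <- function(net, caches, dOut, stop_at = 1L,
                         want_dacts = FALSE) {
  grads <- vector("list", length(net))
  dacts <- if (want_dacts) vector("list", length(net)) else NULL
  d <- dOut
  for (l in rev(seq_along(net))) {
    if (want_dacts) dacts[[l]] <- d
    ly <- net[[l]]
    ca <- caches[[l]]
    if (ly$type == "conv") {
      r <- conv_backward(d, ly$W, ca, need_dx = l > stop_at)
      grads[[l]] <- list(W = r$dW, b = r$db)
      d <- r$dX
    } else if (ly$type == "relu") {
      d <- d * ca$mask
    } else if (ly$type == "pool2") {
      d <- maxpool2_backward(d, ca)
    } else if (ly$type == "dualpool") {
      d <- dualpool_backward(d, ca)
    } else if (ly$type == "gap") {
      d <- gap_backward(d, ca)
    } else if (ly$type == "flatten") {
      d <- array(d, ca$dims)
    } else if (ly$type == "fc") {
      grads[[l]] <- list(W = tcrossprod(d, ca$X), b = rowSums(d))
      d <- crossprod(ly$W, d)
    } else if (ly$type == "res") {
      ds <- d * ca$mask_out
      r2 <- conv_backward(ds, ly$W2, ca$c2)
      dh1 <- r2$dX * ca$mask1
      r1 <- conv_backward(dh1, ly$W1, ca$c1)
      grads[[l]] <- list(W1 = r1$dW, b1 = r1$db, W2 = r2$dW, b2 = r2$db)
      d <- ds + r1$dX
    }
    if (l <= stop_at) break
  }
  list(grads = grads, dX = d, dacts = dacts)
}

layer_param_names <- function(layer) {
  intersect(c("W", "b", "W1", "b1", "W2", "b2"), names(layer))
}

add_grads <- function(g1, g2) {
  if (is.null(g1)) return(g2)
  if (is.null(g2)) return(g1)
  for (l in seq_along(g1)) {
    if (is.null(g1[[l]])) { g1[[l]] <- g2[[l]]; next }
    if (is.null(g2[[l]])) next
    for (p in names(g1[[l]])) g1[[l]][[p]] <- g1[[l]][[p]] + g2[[l]][[p]]
  }
  g1
}

adam_init <- function(net) {
  lapply(net, function(ly) {
    ps <- layer_param_names(ly)
    if (length(ps) == 0) return(NULL)
    st <- list()
    for (p in ps) {
      zero <- ly[[p]] * 0   # same shape/class as the parameter
      st[[p]] <- list(m = zero, v = zero)
    }
    st
  })
}

adam_update <- function(net, grads, state, lr, t, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8,
                        trainable = rep(TRUE, length(net))) {
  for (l in seq_along(net)) {
    if (!trainable[l] || is.null(grads[[l]])) next
    for (p in names(grads[[l]])) {
      g <- grads[[l]][[p]]
      st <- state[[l]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      net[[l]][[p]] <- net[[l]][[p]] - lr * mhat / (sqrt(vhat) + eps)
      state[[l]][[p]] <- st
    }
  }
  list(net = net, state = state)
}

# Rescale a gradient list so its joint L2 norm does not exceed max_norm.
clip_gradients <- function(grads, max_norm) {
  if (is.null(max_norm) || !is.finite(max_norm)) return(grads)
  total <- 0
  for (g in grads) {
    if (is.null(g)) next
    for (p in g) total <- total + sum(p * p)
  }
  total <- sqrt(total)
  if (total <= max_norm || total == 0) return(grads)
  sc <- max_norm / total
  for (l in seq_along(grads)) {
    if (is.null(grads[[l]])) next
    for (p in names(grads[[l]])) {
      grads[[l]][[p]] <- grads[[l]][[p]] * sc
    }
  }
  grads
}

# SGD with classical momentum; `state` carries the velocity buffers and
# may be NULL on the first call.
sgd_update <- function(net, grads, lr, weight_decay = 0,
                       trainable = rep(TRUE, length(net)),
                       momentum = 0, state = NULL) {
  if (is.null(state)) state <- vector("list", length(net))
  for (l in seq_along(net)) {
    if (!trainable[l] || is.null(grads[[l]])) next
    for (p in names(grads[[l]])) {
      g <- grads[[l]][[p]]
      if (weight_decay > 0 && substr(p, 1, 1) == "W") {
        g <- g + weight_decay * net[[l]][[p]]
      }
      if (momentum > 0) {
        v <- state[[l]][[p]]
        v <- if (is.null(v)) g else momentum * v + g
        state[[l]][[p]] <- v
        g <- v
      }
      net[[l]][[p]] <- net[[l]][[p]] - lr * g
    }
  }
  list(net = net, state = state)
}
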