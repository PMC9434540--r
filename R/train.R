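# Training procedures for the two siamese tasks.
#
# Verification: balanced offline-mined pairs, binary cross-entropy on the
# merge-head score, Adam on mini-batches, early stopping on validation
# AUC. Retrieval: online within-batch pair enumeration plus cross-batch
# memory, contrastive loss on embeddings, SGD with weight decay under a
# 1cycle learning-rate policy, in two phases (head only with frozen
# backbone, then the full network).

#' Training configuration
#'
#' Defaults are the full-scale reference settings: batch size 32, patience
#' 5, decision threshold 0.5, margin 1, weight decay 1e-5, 1cycle bounds
#' 0.0063 / 0.1584, 30 head epochs + 50 full epochs, cross-batch memory of
#' 128. Desk-scale runs override `input_side`, the epoch counts and the
#' learning-rate bounds.
#'
#' @param learning_rate Adam learning rate for verification training.
#' @param batch_size Mini-batch size (pairs for verification, images for
#'   retrieval).
#' @param patience Early-stopping patience in epochs.
#' @param threshold Decision threshold on the verification score.
#' @param margin Contrastive-loss margin.
#' @param weight_decay L2 weight decay for retrieval training.
#' @param momentum Classical momentum for retrieval SGD (the usual
#'   companion of a 1cycle schedule).
#' @param clip_norm Global gradient-norm ceiling for retrieval SGD;
#'   gradients are rescaled when their joint L2 norm exceeds it
#'   (stabilizes the high-rate segment of the 1cycle).
#' @param optimizer Optimizer for retrieval training: `"sgd"` (the
#'   reference full-scale setting) or `"adam"` (recommended at desk scale,
#'   where the backbone starts from random weights rather than
#'   natural-image pretraining); both follow the 1cycle rate schedule.
#' @param lr_min,lr_max 1cycle learning-rate bounds.
#' @param epochs_head,epochs_full Retrieval phase lengths in epochs.
#' @param max_epochs Verification epoch cap.
#' @param xbm_capacity Cross-batch memory size (embeddings).
#' @param input_side Network input side length in pixels.
#' @param n_val_pairs Balanced validation pair count for verification.
#' @param seed Seed governing batching and initialization.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 32L,
                         patience = 5L, threshold = 0.5, margin = 1,
                         weight_decay = 1e-5, momentum = 0.9,
                         clip_norm = 1, optimizer = c("sgd", "adam"),
                         lr_min = 0.0063,
                         lr_max = 0.1584, epochs_head = 30L,
                         epochs_full = 50L, max_epochs = 50L,
                         xbm_capacity = 128L, input_side = 256L,
                         n_val_pairs = 1000L, seed = 1L) {
  assert_that(lr_min < lr_max, "lr_min must be below lr_max")
  assert_that(patience >= 1, "patience must be >= 1")
  assert_that(threshold > 0 && threshold < 1,
              "threshold must lie strictly in (0, 1)")
  assert_that(margin > 0, "margin must be positive")
  optimizer <- match.arg(optimizer)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), threshold = threshold,
                 margin = margin, weight_decay = weight_decay,
                 momentum = momentum, clip_norm = clip_norm,
                 optimizer = optimizer,
                 lr_min = lr_min, lr_max = lr_max,
                 epochs_head = as.integer(epochs_head),
                 epochs_full = as.integer(epochs_full),
                 max_epochs = as.integer(max_epochs),
                 xbm_capacity = as.integer(xbm_capacity),
                 input_side = as.integer(input_side),
                 n_val_pairs = as.integer(n_val_pairs),
                 seed = as.integer(seed)),
            class = "train_config")
}

# forward + backward of the verification network on one pair batch;
# returns loss, gradients for net and head
verifier_pair_step <- function(model, x1, x2, y) {
  n <- length(y)
  xb <- array(0, c(dim(x1)[1:3], 2L * n))
  xb[, , , seq_len(n)] <- x1
  xb[, , , n + seq_len(n)] <- x2
  fw <- net_forward(model$net, xb, grad = TRUE)
  z <- fw$out
  z1 <- z[, seq_len(n), drop = FALSE]
  z2 <- z[, n + seq_len(n), drop = FALSE]
  s1 <- sigmoid(z1); s2 <- sigmoid(z2)
  a <- abs(s1 - s2)
  logit <- as.vector(model$head$W %*% a + model$head$b)
  yhat <- sigmoid(logit)
  loss <- mean(bce_loss(yhat, y))
  dlogit <- matrix((yhat - y) / n, nrow = 1)
  head_grad <- list(W = tcrossprod(dlogit, a), b = sum(dlogit))
  da <- crossprod(model$head$W, dlogit)
  sgn <- sign(s1 - s2)
  dz1 <- da * sgn * s1 * (1 - s1)
  dz2 <- -da * sgn * s2 * (1 - s2)
  dz <- cbind(dz1, dz2)
  bw <- net_backward(model$net, fw$caches, dz)
  list(loss = loss, net_grads = bw$grads, head_grad = head_grad)
}

#' Train the verification siamese network
#'
#' Minimizes the binary cross-entropy of the merge-head score with Adam on
#' mini-batches of image pairs. Each epoch's balanced pair set comes from
#' [assemble_epoch_pairs()]: identical positives every epoch, negatives
#' fixed (FTS) or redrawn per epoch (RNP). Validation AUC is monitored
#' after every epoch; training halts once it has not improved for
#' `patience` consecutive epochs and the best-validation weights are
#' returned.
#'
#' @param split A [patient_wise_split()] result with non-empty train and
#'   val cohorts.
#' @param mining A [mining_config()].
#' @param cfg A [train_config()].
#' @param model Optional pre-built [siamese_verifier()]; by default one is
#'   created with `backbone`/`width` at `cfg$input_side`.
#' @param backbone,width Passed to [siamese_verifier()] when `model` is
#'   NULL.
#' @param history_csv Optional path; per-epoch history is written there.
#' @param verbose Print per-epoch progress.
#' @return Object of class `verifier_fit`: `model` (best weights),
#'   `history` (epoch, loss, val_auc, lr), `best_epoch`, `stopped_epoch`.
#' @export
train_verifier <- function(split, mining, cfg = train_config(),
                           model = NULL, backbone = "tiny", width = 8L,
                           history_csv = NULL, verbose = FALSE) {
  positives <- mine_positive_pairs(split$train)
  assert_that(nrow(positives) > 0, "no positive training pairs available")
  if (is.null(model)) {
    model <- siamese_verifier(backbone = backbone, width = width,
                              input_side = cfg$input_side, seed = cfg$seed)
  }
  side <- model$spec$input_side
  train_tensor <- cohort_tensor(split$train, side)
  val_tensor <- cohort_tensor(split$val, side)

  val_pos <- mine_positive_pairs(split$val)
  assert_that(nrow(val_pos) > 0, "validation cohort has no positive pairs")
  n_val <- min(cfg$n_val_pairs, 2L * nrow(val_pos),
               2L * n_cross_pairs(split$val))
  n_val <- n_val - n_val %% 2L
  val_pairs <- assemble_epoch_pairs(
    split$val, val_pos,
    mining_config("FTS", n_s = n_val, seed = mix_seed(cfg$seed, 77L)), 1L)

  adam_net <- adam_init(model$net)
  adam_head <- adam_init(list(model$head))[[1]]
  t_step <- 0L
  best <- list(auc = -Inf, epoch = 0L, net = model$net, head = model$head)
  since_improve <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_auc = numeric(0), lr = numeric(0))
  stopped_epoch <- cfg$max_epochs

  for (epoch in seq_len(cfg$max_epochs)) {
    pairs <- assemble_epoch_pairs(split$train, positives, mining, epoch)
    ord <- with_seed(mix_seed(cfg$seed, 303L, epoch),
                     sample.int(nrow(pairs)))
    pairs <- pairs[ord, , drop = FALSE]
    i1 <- match(pairs$first_id, train_tensor$ids)
    i2 <- match(pairs$second_id, train_tensor$ids)
    losses <- numeric(0)
    for (s in seq(1L, nrow(pairs), cfg$batch_size)) {
      e <- min(s + cfg$batch_size - 1L, nrow(pairs))
      idx <- s:e
      st <- verifier_pair_step(
        model,
        train_tensor$x[, , , i1[idx], drop = FALSE],
        train_tensor$x[, , , i2[idx], drop = FALSE],
        pairs$label[idx])
      t_step <- t_step + 1L
      up <- adam_update(model$net, st$net_grads, adam_net,
                        cfg$learning_rate, t_step)
      model$net <- up$net; adam_net <- up$state
      uph <- adam_update(list(model$head), list(st$head_grad),
                         list(adam_head), cfg$learning_rate, t_step)
      model$head <- uph$net[[1]]; adam_head <- uph$state[[1]]
      losses <- c(losses, st$loss)
    }
    val_scores <- score_pairs(model, val_tensor, val_pairs)
    val_auc <- roc_auc(val_scores, val_pairs$label)
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = mean(losses),
                                val_auc = val_auc,
                                lr = cfg$learning_rate))
    if (verbose) {
      message(sprintf("epoch %d  loss %.4f  val AUC %.4f", epoch,
                      mean(losses), val_auc))
    }
    if (val_auc > best$auc) {
      best <- list(auc = val_auc, epoch = epoch, net = model$net,
                   head = model$head)
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= cfg$patience) {
        stopped_epoch <- epoch
        break
      }
    }
  }
  model$net <- best$net
  model$head <- best$head
  if (!is.null(history_csv)) {
    utils::write.csv(history, history_csv, row.names = FALSE)
  }
  structure(list(model = model, history = history,
                 best_epoch = best$epoch, best_val_auc = best$auc,
                 stopped_epoch = stopped_epoch, config = cfg,
                 mining = mining),
            class = "verifier_fit")
}

#' @export
print.verifier_fit <- function(x, ...) {
  cat(sprintf(
    "<verifier_fit> best val AUC %.4f at epoch %d (stopped after %d)\n",
    x$best_val_auc, x$best_epoch, x$stopped_epoch))
  invisible(x)
}

# one optimization step of the retrieval network on a batch of images
retriever_batch_step <- function(model, xb, pids, memory, margin,
                                 stop_at = 1L, ids = NULL) {
  fw <- net_forward(model$net, xb, grad = TRUE)
  z <- fw$out
  b <- ncol(z)
  pr <- enumerate_online_pairs(pids, memory$labels,
                               batch_ids = ids, memory_ids = memory$ids)
  if (nrow(pr) == 0) {
    return(list(loss = NA_real_, grads = NULL, z = z))
  }
  zi <- z[, pr$i, drop = FALSE]
  zj <- matrix(0, nrow(z), nrow(pr))
  isb <- pr$kind == "batch"
  if (any(isb)) zj[, isb] <- z[, pr$j[isb], drop = FALSE]
  if (any(!isb)) zj[, !isb] <- memory$embeddings[, pr$j[!isb], drop = FALSE]
  diff <- zi - zj
  d <- sqrt(colSums(diff^2))
  per_pair <- pr$y * d^2 + (1 - pr$y) * pmax(0, margin - d)^2
  # balanced aggregation: positives are a small fraction of the enumerated
  # pairs, so the two classes are averaged separately and weighted equally
  # — otherwise the attractive term is swamped by negative repulsion
  n_pos <- sum(pr$y == 1)
  n_neg <- sum(pr$y == 0)
  w <- ifelse(pr$y == 1,
              if (n_pos > 0) 0.5 / n_pos else 0,
              if (n_neg > 0) 0.5 / n_neg else 0)
  if (n_pos == 0 || n_neg == 0) w <- w * 2  # single-class batch: plain mean
  loss <- sum(w * per_pair)
  G <- contrastive_grad_z1(diff, d, pr$y, margin)
  G <- sweep(G, 2, w, `*`)
  S <- matrix(0, nrow(pr), b)
  S[cbind(seq_len(nrow(pr)), pr$i)] <- 1
  bi <- which(isb)
  if (length(bi) > 0) S[cbind(bi, pr$j[bi])] <- -1
  dz <- G %*% S
  bw <- net_backward(model$net, fw$caches, dz, stop_at = stop_at)
  list(loss = loss, grads = bw$grads, z = z)
}

#' Train the retrieval siamese network
#'
#' Two-phase metric learning with the contrastive loss over all
#' within-batch pairs plus pairs against a cross-batch memory: phase 1
#' trains the adapted head for `epochs_head` epochs with the backbone
#' frozen under one 1cycle schedule; phase 2 trains all parameters for
#' `epochs_full` epochs under a second 1cycle. The optimizer is SGD with
#' L2 weight decay; the learning rate is updated after every single batch.
#' Patients with a single image are discarded from the training cohort
#' (they can never appear in a positive pair); batches are formed by
#' shuffling patients so that same-patient images land in the same batch.
#'
#' @inheritParams train_verifier
#' @param model Optional pre-built [siamese_retriever()].
#' @return Object of class `retriever_fit`: `model`, `history` (per-epoch
#'   phase/loss), `lr_trace` (per-step learning rates, both cycles).
#' @export
train_retriever <- function(split, cfg = train_config(), model = NULL,
                            backbone = "tiny", width = 8L,
                            history_csv = NULL, verbose = FALSE) {
  multi <- names(split$train$patient_index)[
    lengths(split$train$patient_index) >= 2]
  assert_that(length(multi) >= 2,
              "online mining impossible: need >= 2 multi-image patients")
  cohort <- subset_patients(split$train, multi)
  if (is.null(model)) {
    model <- siamese_retriever(backbone = backbone, width = width,
                               seed = cfg$seed)
  }
  tensor <- cohort_tensor(cohort, cfg$input_side)
  pids <- cohort$records$patient_id
  n <- length(pids)
  n_batches <- n %/% cfg$batch_size + as.integer(n %% cfg$batch_size >= 2)
  assert_that(n_batches >= 1, "training cohort smaller than one batch")

  history <- data.frame(phase = character(0), epoch = integer(0),
                        loss = numeric(0))
  lr_trace <- numeric(0)

  run_phase <- function(model, phase, phase_id, epochs, stop_at,
                        trainable) {
    total_steps <- epochs * n_batches
    memory <- xbm_new(cfg$xbm_capacity, model$spec$embed_dim)
    opt_state <- NULL
    adam_state <- if (cfg$optimizer == "adam") adam_init(model$net)
                  else NULL
    step <- 0L
    for (epoch in seq_len(epochs)) {
      ord_p <- with_seed(mix_seed(cfg$seed, 404L, phase_id, epoch),
                         sample(unique(pids)))
      img_order <- unlist(lapply(ord_p, function(p) which(pids == p)),
                          use.names = FALSE)
      losses <- numeric(0)
      for (bidx in seq_len(n_batches)) {
        s <- (bidx - 1L) * cfg$batch_size + 1L
        e <- min(bidx * cfg$batch_size, n)
        take <- img_order[s:e]
        if (length(take) < 2) next
        lr <- one_cycle_lr(step, total_steps, cfg$lr_min, cfg$lr_max)
        st <- retriever_batch_step(
          model, tensor$x[, , , take, drop = FALSE], pids[take], memory,
          cfg$margin, stop_at = stop_at, ids = tensor$ids[take])
        if (!is.null(st$grads)) {
          st$grads <- clip_gradients(st$grads, cfg$clip_norm)
          if (cfg$optimizer == "adam") {
            # decoupled-style L2 term, then the adaptive step
            if (cfg$weight_decay > 0) {
              for (l in which(trainable)) {
                if (is.null(st$grads[[l]])) next
                for (p in names(st$grads[[l]])) {
                  if (substr(p, 1, 1) == "W") {
                    st$grads[[l]][[p]] <- st$grads[[l]][[p]] +
                      cfg$weight_decay * model$net[[l]][[p]]
                  }
                }
              }
            }
            up <- adam_update(model$net, st$grads, adam_state, lr,
                              step + 1L, trainable = trainable)
            model$net <- up$net
            adam_state <- up$state
          } else {
            up <- sgd_update(model$net, st$grads, lr, cfg$weight_decay,
                             trainable, cfg$momentum, opt_state)
            model$net <- up$net
            opt_state <- up$state
          }
        }
        memory <- xbm_update(memory, st$z, pids[take],
                             ids = tensor$ids[take])
        lr_trace <<- c(lr_trace, lr)
        step <- step + 1L
        losses <- c(losses, st$loss)
      }
      history <<- rbind(history,
                        data.frame(phase = phase, epoch = epoch,
                                   loss = mean(losses, na.rm = TRUE)))
      if (verbose) {
        message(sprintf("[%s] epoch %d  loss %.4f", phase, epoch,
                        mean(losses, na.rm = TRUE)))
      }
    }
    model
  }

  nl <- length(model$net)
  head_only <- c(rep(FALSE, model$backbone_len),
                 rep(TRUE, nl - model$backbone_len))
  backbone_before <- model$net[seq_len(model$backbone_len)]
  model <- run_phase(model, "head", 1L, cfg$epochs_head,
                     stop_at = model$backbone_len + 1L,
                     trainable = head_only)
  stopifnot(identical(backbone_before,
                      model$net[seq_len(model$backbone_len)]))
  model <- run_phase(model, "full", 2L, cfg$epochs_full, stop_at = 1L,
                     trainable = rep(TRUE, nl))

  if (!is.null(history_csv)) {
    utils::write.csv(history, history_csv, row.names = FALSE)
  }
  structure(list(model = model, history = history, lr_trace = lr_trace,
                 config = cfg,
                 n_steps = c(head = cfg$epochs_head * n_batches,
                             full = cfg$epochs_full * n_batches)),
            class = "retriever_fit")
}

#' @export
print.retriever_fit <- function(x, ...) {
  cat(sprintf("<retriever_fit> %d training steps, final loss %.4f\n",
              length(x$lr_trace), utils::tail(x$history$loss, 1)))
  invisible(x)
}
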