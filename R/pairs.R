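# Pair mining: offline positive/negative pair construction for the
# verification task, epoch-wise pair assembly (fixed training set vs
# randomized negative pairs), and online within-batch pair enumeration for
# the retrieval task.

new_pair_set <- function(first_id, second_id, label) {
  # canonical storage: unordered pairs with lexicographically smaller id first
  first_id <- as.character(first_id)
  second_id <- as.character(second_id)
  swap <- first_id > second_id
  tmp <- first_id[swap]
  first_id[swap] <- second_id[swap]
  second_id[swap] <- tmp
  assert_that(!any(first_id == second_id),
              "a pair may not pair an image with itself")
  df <- data.frame(first_id = first_id, second_id = second_id,
                   label = as.integer(label), stringsAsFactors = FALSE)
  key <- paste(df$first_id, df$second_id, sep = "\r")
  assert_that(!anyDuplicated(key), "duplicate unordered pairs in pair set")
  class(df) <- c("pair_set", "data.frame")
  df
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("<pair_set> %d pairs (%d positive, %d negative)\n",
              nrow(x), sum(x$label == 1), sum(x$label == 0)))
  invisible(x)
}

pair_keys <- function(pairs) paste(pairs$first_id, pairs$second_id, sep = "\r")

#' Mine all positive image pairs of a cohort
#'
#' For every patient with n >= 2 images, emits all `choose(n, 2)` unordered
#' same-patient pairs (label 1). Patients with a single image contribute
#' nothing.
#'
#' @param cohort A `cohort`.
#' @return A `pair_set` data frame (`first_id`, `second_id`, `label`).
#' @export
mine_positive_pairs <- function(cohort) {
  per <- lapply(cohort$patient_index, function(ids) {
    if (length(ids) < 2) return(NULL)
    cmb <- utils::combn(sort(ids), 2)
    data.frame(first_id = cmb[1, ], second_id = cmb[2, ],
               stringsAsFactors = FALSE)
  })
  per <- per[!vapply(per, is.null, TRUE)]
  if (length(per) == 0) {
    return(new_pair_set(character(0), character(0), integer(0)))
  }
  all <- do.call(rbind, per)
  new_pair_set(all$first_id, all$second_id, rep(1L, nrow(all)))
}

# number of distinct cross-patient unordered pairs in a cohort
n_cross_pairs <- function(cohort) {
  n <- n_images(cohort)
  per <- lengths(cohort$patient_index)
  choose(n, 2) - sum(choose(per, 2))
}

#' Sample distinct negative (cross-patient) image pairs
#'
#' Draws `count` distinct unordered pairs whose two images belong to
#' different patients (label 0), deterministically for a given seed.
#' Sampling is without replacement: rejection sampling with deduplication,
#' falling back to full enumeration when `count` approaches the size of the
#' cross-patient pair universe.
#'
#' @param cohort A `cohort` with at least two patients.
#' @param count Number of pairs to draw; must not exceed the number of
#'   distinct cross-patient pairs.
#' @param seed Integer seed.
#' @return A `pair_set` of `count` negative pairs.
#' @export
sample_negative_pairs <- function(cohort, count, seed = 1) {
  assert_that(n_patients(cohort) >= 2, "need at least 2 patients")
  total <- n_cross_pairs(cohort)
  assert_that(count <= total,
              sprintf("count (%d) exceeds available cross-patient pairs (%d)",
                      count, total))
  if (count == 0) {
    return(new_pair_set(character(0), character(0), integer(0)))
  }
  ids <- cohort$records$image_id
  pid <- cohort$records$patient_id
  n <- length(ids)
  with_seed(seed, {
    if (total <= 2e6 && count > total / 4) {
      # small universe: enumerate all cross pairs and sample exactly
      cmb <- utils::combn(n, 2)
      cross <- cmb[, pid[cmb[1, ]] != pid[cmb[2, ]], drop = FALSE]
      pick <- cross[, sample(ncol(cross), count), drop = FALSE]
      return(new_pair_set(ids[pick[1, ]], ids[pick[2, ]],
                          rep(0L, count)))
    }
    seen <- new.env(hash = TRUE, parent = emptyenv())
    f <- character(count); s <- character(count)
    got <- 0L
    while (got < count) {
      take <- max(64L, 2L * (count - got))
      i1 <- sample.int(n, take, replace = TRUE)
      i2 <- sample.int(n, take, replace = TRUE)
      ok <- pid[i1] != pid[i2]
      i1 <- i1[ok]; i2 <- i2[ok]
      for (k in seq_along(i1)) {
        a <- ids[i1[k]]; b <- ids[i2[k]]
        if (a > b) { tmp <- a; a <- b; b <- tmp }
        key <- paste(a, b, sep = "\r")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          got <- got + 1L
          f[got] <- a; s[got] <- b
          if (got == count) break
        }
      }
    }
    new_pair_set(f, s, rep(0L, count))
  })
}

#' Mining configuration for epoch-wise pair assembly
#'
#' @param mode `"FTS"` (fixed training set: negatives drawn once and reused
#'   every epoch) or `"RNP"` (randomized negative pairs: negatives redrawn
#'   each epoch).
#' @param n_s Target balanced set size (even); the set holds `n_s/2`
#'   positive and `n_s/2` negative pairs.
#' @param seed Integer seed for subsampling and negative drawing.
#' @return Object of class `mining_config`.
#' @export
mining_config <- function(mode = c("RNP", "FTS"), n_s, seed = 1) {
  mode <- match.arg(mode)
  assert_that(n_s %% 2 == 0, "n_s must be even for balanced pair sets")
  structure(list(mode = mode, n_s = as.integer(n_s), seed = as.integer(seed)),
            class = "mining_config")
}

#' Assemble the balanced pair set for one training epoch
#'
#' Positives are subsampled once (deterministically from the config seed) to
#' `n_s/2` and are identical in every epoch. Negatives are drawn from the
#' cohort: under FTS from the config seed alone (identical across epochs);
#' under RNP from `(seed, epoch)` so that fresh negatives are seen each
#' epoch.
#'
#' @param cohort The cohort negatives are drawn from.
#' @param positives `pair_set` of available positive pairs.
#' @param config A [mining_config()].
#' @param epoch Epoch number (1-based).
#' @return A balanced `pair_set` of size `n_s`.
#' @export
assemble_epoch_pairs <- function(cohort, positives, config, epoch = 1) {
  half <- config$n_s %/% 2L
  assert_that(nrow(positives) >= half,
              sprintf("insufficient positives: have %d, need %d",
                      nrow(positives), half))
  pos <- positives
  if (nrow(pos) > half) {
    keep <- with_seed(mix_seed(config$seed, 101L),
                      sample.int(nrow(pos), half))
    pos <- pos[sort(keep), , drop = FALSE]
  }
  neg_seed <- if (config$mode == "FTS") {
    mix_seed(config$seed, 202L)
  } else {
    mix_seed(config$seed, 202L, epoch)
  }
  neg <- sample_negative_pairs(cohort, half, seed = neg_seed)
  out <- rbind(as.data.frame(pos), as.data.frame(neg))
  rownames(out) <- NULL
  class(out) <- c("pair_set", "data.frame")
  out
}

#' Enumerate online pairs within a batch and against a cross-batch memory
#'
#' Returns all `choose(b, 2)` intra-batch unordered index pairs plus all
#' `b * m` batch-to-memory pairs; the label is 1 when the two patient ids
#' agree.
#'
#' @param batch_labels Character vector of patient ids for the batch
#'   (length b).
#' @param memory_labels Character vector of patient ids held in the
#'   cross-batch memory (length m, possibly 0).
#' @param batch_ids,memory_ids Optional image ids; when both are given,
#'   batch-to-memory pairs whose two sides are the same image (a stale
#'   snapshot of itself) are dropped — a pair never pairs an image with
#'   itself.
#' @return Data frame with columns `i`, `j`, `y`, `kind` (`"batch"`: `j`
#'   indexes the batch; `"memory"`: `j` indexes the memory).
#' @export
enumerate_online_pairs <- function(batch_labels,
                                   memory_labels = character(0),
                                   batch_ids = NULL, memory_ids = NULL) {
  b <- length(batch_labels)
  assert_that(b >= 1, "batch must be non-empty")
  out <- list()
  if (b >= 2) {
    cmb <- utils::combn(b, 2)
    out$batch <- data.frame(
      i = cmb[1, ], j = cmb[2, ],
      y = as.integer(batch_labels[cmb[1, ]] == batch_labels[cmb[2, ]]),
      kind = "batch", stringsAsFactors = FALSE)
  }
  m <- length(memory_labels)
  if (m > 0) {
    ii <- rep(seq_len(b), times = m)
    jj <- rep(seq_len(m), each = b)
    mem <- data.frame(
      i = ii, j = jj,
      y = as.integer(batch_labels[ii] == memory_labels[jj]),
      kind = "memory", stringsAsFactors = FALSE)
    if (!is.null(batch_ids) && !is.null(memory_ids)) {
      self <- !is.na(memory_ids[jj]) & batch_ids[ii] == memory_ids[jj]
      mem <- mem[!self, , drop = FALSE]
    }
    out$memory <- mem
  }
  if (length(out) == 0) {
    return(data.frame(i = integer(0), j = integer(0), y = integer(0),
                      kind = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write / read a pair manifest CSV (first_id, second_id, label)
#' @param pairs A `pair_set`.
#' @param csv_path File path.
#' @return `csv_path` (write) or a `pair_set` (read).
#' @export
write_pairs <- function(pairs, csv_path) {
  utils::write.csv(as.data.frame(pairs), csv_path, row.names = FALSE)
  invisible(csv_path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(csv_path) {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "integer"))
  new_pair_set(df$first_id, df$second_id, df$label)
}
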