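# Cross-batch memory: a FIFO store of recent embeddings and their patient
# labels, mined against the current batch to multiply the number of pairs
# seen by the contrastive loss. Entries are detached snapshots — no
# gradient ever flows into memory embeddings (the "slow drift" of
# embeddings across nearby iterations makes slightly stale entries usable).

#' Create an empty cross-batch memory
#'
#' @param capacity Maximum number of stored embeddings. With the default
#'   capacity 128 and batches of 32, the memory holds exactly the last 4
#'   batches. Capacity 0 disables the memory (a permanent no-op).
#' @param embed_dim Embedding dimension.
#' @return Object of class `xbm`.
#' @export
xbm_new <- function(capacity = 128L, embed_dim = 128L) {
  structure(list(capacity = as.integer(capacity),
                 embeddings = matrix(0, embed_dim, 0),
                 labels = character(0),
                 ids = character(0)),
            class = "xbm")
}

#' Enqueue a batch of embeddings into the memory
#'
#' FIFO semantics: new entries are appended and the oldest are evicted once
#' the capacity is exceeded. Eviction order equals insertion order.
#'
#' @param memory An [xbm_new()] object.
#' @param embeddings Matrix `embed_dim x n` (snapshots; copied).
#' @param labels Character vector of patient ids, length n.
#' @param ids Optional image ids, length n; stored so that an image seen
#'   again in a later batch is never paired against its own stale
#'   embedding.
#' @return The updated `xbm`.
#' @export
xbm_update <- function(memory, embeddings, labels, ids = NULL) {
  embeddings <- as.matrix(embeddings)
  assert_that(ncol(embeddings) == length(labels),
              "embeddings and labels must have equal length")
  if (is.null(ids)) ids <- rep(NA_character_, length(labels))
  assert_that(length(ids) == length(labels),
              "ids and labels must have equal length")
  if (memory$capacity == 0L) return(memory)
  emb <- cbind(memory$embeddings, embeddings)
  lab <- c(memory$labels, as.character(labels))
  mid <- c(memory$ids, as.character(ids))
  n <- length(lab)
  if (n > memory$capacity) {
    keep <- (n - memory$capacity + 1L):n
    emb <- emb[, keep, drop = FALSE]
    lab <- lab[keep]
    mid <- mid[keep]
  }
  memory$embeddings <- emb
  memory$labels <- lab
  memory$ids <- mid
  memory
}

#' @export
print.xbm <- function(x, ...) {
  cat(sprintf("<xbm> %d / %d embeddings\n", length(x$labels), x$capacity))
  invisible(x)
}
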