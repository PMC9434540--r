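# Retrieval-side evaluation: gallery construction, Euclidean-distance
# ranking with deterministic tie-breaking, and the retrieval metrics
# mAP@R, R-Precision and Precision@1.

#' Build a gallery index from a cohort
#'
#' Embeds every image of the cohort with the retrieval branch at the given
#' input side and stores the embeddings with their image and patient ids.
#'
#' @param model A [siamese_retriever()] (or `retriever_fit$model`).
#' @param cohort A `cohort`.
#' @param input_side Evaluation resolution; adaptive pooling lets one model
#'   serve any side length.
#' @param batch_size Images per forward batch.
#' @param l2_normalize If TRUE, embeddings are L2-normalized before
#'   distance computation (default FALSE: raw Euclidean distance).
#' @return Object of class `gallery_index`: `ids`, `patient_ids`,
#'   `embeddings` (n x embed_dim matrix).
#' @export
embed_cohort <- function(model, cohort, input_side = 64L,
                         batch_size = 64L, l2_normalize = FALSE) {
  tensor <- cohort_tensor(cohort, input_side)
  n <- length(tensor$ids)
  emb <- matrix(0, n, model$spec$embed_dim)
  for (s in seq(1L, n, batch_size)) {
    e <- min(s + batch_size - 1L, n)
    emb[s:e, ] <- t(embed_retrieval(model,
                                    tensor$x[, , , s:e, drop = FALSE]))
  }
  gallery_index(tensor$ids, cohort$records$patient_id, emb,
                l2_normalize = l2_normalize)
}

#' Construct a gallery index from precomputed embeddings
#'
#' @param ids Image ids (unique).
#' @param patient_ids Aligned patient ids.
#' @param embeddings Matrix, one row per image.
#' @param l2_normalize L2-normalize rows before use.
#' @return Object of class `gallery_index`.
#' @export
gallery_index <- function(ids, patient_ids, embeddings,
                          l2_normalize = FALSE) {
  embeddings <- as.matrix(embeddings)
  assert_that(length(ids) == nrow(embeddings) &&
                length(patient_ids) == nrow(embeddings),
              "ids, patient_ids and embeddings must be aligned")
  assert_that(all(is.finite(embeddings)), "embeddings must be finite")
  if (l2_normalize) {
    nrm <- sqrt(rowSums(embeddings^2))
    nrm[nrm == 0] <- 1
    embeddings <- embeddings / nrm
  }
  dimnames(embeddings) <- NULL
  structure(list(ids = as.character(ids),
                 patient_ids = as.character(patient_ids),
                 embeddings = embeddings),
            class = "gallery_index")
}

#' Rank a gallery against one query by embedding distance
#'
#' The query image itself is excluded from its gallery; remaining entries
#' are sorted by ascending Euclidean distance, ties broken by ascending
#' image id for determinism. An entry is relevant when it shares the
#' query's patient id.
#'
#' @param gallery A [gallery_index()] containing the query.
#' @param query_id Image id of the query.
#' @return Object of class `ranked_retrieval`: `query_id`, `ranked_ids`,
#'   `distances`, `relevance` (0/1), `R` (number of relevant entries).
#' @export
rank_by_distance <- function(gallery, query_id) {
  qi <- match(query_id, gallery$ids)
  assert_that(!is.na(qi), paste0("query id not in gallery: ", query_id))
  assert_that(length(gallery$ids) >= 2,
              "gallery must contain at least one non-query entry")
  q <- gallery$embeddings[qi, ]
  d <- sqrt(rowSums(sweep(gallery$embeddings, 2, q)^2))
  keep <- setdiff(seq_along(gallery$ids), qi)
  ord <- keep[order(d[keep], gallery$ids[keep])]
  rel <- as.integer(gallery$patient_ids[ord] == gallery$patient_ids[qi])
  structure(list(query_id = query_id, ranked_ids = gallery$ids[ord],
                 distances = d[ord], relevance = rel, R = sum(rel)),
            class = "ranked_retrieval")
}

#' R-Precision of one ranked retrieval
#'
#' The fraction `r / R` of relevant items within the first `R` ranks,
#' where `R` is the number of relevant gallery entries for the query.
#'
#' @param rr A [rank_by_distance()] result with `R >= 1`.
#' @return Value in `[0, 1]`.
#' @export
r_precision <- function(rr) {
  assert_that(rr$R >= 1, "r_precision requires R >= 1")
  sum(rr$relevance[seq_len(rr$R)]) / rr$R
}

#' Average precision at R of one ranked retrieval
#'
#' `AP@R = (1/R) * sum_{i=1..R} P@i * rel@i` where `P@i` is the precision
#' over the first i ranks and `rel@i` indicates relevance at rank i. By
#' default the sum runs over the first `R` RANKS, so relevant items beyond
#' rank R contribute zero; `domain = "relevant"` instead sums the
#' precision at the ranks of the first R relevant items wherever they sit
#' in the list (the alternative reading of an average "over all R relevant
#' samples").
#'
#' @param rr A [rank_by_distance()] result with `R >= 1`.
#' @param domain `"ranks"` (default) or `"relevant"`.
#' @return Value in `[0, 1]`.
#' @export
average_precision_at_r <- function(rr, domain = c("ranks", "relevant")) {
  domain <- match.arg(domain)
  assert_that(rr$R >= 1, "average_precision_at_r requires R >= 1")
  rel <- rr$relevance
  prec <- cumsum(rel) / seq_along(rel)
  if (domain == "ranks") {
    i <- seq_len(min(rr$R, length(rel)))
    sum(prec[i] * rel[i]) / rr$R
  } else {
    at <- which(rel == 1)
    sum(prec[at]) / rr$R
  }
}

#' Mean average precision at R over queries
#'
#' @param rrs List of `ranked_retrieval` objects (each with `R >= 1`).
#' @param domain Passed to [average_precision_at_r()].
#' @return Arithmetic mean of AP@R.
#' @export
mean_ap_at_r <- function(rrs, domain = "ranks") {
  assert_that(length(rrs) >= 1, "need at least one retained query")
  mean(vapply(rrs, average_precision_at_r, 0, domain = domain))
}

#' Precision at rank 1 over queries
#'
#' Fraction of queries whose nearest gallery neighbour shares the query's
#' patient identity.
#'
#' @param rrs List of `ranked_retrieval` objects.
#' @return Value in `[0, 1]`.
#' @export
precision_at_1 <- function(rrs) {
  assert_that(length(rrs) >= 1, "need at least one query")
  mean(vapply(rrs, function(rr) rr$relevance[1], 0L))
}

#' Retrieval metrics of a gallery (every image used as query)
#'
#' Each image queries the gallery of all other images. Queries with no
#' relevant gallery entry (single-image patients in the evaluation cohort,
#' R = 0) are excluded from all three metrics; their count is reported.
#'
#' @param gallery A [gallery_index()].
#' @param domain Passed to [average_precision_at_r()].
#' @return Object of class `retrieval_report`: `map_at_r`, `r_precision`,
#'   `precision_at_1`, `n_queries`, `n_excluded`.
#' @export
evaluate_gallery <- function(gallery, domain = "ranks") {
  rrs <- lapply(gallery$ids, function(id) rank_by_distance(gallery, id))
  keep <- vapply(rrs, function(rr) rr$R >= 1, TRUE)
  assert_that(any(keep), "no query has a relevant gallery entry")
  rrs <- rrs[keep]
  structure(list(
    map_at_r = mean_ap_at_r(rrs, domain = domain),
    r_precision = mean(vapply(rrs, r_precision, 0)),
    precision_at_1 = precision_at_1(rrs),
    n_queries = length(rrs), n_excluded = sum(!keep)),
    class = "retrieval_report")
}

#' End-to-end retrieval evaluation of a cohort
#'
#' Embeds every image of the cohort at `input_side` and reports mAP@R,
#' R-Precision and Precision@1 with every image as a query against all
#' others.
#'
#' @inheritParams embed_cohort
#' @param domain Passed to [average_precision_at_r()].
#' @return A `retrieval_report`.
#' @export
evaluate_retrieval <- function(model, cohort, input_side = 64L,
                               l2_normalize = FALSE, domain = "ranks") {
  assert_that(any(lengths(cohort$patient_index) >= 2),
              "cohort has no multi-image patients")
  evaluate_gallery(embed_cohort(model, cohort, input_side,
                                l2_normalize = l2_normalize),
                   domain = domain)
}

#' @export
print.retrieval_report <- function(x, ...) {
  cat(sprintf(
    "<retrieval_report> mAP@R %.4f  R-Precision %.4f  Precision@1 %.4f (%d queries, %d excluded)\n",
    x$map_at_r, x$r_precision, x$precision_at_1, x$n_queries,
    x$n_excluded))
  invisible(x)
}

#' Write per-query ranked lists as CSV
#'
#' Columns: `query_id`, `rank`, `gallery_id`, `distance`, `relevant`.
#'
#' @param gallery A `gallery_index`.
#' @param path Output CSV path.
#' @param top_k Ranks to keep per query (default all).
#' @return `path`, invisibly.
#' @export
write_ranked_lists <- function(gallery, path, top_k = Inf) {
  rows <- lapply(gallery$ids, function(id) {
    rr <- rank_by_distance(gallery, id)
    k <- min(top_k, length(rr$ranked_ids))
    data.frame(query_id = id, rank = seq_len(k),
               gallery_id = rr$ranked_ids[seq_len(k)],
               distance = rr$distances[seq_len(k)],
               relevant = rr$relevance[seq_len(k)],
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a retrieval report as JSON
#' @param report A `retrieval_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_retrieval_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
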