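# Fixtures built in code: small in-memory cohorts for pair/metric tests
# and cached on-disk phantom cohorts for image-dependent tests.

# cohort of n_patients, each with a fixed number of images; no image files
# on disk (image_path is synthetic) — suitable for everything that never
# touches pixels
toy_cohort <- function(n_patients = 3, images_each = 2, seed = 1) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(n_patients), function(p) {
    k <- if (length(images_each) == 1) images_each
         else images_each[((p - 1) %% length(images_each)) + 1]
    data.frame(
      image_id = sprintf("%05d_%03d", p, seq_len(k) - 1),
      patient_id = as.character(p),
      follow_up_index = seq_len(k) - 1L,
      age_years = 40L + p + seq_len(k) - 1L,
      sex = c("M", "F")[p %% 2 + 1],
      view = "PA",
      image_path = sprintf("/nonexistent/%05d_%03d.png", p,
                           seq_len(k) - 1),
      stringsAsFactors = FALSE)
  }))
  rows$findings <- rep(list("No Finding"), nrow(rows))
  new_cohort(rows)
}

# cached phantom cohorts keyed by config so repeated test files reuse them
phantom_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function(n_patients = 12, side = 64, seed = 5, ...) {
    key <- paste(n_patients, side, seed, ..., sep = "_")
    if (is.null(cache[[key]])) {
      dir <- file.path(tempdir(),
                       paste0("xrayid_fixture_", gsub("[^0-9a-zA-Z_.]", "-",
                                                      key)))
      cfg <- phantom_config(n_patients = n_patients, side = side,
                            seed = seed, ...)
      cache[[key]] <- generate_cohort(cfg, dir)
    }
    cache[[key]]
  }
})

# independent brute-force AUC: mean pairwise comparison with 0.5 for ties
auc_oracle <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(sp) * length(sn))
}

# independent brute-force retrieval metrics: re-enumerates distances,
# orderings and precision curves with plain loops
retrieval_oracle <- function(ids, pids, emb) {
  n <- length(ids)
  aps <- c(); rps <- c(); p1 <- c()
  for (q in seq_len(n)) {
    d <- rep(NA_real_, n)
    for (g in seq_len(n)) {
      if (g != q) d[g] <- sqrt(sum((emb[q, ] - emb[g, ])^2))
    }
    others <- setdiff(seq_len(n), q)
    ord <- others[order(d[others], ids[others])]
    rel <- as.integer(pids[ord] == pids[q])
    R <- sum(rel)
    if (R == 0) next
    prec <- cumsum(rel) / seq_along(rel)
    aps <- c(aps, sum(prec[1:R] * rel[1:R]) / R)
    rps <- c(rps, sum(rel[1:R]) / R)
    p1 <- c(p1, rel[1])
  }
  list(map_at_r = mean(aps), r_precision = mean(rps),
       precision_at_1 = mean(p1), n_queries = length(aps))
}
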