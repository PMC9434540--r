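# Gallery ranking and the mAP@R / R-Precision / Precision@1 metrics.

# build a ranked_retrieval directly from a relevance pattern
rr_of <- function(relevance, R = sum(relevance)) {
  structure(list(query_id = "q",
                 ranked_ids = sprintf("g%d", seq_along(relevance)),
                 distances = seq_along(relevance),
                 relevance = as.integer(relevance), R = R),
            class = "ranked_retrieval")
}

test_that("ranking is by distance with id tie-breaks and self-exclusion", {
  emb <- rbind(q = c(0, 0), a = c(1, 0), b = c(0, 2), c = c(1, 0),
               d = c(3, 0))
  g <- gallery_index(c("q", "a", "b", "c", "d"),
                     c("p1", "p1", "p2", "p2", "p1"), emb)
  rr <- rank_by_distance(g, "q")
  expect_false("q" %in% rr$ranked_ids)
  expect_equal(rr$ranked_ids, c("a", "c", "b", "d"))  # tie a/c by id
  expect_equal(rr$distances, c(1, 1, 2, 3))
  expect_equal(rr$relevance, c(1L, 0L, 0L, 1L))
  expect_equal(rr$R, 2L)
  # identical embedding lands at rank 1 with distance 0
  g2 <- gallery_index(c("q", "z"), c("p", "p"), rbind(c(5, 5), c(5, 5)))
  rr2 <- rank_by_distance(g2, "q")
  expect_equal(rr2$distances, 0)
  # invariant to gallery permutation
  perm <- c(3, 5, 1, 2, 4)
  gp <- gallery_index(g$ids[perm], g$patient_ids[perm],
                      g$embeddings[perm, ])
  expect_equal(rank_by_distance(gp, "q")$ranked_ids, rr$ranked_ids)
})

test_that("R-Precision and AP@R match hand-worked examples", {
  expect_equal(r_precision(rr_of(c(1, 1, 1, 1))), 1)
  expect_equal(r_precision(rr_of(c(1, 1, 1, 0), R = 4)), 0.75)
  expect_equal(r_precision(rr_of(c(0, 0, 0, 1, 1), R = 3)), 0)
  # R = 2, hits at ranks 1 and 3: (1/2) * (1 * 1 + 0) = 0.5
  expect_equal(average_precision_at_r(rr_of(c(1, 0, 1), R = 2)), 0.5)
  # R = 2, hit only at rank 2 within top R: (1/2) * (1/2) = 0.25
  expect_equal(average_precision_at_r(rr_of(c(0, 1, 1), R = 2)), 0.25)
  expect_equal(average_precision_at_r(rr_of(c(1, 1))), 1)
  # alternative reading sums precision at the relevant ranks themselves
  expect_equal(average_precision_at_r(rr_of(c(1, 0, 1), R = 2),
                                      domain = "relevant"),
               (1 + 2 / 3) / 2)
})

test_that("mean AP@R and Precision@1 aggregate as plain means", {
  rrs <- list(rr_of(c(1, 1)), rr_of(c(0, 1, 1), R = 2))
  expect_equal(mean_ap_at_r(rrs), (1 + 0.25) / 2)
  expect_equal(precision_at_1(list(rr_of(1), rr_of(1), rr_of(1),
                                   rr_of(c(0, 1)))), 0.75)
})

test_that("all three metrics equal the brute-force oracle on random galleries", {
  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(4:12, 1)
    pids <- sprintf("p%d", sample(1:4, n, replace = TRUE))
    while (max(table(pids)) < 2) {
      pids <- sprintf("p%d", sample(1:4, n, replace = TRUE))
    }
    ids <- sprintf("img%02d", seq_len(n))
    emb <- matrix(round(rnorm(n * 3), 1), n, 3)  # rounding forces ties
    g <- gallery_index(ids, pids, emb)
    got <- evaluate_gallery(g)
    want <- retrieval_oracle(ids, pids, emb)
    expect_equal(got$map_at_r, want$map_at_r, tolerance = 1e-12)
    expect_equal(got$r_precision, want$r_precision, tolerance = 1e-12)
    expect_equal(got$precision_at_1, want$precision_at_1,
                 tolerance = 1e-12)
    expect_equal(got$n_queries, want$n_queries)
  }
})

test_that("metrics are invariant under global isometries of the embedding", {
  set.seed(7)
  n <- 10
  emb <- matrix(rnorm(n * 5), n, 5)
  pids <- sprintf("p%d", rep(1:5, each = 2))
  ids <- sprintf("i%d", 1:n)
  base <- evaluate_gallery(gallery_index(ids, pids, emb))
  rot <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  moved <- emb %*% rot + matrix(3, n, 5)
  iso <- evaluate_gallery(gallery_index(ids, pids, moved))
  expect_equal(iso$map_at_r, base$map_at_r, tolerance = 1e-9)
  expect_equal(iso$r_precision, base$r_precision, tolerance = 1e-9)
  expect_equal(iso$precision_at_1, base$precision_at_1, tolerance = 1e-9)
})

test_that("duplicating the gallery never lowers Precision@1; R=0 queries are excluded", {
  set.seed(9)
  n <- 8
  emb <- matrix(rnorm(n * 4), n, 4)
  pids <- sprintf("p%d", c(1, 1, 2, 2, 3, 3, 4, 5))
  ids <- sprintf("i%d", 1:n)
  base <- evaluate_gallery(gallery_index(ids, pids, emb))
  expect_equal(base$n_excluded, 2)  # patients 4 and 5 are singletons
  dup <- gallery_index(c(ids, paste0(ids, "_dup")), c(pids, pids),
                       rbind(emb, emb))
  dd <- evaluate_gallery(dup)
  expect_gte(dd$precision_at_1, base$precision_at_1)
  expect_equal(dd$n_excluded, 0)
  g1 <- gallery_index(c("a", "b"), c("x", "y"), rbind(c(0, 0), c(1, 1)))
  expect_error(evaluate_gallery(g1), "no query")
})

test_that("noisier embeddings never improve the oracle metrics (seeded trend)", {
  set.seed(13)
  n <- 16
  pids <- sprintf("p%d", rep(1:4, each = 4))
  ids <- sprintf("i%02d", 1:n)
  centers <- matrix(rnorm(4 * 6, sd = 4), 4, 6)
  clean <- centers[rep(1:4, each = 4), ]
  maps <- vapply(c(0.1, 2, 8), function(sd) {
    res <- replicate(5, {
      noisy <- clean + matrix(rnorm(n * 6, sd = sd), n, 6)
      evaluate_gallery(gallery_index(ids, pids, noisy))$map_at_r
    })
    mean(res)
  }, 0)
  expect_true(all(diff(maps) <= 0.02))
  expect_gt(maps[1], maps[3])
})

test_that("ranked lists and reports serialize to CSV/JSON", {
  set.seed(2)
  g <- gallery_index(sprintf("i%d", 1:6), sprintf("p%d", rep(1:3, 2)),
                     matrix(rnorm(12), 6, 2))
  csv <- tempfile(fileext = ".csv")
  write_ranked_lists(g, csv, top_k = 3)
  df <- utils::read.csv(csv)
  expect_equal(nrow(df), 18)
  expect_true(all(df$rank <= 3))
  rep_ <- evaluate_gallery(g)
  p <- tempfile(fileext = ".json")
  write_retrieval_report(rep_, p)
  expect_equal(jsonlite::read_json(p)$map_at_r, rep_$map_at_r)
})
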