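# Offline and online pair mining.

test_that("positive mining enumerates all same-patient combinations", {
  co <- toy_cohort(n_patients = 1, images_each = 4)
  expect_equal(nrow(mine_positive_pairs(co)), choose(4, 2))
  expect_equal(nrow(mine_positive_pairs(toy_cohort(1, 1))), 0)
  # property: matches a brute-force double loop on random cohorts
  for (seed in 1:5) {
    set.seed(seed)
    sizes <- sample(1:5, 6, replace = TRUE)
    co <- toy_cohort(n_patients = 6, images_each = sizes, seed = seed)
    got <- mine_positive_pairs(co)
    ids <- co$records$image_id
    pid <- co$records$patient_id
    brute <- 0
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i < j && pid[i] == pid[j]) brute <- brute + 1
    }
    expect_equal(nrow(got), brute)
    expect_true(all(got$label == 1))
    expect_true(all(got$first_id != got$second_id))
  }
})

test_that("negative sampling draws distinct cross-patient pairs deterministically", {
  co2 <- toy_cohort(n_patients = 2, images_each = 1)
  one <- sample_negative_pairs(co2, 1, seed = 3)
  expect_equal(nrow(one), 1)
  expect_equal(one$label, 0L)
  # 3 patients x 2 images: the full cross universe has 2*2*3 = 12 pairs
  co <- toy_cohort(n_patients = 3, images_each = 2)
  all12 <- sample_negative_pairs(co, 12, seed = 1)
  expect_equal(nrow(all12), 12)
  expect_equal(anyDuplicated(paste(all12$first_id, all12$second_id)), 0)
  pid <- stats::setNames(co$records$patient_id, co$records$image_id)
  expect_true(all(pid[all12$first_id] != pid[all12$second_id]))
  expect_error(sample_negative_pairs(co, 13, seed = 1), "exceeds")
  # determinism
  a <- sample_negative_pairs(co, 5, seed = 9)
  b <- sample_negative_pairs(co, 5, seed = 9)
  expect_identical(a, b)
})

test_that("epoch assembly is balanced; FTS reuses negatives, RNP redraws them", {
  co <- toy_cohort(n_patients = 30, images_each = 3, seed = 2)
  pos <- mine_positive_pairs(co)
  fts <- mining_config("FTS", n_s = 40, seed = 5)
  rnp <- mining_config("RNP", n_s = 40, seed = 5)
  e1 <- assemble_epoch_pairs(co, pos, fts, 1)
  e2 <- assemble_epoch_pairs(co, pos, fts, 2)
  expect_identical(e1, e2)
  r1 <- assemble_epoch_pairs(co, pos, rnp, 1)
  r2 <- assemble_epoch_pairs(co, pos, rnp, 2)
  for (e in list(e1, r1, r2)) {
    expect_equal(sum(e$label == 1), 20)
    expect_equal(sum(e$label == 0), 20)
  }
  # positives identical across epochs in both modes
  expect_identical(r1[r1$label == 1, ], r2[r2$label == 1, ])
  expect_identical(e1[e1$label == 1, ], r1[r1$label == 1, ])
  # negatives differ across RNP epochs (large negative universe)
  k1 <- paste(r1$first_id, r1$second_id)[r1$label == 0]
  k2 <- paste(r2$first_id, r2$second_id)[r2$label == 0]
  expect_false(setequal(k1, k2))
  expect_error(assemble_epoch_pairs(co, pos[1:2, ],
                                    mining_config("FTS", 40, 1), 1),
               "insufficient positives")
  expect_error(mining_config("FTS", n_s = 7), "even")
})

test_that("distinct RNP negatives accumulate over epochs beyond the FTS count", {
  co <- toy_cohort(n_patients = 20, images_each = 3, seed = 3)
  pos <- mine_positive_pairs(co)
  rnp <- mining_config("RNP", n_s = 40, seed = 8)
  fts_neg <- 20
  seen <- character(0)
  for (ep in 1:4) {
    e <- assemble_epoch_pairs(co, pos, rnp, ep)
    seen <- union(seen, paste(e$first_id, e$second_id)[e$label == 0])
  }
  expect_gte(length(seen), fts_neg)
  expect_lte(length(seen), 4 * fts_neg)
  expect_gt(length(seen), fts_neg)  # large universe: strictly more w.h.p.
})

test_that("online enumeration counts intra-batch and memory pairs", {
  b32 <- sprintf("p%02d", 1:32)
  expect_equal(nrow(enumerate_online_pairs(b32)), choose(32, 2))
  mem <- sprintf("p%02d", rep(1:16, each = 8))
  both <- enumerate_online_pairs(b32, mem)
  expect_equal(nrow(both), choose(32, 2) + 32 * 128)
  expect_equal(nrow(enumerate_online_pairs("p1")), 0)
  # labels follow patient equality
  tiny <- enumerate_online_pairs(c("a", "a", "b"), c("b", "c"))
  batch <- tiny[tiny$kind == "batch", ]
  expect_equal(batch$y, c(1L, 0L, 0L))
  memp <- tiny[tiny$kind == "memory", ]
  expect_equal(memp$y[memp$i == 3 & memp$j == 1], 1L)
  expect_equal(sum(memp$y), 1L)
})

test_that("pair manifests round-trip through CSV", {
  co <- toy_cohort(n_patients = 4, images_each = 2)
  pos <- mine_positive_pairs(co)
  csv <- tempfile(fileext = ".csv")
  write_pairs(pos, csv)
  expect_identical(read_pairs(csv), pos)
})
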