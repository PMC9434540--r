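# Thresholding, confusion statistics, ROC/AUC, bootstrap CI, subgroup TPR.

test_that("classification thresholds with ties counted positive", {
  expect_equal(classify(c(0.2, 0.5, 0.9), 0.5), c(0L, 1L, 1L))
  expect_equal(classify(rep(0.5, 4), 0.5), rep(1L, 4))
  s <- runif(50)
  expect_equal(classify(s, 0.5), classify(plogis(10 * (s - 0.5)),
                                          plogis(0)))
  expect_error(classify(s, 0), "threshold")
})

test_that("confusion metrics reproduce published printed values exactly", {
  tab <- published_verification_counts()
  for (i in seq_len(nrow(tab))) {
    m <- confusion_metrics(list(tp = tab$tp[i], fn = tab$fn[i],
                                tn = tab$tn[i], fp = tab$fp[i]))
    for (nm in c("accuracy", "specificity", "recall", "precision", "f1")) {
      # half-ULP slack: several printed values sit exactly on a rounding
      # boundary, and printed F1 scores derive from rounded components
      expect_lt(abs(m[[nm]] - tab[[nm]][i]), 5.1e-5)
    }
  }
})

test_that("confusion metrics handle perfect and degenerate cases", {
  perfect <- confusion_metrics(list(tp = 10, fn = 0, tn = 20, fp = 0))
  expect_true(all(unlist(perfect) == 1))
  nopos <- confusion_metrics(list(tp = 0, fn = 0, tn = 5, fp = 0))
  expect_true(is.na(nopos$recall))
  expect_true(is.na(nopos$precision))
  expect_equal(nopos$accuracy, 1)
  cc <- confusion_counts(c(1, 0, 1, 0), c(1, 1, 0, 0))
  expect_equal(unclass(cc)[c("tp", "fn", "tn", "fp")],
               list(tp = 1L, fn = 1L, tn = 1L, fp = 1L),
               ignore_attr = TRUE)
})

test_that("roc_auc equals the exhaustive pairwise oracle (incl. ties)", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)),
               auc_oracle(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)),
               tolerance = 1e-12)
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:50, 1)
    sc <- round(runif(n), 2)       # coarse scores force ties
    lb <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(roc_auc(sc, lb), auc_oracle(sc, lb), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("roc_auc is invariant under strictly monotone transforms", {
  set.seed(5)
  sc <- runif(40)
  lb <- rbinom(40, 1, 0.5)
  lb[1:2] <- c(0, 1)
  a <- roc_auc(sc, lb)
  expect_equal(roc_auc(exp(3 * sc), lb), a, tolerance = 1e-12)
  expect_equal(roc_auc(rank(sc), lb), a, tolerance = 1e-12)
})

test_that("roc_auc agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  sc <- runif(200)
  lb <- rbinom(200, 1, 0.4)
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(sc, lb), ref, tolerance = 1e-10)
})

test_that("bootstrap interval degenerates on separable data and brackets the AUC", {
  ci <- bootstrap_auc_ci(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1),
                         B = 200, seed = 1)
  expect_equal(ci$low, 1)
  expect_equal(ci$high, 1)
  set.seed(2)
  sc <- c(rnorm(60, 1), rnorm(60))
  lb <- rep(1:0, each = 60)
  hits <- 0
  for (s in 1:10) {
    ci <- bootstrap_auc_ci(sc, lb, B = 300, seed = s)
    a <- roc_auc(sc, lb)
    hits <- hits + (ci$low <= a && a <= ci$high)
  }
  expect_gte(hits, 9)
  expect_error(bootstrap_auc_ci(sc, lb, B = 10), "B must")
})

test_that("a single all-encompassing age bin reproduces the overall recall", {
  co <- phantom_fixture(n_patients = 10, seed = 31)
  pos <- mine_positive_pairs(co)
  set.seed(3)
  scores <- runif(nrow(pos), 0.3, 1)
  res <- subgroup_tpr(pos, scores, co, "age_gap_years",
                      bins = c(0, 100))
  overall <- mean(classify(scores) == 1)
  expect_equal(nrow(res), 1)
  expect_equal(res$tpr, overall)
  expect_equal(res$p, nrow(pos))
})

test_that("view-change and disease-change subgroups bin as defined", {
  rec <- data.frame(
    image_id = c("a0", "a1", "b0", "b1"),
    patient_id = c("a", "a", "b", "b"),
    follow_up_index = c(0L, 1L, 0L, 1L),
    age_years = c(50L, 52L, 60L, 60L),
    sex = "M", view = c("PA", "AP", "PA", "PA"),
    image_path = "x", stringsAsFactors = FALSE)
  rec$findings <- list("No Finding", c("Effusion", "Mass"), "Nodule",
                       "Nodule")
  co <- new_cohort(rec)
  pairs <- data.frame(first_id = c("a0", "b0"), second_id = c("a1", "b1"),
                      label = 1L)
  scores <- c(0.9, 0.2)
  vw <- subgroup_tpr(pairs, scores, co, "view_change")
  expect_equal(vw$tpr[vw$bin == "view change"], 1)
  expect_equal(vw$tpr[vw$bin == "same view"], 0)
  dc <- subgroup_tpr(pairs, scores, co, "disease_change")
  # pair a contributes to both new findings; pair b to "no change"
  expect_setequal(dc$bin, c("Effusion", "Mass", "no change"))
  expect_equal(dc$tpr[dc$bin == "Effusion"], 1)
  expect_equal(dc$tpr[dc$bin == "no change"], 0)
})

test_that("verification report assembles finite, consistent fields", {
  set.seed(4)
  sc <- c(runif(40, 0.5, 1), runif(40, 0, 0.5))
  lb <- rep(1:0, each = 40)
  rep_ <- verification_report(sc, lb, B = 200, seed = 2)
  expect_gte(rep_$auc, rep_$ci_low - 0.05)
  expect_lte(rep_$auc, rep_$ci_high + 0.05)
  expect_true(all(unlist(rep_[c("accuracy", "specificity", "recall",
                                "precision", "f1")]) >= 0))
  p <- tempfile(fileext = ".json")
  write_verification_report(rep_, p)
  back <- jsonlite::read_json(p)
  expect_equal(back$auc, rep_$auc)
})
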