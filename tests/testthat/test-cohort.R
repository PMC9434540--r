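# Cohort data model, metadata I/O, image loading and patient-wise splits.

write_toy_csv <- function(path, rows) {
  df <- data.frame(
    check.names = FALSE, stringsAsFactors = FALSE,
    `Image Index` = rows$img, `Finding Labels` = rows$find,
    `Follow-up #` = rows$fu, `Patient ID` = rows$pid,
    `Patient Age` = rows$age, `Patient Gender` = rows$sex,
    `View Position` = rows$view)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

test_that("load_metadata parses the chest X-ray dialect and builds the patient index", {
  csv <- write_toy_csv(tempfile(fileext = ".csv"), list(
    img = c("a_000.png", "a_001.png", "b_000.png"),
    find = c("No Finding", "Effusion|Nodule", "Mass"),
    fu = 0:2 * c(0, 1, 0), pid = c("1", "1", "2"),
    age = c(50L, 51L, 60L), sex = c("M", "M", "F"),
    view = c("PA", "ap", "XX")))
  co <- load_metadata(csv)
  expect_equal(n_images(co), 3)
  expect_equal(n_patients(co), 2)
  expect_equal(sort(names(co$patient_index)), c("1", "2"))
  expect_equal(co$records$image_id, c("a_000", "a_001", "b_000"))
  expect_equal(co$records$view, c("PA", "AP", "unknown"))
  expect_equal(co$records$findings[[2]], c("Effusion", "Nodule"))
})

test_that("schema and integrity violations are reported by name", {
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = 1), csv, row.names = FALSE)
  expect_error(load_metadata(csv), "Image Index")
  csv2 <- write_toy_csv(tempfile(fileext = ".csv"), list(
    img = c("a_000.png", "a_000.png"), find = c("No Finding", "No Finding"),
    fu = c(0L, 1L), pid = c("1", "2"), age = c(5L, 6L),
    sex = c("M", "F"), view = c("PA", "PA")))
  expect_error(load_metadata(csv2), "duplicate image_id")
  expect_error(load_metadata(tempfile()), "not found")
})

test_that("metadata round-trips exactly through write and re-load", {
  co <- phantom_fixture(n_patients = 8, seed = 21)
  csv <- tempfile(fileext = ".csv")
  write_metadata(co, csv)
  co2 <- load_metadata(csv, image_dir = dirname(co$records$image_path[1]))
  expect_equal(co2$records$image_id, co$records$image_id)
  expect_equal(co2$records$patient_id, co$records$patient_id)
  expect_equal(co2$records$follow_up_index, co$records$follow_up_index)
  expect_equal(co2$records$age_years, co$records$age_years)
  expect_equal(co2$records$sex, co$records$sex)
  expect_equal(co2$records$view, co$records$view)
  expect_equal(co2$records$findings, co$records$findings)
})

test_that("load_image returns an 8-bit grid, reduces colour, keeps zeros", {
  px <- matrix(0:255, 16, 16) %% 256
  p <- tempfile(fileext = ".png")
  png::writePNG(px / 255, p)
  rec <- list(image_path = p, image_id = "t")
  got <- load_image(rec)
  expect_equal(dim(got), c(16, 16))
  expect_true(all(got >= 0 & got <= 255))
  # colour JPG reduced to one luminance channel
  rgb <- array(runif(12 * 12 * 3), c(12, 12, 3))
  pj <- tempfile(fileext = ".jpg")
  jpeg::writeJPEG(rgb, pj, quality = 1)
  gj <- load_image(list(image_path = pj, image_id = "c"))
  expect_equal(dim(gj), c(12, 12))
  # all-zero image stays all zero (no normalization at this stage)
  pz <- tempfile(fileext = ".png")
  png::writePNG(matrix(0, 8, 8), pz)
  expect_true(all(load_image(list(image_path = pz, image_id = "z")) == 0))
  # unreadable file carries the image id
  expect_error(load_image(list(image_path = "/nope.png", image_id = "xx")),
               "xx")
})

test_that("prepare_model_input resizes, replicates channels and standardizes", {
  px <- matrix(255, 32, 32)
  out <- prepare_model_input(px, side = 16, channel_mean = c(0, 0, 0),
                             channel_sd = c(1, 1, 1))
  expect_equal(dim(out), c(16, 16, 3))
  expect_equal(out[, , 1], out[, , 2])  # constant input: channels equal
  expect_true(all(abs(out - 1) < 1e-12))
  big <- prepare_model_input(matrix(runif(1024), 32, 32), side = 256)
  expect_equal(dim(big), c(256, 256, 3))
  # preparing an already side-sized image keeps content ordering
  x <- matrix(seq(0, 255, length.out = 64), 8, 8)
  same <- prepare_model_input(x, side = 8, channel_mean = c(0, 0, 0),
                              channel_sd = c(1, 1, 1))
  expect_equal(same[, , 1], x / 255)
  expect_error(prepare_model_input(matrix(1, 4, 4), side = 4), "side")
  expect_error(prepare_model_input(matrix(numeric(0), 0, 0), side = 16),
               "grid")
})

test_that("patient-wise split hits exact patient fractions and is leakage-free", {
  co <- toy_cohort(n_patients = 10, images_each = 1)
  sp <- patient_wise_split(co, c(0.7, 0.1, 0.2), seed = 4)
  expect_equal(n_patients(sp$train), 7)
  expect_equal(n_patients(sp$val), 1)
  expect_equal(n_patients(sp$test), 2)
  # disjoint patients, all records preserved
  co2 <- phantom_fixture(n_patients = 15, seed = 9)
  for (seed in c(1, 2, 3)) {
    sp2 <- patient_wise_split(co2, seed = seed)
    pt <- lapply(sp2[c("train", "val", "test")],
                 function(x) names(x$patient_index))
    expect_length(intersect(pt$train, pt$val), 0)
    expect_length(intersect(pt$train, pt$test), 0)
    expect_length(intersect(pt$val, pt$test), 0)
    expect_equal(n_images(sp2$train) + n_images(sp2$val) +
                   n_images(sp2$test), n_images(co2))
  }
  # determinism
  a <- patient_wise_split(co2, seed = 11)
  b <- patient_wise_split(co2, seed = 11)
  expect_identical(a$train$records$image_id, b$train$records$image_id)
  expect_error(patient_wise_split(toy_cohort(2), c(0.4, 0.3, 0.3)),
               "fewer patients")
})

test_that("an official assignment is honored verbatim", {
  co <- toy_cohort(n_patients = 4, images_each = 2)
  asg <- c("1" = "test", "2" = "train", "3" = "train", "4" = "val")
  sp <- patient_wise_split(co, official_assignment = asg)
  expect_equal(sort(names(sp$train$patient_index)), c("2", "3"))
  expect_equal(names(sp$val$patient_index), "4")
  expect_equal(names(sp$test$patient_index), "1")
  expect_error(patient_wise_split(co, official_assignment = asg[-1]),
               "cover all patients")
})

test_that("split manifests round-trip through CSV", {
  co <- phantom_fixture(n_patients = 8, seed = 21)
  sp <- patient_wise_split(co, seed = 2)
  csv <- tempfile(fileext = ".csv")
  write_split_manifest(sp, csv)
  sp2 <- read_split_manifest(co, csv)
  expect_setequal(sp2$train$records$image_id, sp$train$records$image_id)
  expect_setequal(sp2$test$records$image_id, sp$test$records$image_id)
})
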