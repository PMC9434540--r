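# Synthetic phantom generator: determinism, identity structure, nuisance.

test_that("identity latents are deterministic, distinct and within bounds", {
  a <- sample_identity(3)
  b <- sample_identity(3)
  c <- sample_identity(4)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_true(a$body_a >= 0.75 && a$body_a <= 0.92)
  expect_true(a$rib_count %in% 4:7)
  expect_true(a$lung_left["cx"] < 0 && a$lung_right["cx"] > 0)
})

test_that("rendering is deterministic and respects the canvas contract", {
  lat <- sample_identity(11)
  img1 <- render_image(lat, acquisition_nuisance(), side = 64)
  img2 <- render_image(lat, acquisition_nuisance(), side = 64)
  expect_identical(img1, img2)
  expect_equal(dim(img1), c(64, 64))
  expect_true(all(img1 >= 0 & img1 <= 255))
  expect_true(all(img1 == round(img1)))
  # noise is reproducible through its seed
  nz <- acquisition_nuisance(noise_sd = 0.05, noise_seed = 9)
  expect_identical(render_image(lat, nz, 64), render_image(lat, nz, 64))
  expect_false(identical(render_image(lat, nz, 64),
                         render_image(lat, acquisition_nuisance(
                           noise_sd = 0.05, noise_seed = 10), 64)))
})

test_that("the AP view is the mirrored PA rendering", {
  lat <- sample_identity(12)
  pa <- render_image(lat, acquisition_nuisance(), side = 64)
  ap <- render_image(lat, acquisition_nuisance(view_flip = TRUE),
                     side = 64)
  expect_identical(ap, pa[, 64:1])
  expect_false(identical(ap, pa))  # asymmetric latent: flip is visible
})

test_that("within-identity distance is below between-identity distance", {
  set.seed(1)
  imgs <- lapply(1:20, function(s) {
    lat <- sample_identity(s)
    list(a = render_image(lat, acquisition_nuisance(noise_sd = 0.01,
                                                    noise_seed = s), 64),
         b = render_image(lat, acquisition_nuisance(noise_sd = 0.01,
                                                    noise_seed = s + 100),
                          64))
  })
  within <- mean(vapply(imgs, function(p) mean((p$a - p$b)^2), 0))
  between <- mean(vapply(1:19, function(i) {
    mean((imgs[[i]]$a - imgs[[i + 1]]$a)^2)
  }, 0))
  expect_lt(within, between)
})

test_that("aging drift grows pixel distance monotonically with the year gap", {
  lat <- sample_identity(21)
  base <- render_image(lat, acquisition_nuisance(
    aging_scale_per_year = 0.008, aging_diaphragm_per_year = 0.015,
    age_gap_years = 0), 64)
  dists <- vapply(c(2, 6, 12), function(gap) {
    img <- render_image(lat, acquisition_nuisance(
      aging_scale_per_year = 0.008, aging_diaphragm_per_year = 0.015,
      age_gap_years = gap), 64)
    mean((img - base)^2)
  }, 0)
  expect_true(all(diff(dists) > 0))
})

test_that("generated cohorts are deterministic and carry coherent metadata", {
  cfg <- phantom_config(n_patients = 6, seed = 17)
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  co1 <- generate_cohort(cfg, d1)
  co2 <- generate_cohort(cfg, d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "metadata.csv"))),
                   unname(tools::md5sum(file.path(d2, "metadata.csv"))))
  i1 <- sort(list.files(d1, pattern = "png$"))
  expect_identical(unname(tools::md5sum(file.path(d1, i1))),
                   unname(tools::md5sum(file.path(d2, i1))))
  expect_equal(n_patients(co1), 6)
  # positive-pair yield matches the per-patient image counts
  ks <- lengths(co1$patient_index)
  expect_equal(nrow(mine_positive_pairs(co1)), sum(choose(ks, 2)))
  # images load and ages/follow-ups are coherent
  px <- load_image(co1$records[1, ])
  expect_equal(dim(px), c(64, 64))
  for (p in names(co1$patient_index)) {
    r <- co1$records[co1$records$patient_id == p, ]
    r <- r[order(r$follow_up_index), ]
    expect_true(all(diff(r$age_years) >= 0))
    expect_equal(r$follow_up_index, seq_len(nrow(r)) - 1L)
  }
})

test_that("the image-count distribution averages 3-4 images per patient", {
  co <- phantom_fixture(n_patients = 60, seed = 41)
  m <- mean(lengths(co$patient_index))
  expect_gt(m, 2.5)
  expect_lt(m, 4.5)
  expect_true(all(lengths(co$patient_index) >= 1))
})

test_that("disease marks change pixels and labels jointly", {
  cfg <- phantom_config(n_patients = 25, seed = 77, disease_rate = 0.6)
  co <- generate_cohort(cfg, file.path(tempdir(), "dz"))
  has_dz <- vapply(co$records$findings,
                   function(f) !identical(f, "No Finding"), TRUE)
  expect_gt(sum(has_dz), 0)
  # a record with findings differs from the same nuisance-free identity
  # more than label-free renders do (marks are visible)
  expect_true(any(vapply(co$records$findings[has_dz],
                         function(f) all(f %in%
                           xrayid:::PHANTOM_FINDINGS), TRUE)))
})
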