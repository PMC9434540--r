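# Synthetic chest-phantom cohort generator.
#
# Each patient is an identity latent — a parametric thorax geometry (lung
# ellipses, rib arcs, heart, clavicles, diaphragm dome) — rendered once per
# follow-up under independently sampled acquisition nuisance: windowing
# (contrast/brightness), rotation, scaling, translation, additive noise,
# projection-view flips, an aging drift that grows with the simulated year
# gap, and disease marks that alter pixels and finding labels jointly.
# Metadata is written in the same dialect as large public chest X-ray
# collections, so every other module of the package runs on a phantom
# cohort with no external download.

PHANTOM_FINDINGS <- c("Effusion", "Nodule", "Mass", "Infiltration",
                      "Cardiomegaly", "Atelectasis", "Consolidation",
                      "Pneumothorax")

#' Phantom cohort configuration
#'
#' The defaults define the package's reference desk-scale study
#' conditions: 200 patients averaging 3.5 images each at 64 px, with
#' moderate acquisition nuisance.
#'
#' @param n_patients Number of identities (>= 2).
#' @param side Canvas side length in pixels (>= 32).
#' @param images_per_patient_mean Mean images per patient; counts are
#'   drawn as `1 + Poisson(mean - 1)` (min 1), mimicking follow-up
#'   accrual at an average of 3-4 images per patient.
#' @param rotation_sd Rotation nuisance, degrees (normal sd).
#' @param scale_sd Scale nuisance (normal sd around 1).
#' @param translate_sd Translation nuisance, fraction of the canvas.
#' @param window_center_sd,window_width_sd Windowing nuisance (display
#'   center around 0.5, width factor around 1).
#' @param noise_sd Additive Gaussian pixel noise, intensity units in
#'   `[0, 1]`.
#' @param view_flip_prob Probability a follow-up is acquired in the AP
#'   view (rendered as a horizontal mirror with a shifted heart).
#' @param aging_scale_per_year,aging_diaphragm_per_year Aging drift: body
#'   scale change and diaphragm elevation per simulated year between
#'   follow-ups.
#' @param disease_rate Probability a follow-up introduces a new persistent
#'   disease mark (pixels and finding label change together).
#' @param seed Root seed; all randomness flows from it through named
#'   substreams so any single image is reproducible in isolation.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(n_patients = 200L, side = 64L,
                           images_per_patient_mean = 3.5,
                           rotation_sd = 2, scale_sd = 0.03,
                           translate_sd = 0.02,
                           window_center_sd = 0.05,
                           window_width_sd = 0.10, noise_sd = 0.02,
                           view_flip_prob = 0.15,
                           aging_scale_per_year = 0.008,
                           aging_diaphragm_per_year = 0.015,
                           disease_rate = 0.25, seed = 1L) {
  assert_that(n_patients >= 2, "n_patients must be >= 2")
  assert_that(side >= 32, "side must be >= 32")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  structure(as.list(environment()), class = "phantom_config")
}

#' Low-nuisance phantom configuration
#'
#' The parameter-recovery study condition: the same identity structure as
#' [phantom_config()] but with acquisition nuisance reduced to a level
#' where identity is cleanly recoverable — small windowing, rigid and
#' noise perturbations, no projection-view flips, mild aging drift. Used
#' by the package's training-recovery checks; view-change and heavy-noise
#' behaviour are exercised separately at the moderate default level.
#'
#' @param n_patients,side,seed As in [phantom_config()].
#' @param ... Further overrides passed to [phantom_config()].
#' @return A `phantom_config`.
#' @export
phantom_config_low_nuisance <- function(n_patients = 200L, side = 64L,
                                        seed = 1L, ...) {
  args <- list(n_patients = n_patients, side = side,
               rotation_sd = 1, scale_sd = 0.01, translate_sd = 0.01,
               window_center_sd = 0.02, window_width_sd = 0.04,
               noise_sd = 0.01, view_flip_prob = 0,
               aging_scale_per_year = 0.004,
               aging_diaphragm_per_year = 0.008,
               seed = seed)
  args <- utils::modifyList(args, list(...))   # explicit overrides win
  do.call(phantom_config, args)
}

#' Sample one identity latent
#'
#' Draws the parametric thorax geometry of one phantom patient from
#' documented uniform ranges; deterministic for a given seed.
#'
#' @param seed Integer seed.
#' @return Object of class `identity_latent`.
#' @export
sample_identity <- function(seed = 1L) {
  with_seed(seed, {
    lung <- function(sgn) {
      c(a = stats::runif(1, 0.22, 0.32), b = stats::runif(1, 0.36, 0.5),
        cx = sgn * stats::runif(1, 0.34, 0.46),
        cy = stats::runif(1, -0.2, -0.05))
    }
    structure(list(
      body_a = stats::runif(1, 0.75, 0.92),
      body_b = stats::runif(1, 0.85, 0.98),
      lung_left = lung(-1), lung_right = lung(1),
      rib_count = sample(4:7, 1),
      rib_spacing = stats::runif(1, 0.10, 0.16),
      rib_curv = stats::runif(1, 0.15, 0.45),
      rib_thickness = stats::runif(1, 0.018, 0.032),
      heart = c(a = stats::runif(1, 0.18, 0.28),
                b = stats::runif(1, 0.15, 0.22),
                cx = stats::runif(1, 0.06, 0.18),
                cy = stats::runif(1, 0.08, 0.22)),
      clav_angle_deg = stats::runif(1, 5, 20),
      clav_y = stats::runif(1, -0.58, -0.46),
      diaphragm_y = stats::runif(1, 0.42, 0.58),
      diaphragm_amp = stats::runif(1, 0.05, 0.16)
    ), class = "identity_latent")
  })
}

#' Acquisition nuisance for one phantom render
#'
#' All fields default to the identity transform (zero nuisance).
#'
#' @param rotation_deg,scale,translate_x,translate_y Rigid geometry.
#' @param window_center,window_width Display windowing.
#' @param noise_sd Additive Gaussian noise sd (intensity units).
#' @param noise_seed Seed realizing the noise field (renders are fully
#'   deterministic given the nuisance object).
#' @param view_flip TRUE renders the AP view (horizontal mirror, shifted
#'   heart).
#' @param age_gap_years Years since the identity's first scan; drives the
#'   aging drift.
#' @param aging_scale_per_year,aging_diaphragm_per_year Drift
#'   coefficients.
#' @param disease_marks Data frame (`label`, `x`, `y`, `r`, `intensity`)
#'   of blob descriptors, or NULL.
#' @return Object of class `acquisition_nuisance`.
#' @export
acquisition_nuisance <- function(rotation_deg = 0, scale = 1,
                                 translate_x = 0, translate_y = 0,
                                 window_center = 0.5, window_width = 1,
                                 noise_sd = 0, noise_seed = 1L,
                                 view_flip = FALSE, age_gap_years = 0,
                                 aging_scale_per_year = 0,
                                 aging_diaphragm_per_year = 0,
                                 disease_marks = NULL) {
  assert_that(scale > 0, "scale must be positive")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  structure(as.list(environment()), class = "acquisition_nuisance")
}

ellipse_mask <- function(x, y, cx, cy, a, b) {
  ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
}

bilinear_sample <- function(img, rs, cs, fill) {
  H <- nrow(img); W <- ncol(img)
  r0 <- floor(rs); c0 <- floor(cs)
  dr <- rs - r0; dc <- cs - c0
  at <- function(r, c) {
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    v <- rep(fill, length(r))
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  v <- (1 - dr) * (1 - dc) * at(r0, c0) + (1 - dr) * dc * at(r0, c0 + 1) +
    dr * (1 - dc) * at(r0 + 1, c0) + dr * dc * at(r0 + 1, c0 + 1)
  matrix(v, H, W)
}

#' Render one phantom radiograph
#'
#' Deterministic given `(latent, nuisance, side)`. Order of operations:
#' aging drift adjusts the latent, the thorax is drawn (body silhouette,
#' lungs, rib arcs, clavicles, heart, diaphragm dome, disease marks), the
#' AP view is mirrored, then the rigid geometry, windowing and noise of
#' the nuisance are applied and the image is quantized to 8 bits.
#'
#' @param latent An [sample_identity()] latent.
#' @param nuisance An [acquisition_nuisance()].
#' @param side Canvas side in pixels.
#' @return Integer-valued numeric matrix `side x side` in `[0, 255]`.
#' @export
render_image <- function(latent, nuisance = acquisition_nuisance(),
                         side = 64L) {
  lat <- latent
  gap <- nuisance$age_gap_years
  lat$diaphragm_y <- lat$diaphragm_y -
    nuisance$aging_diaphragm_per_year * gap
  eff_scale <- nuisance$scale * (1 + nuisance$aging_scale_per_year * gap)

  ax <- seq(-1, 1, length.out = side)
  x <- matrix(ax, side, side, byrow = TRUE)
  y <- matrix(ax, side, side)
  img <- matrix(0.05, side, side)

  body <- ellipse_mask(x, y, 0, 0.03, lat$body_a, lat$body_b)
  img[body] <- 0.55
  lungs <- matrix(FALSE, side, side)
  for (lg in list(lat$lung_left, lat$lung_right)) {
    m <- ellipse_mask(x, y, lg["cx"], lg["cy"], lg["a"], lg["b"]) & body
    lungs <- lungs | m
  }
  img[lungs] <- 0.22
  # rib arcs: parabolic curves through the lung fields
  y0 <- min(lat$lung_left["cy"] - lat$lung_left["b"],
            lat$lung_right["cy"] - lat$lung_right["b"]) + 0.08
  for (r in seq_len(lat$rib_count)) {
    yr <- y0 + (r - 1) * lat$rib_spacing
    on <- abs(y - (yr + lat$rib_curv * x^2)) < lat$rib_thickness & lungs
    img[on] <- 0.5
  }
  # clavicles: straight bright lines falling from the midline
  slope <- tan(lat$clav_angle_deg * pi / 180)
  clav <- abs(y - (lat$clav_y + slope * abs(x))) < 0.022 &
    abs(x) < 0.62 & body
  img[clav] <- 0.72
  heart <- ellipse_mask(x, y, lat$heart["cx"], lat$heart["cy"],
                        lat$heart["a"], lat$heart["b"]) & body
  img[heart] <- 0.62
  # diaphragm dome: bright abdomen below a cosine contour
  below <- y > (lat$diaphragm_y - lat$diaphragm_amp * cos(1.6 * x)) & body
  img[below] <- 0.66
  if (!is.null(nuisance$disease_marks) &&
      nrow(nuisance$disease_marks) > 0) {
    for (k in seq_len(nrow(nuisance$disease_marks))) {
      mk <- nuisance$disease_marks[k, ]
      img <- img + mk$intensity *
        exp(-((x - mk$x)^2 + (y - mk$y)^2) / (2 * mk$r^2)) * body
    }
  }
  if (nuisance$view_flip) img <- img[, rev(seq_len(side))]

  # rigid geometry: inverse-map the output grid and sample bilinearly;
  # an identity transform is skipped exactly
  th <- nuisance$rotation_deg * pi / 180
  if (th != 0 || eff_scale != 1 || nuisance$translate_x != 0 ||
      nuisance$translate_y != 0) {
    xo <- x - nuisance$translate_x
    yo <- y - nuisance$translate_y
    xs <- (cos(th) * xo + sin(th) * yo) / eff_scale
    ys <- (-sin(th) * xo + cos(th) * yo) / eff_scale
    cs <- (xs + 1) / 2 * (side - 1) + 1
    rs <- (ys + 1) / 2 * (side - 1) + 1
    img <- bilinear_sample(img, rs, cs, fill = 0.05)
  }

  img <- 0.5 + (img - nuisance$window_center) * nuisance$window_width
  if (nuisance$noise_sd > 0) {
    img <- img + with_seed(nuisance$noise_seed,
                           matrix(stats::rnorm(side * side, 0,
                                               nuisance$noise_sd),
                                  side, side))
  }
  round(pmin(pmax(img, 0), 1) * 255)
}

sample_nuisance <- function(config, seed, age_gap, view_flip,
                            disease_marks) {
  with_seed(seed, acquisition_nuisance(
    rotation_deg = stats::rnorm(1, 0, config$rotation_sd),
    scale = max(0.5, stats::rnorm(1, 1, config$scale_sd)),
    translate_x = stats::rnorm(1, 0, config$translate_sd),
    translate_y = stats::rnorm(1, 0, config$translate_sd),
    window_center = stats::rnorm(1, 0.5, config$window_center_sd),
    window_width = max(0.3, stats::rnorm(1, 1, config$window_width_sd)),
    noise_sd = config$noise_sd,
    noise_seed = mix_seed(seed, 5L),
    view_flip = view_flip, age_gap_years = age_gap,
    aging_scale_per_year = config$aging_scale_per_year,
    aging_diaphragm_per_year = config$aging_diaphragm_per_year,
    disease_marks = disease_marks))
}

sample_mark <- function(seed, existing_labels) {
  with_seed(seed, {
    pool <- setdiff(PHANTOM_FINDINGS, existing_labels)
    if (length(pool) == 0) return(NULL)
    data.frame(label = sample(pool, 1),
               x = stats::runif(1, -0.5, 0.5),
               y = stats::runif(1, -0.35, 0.35),
               r = stats::runif(1, 0.05, 0.12),
               intensity = stats::runif(1, 0.18, 0.3),
               stringsAsFactors = FALSE)
  })
}

#' Generate a phantom cohort on disk
#'
#' Writes one PNG per image, a metadata CSV in the public chest X-ray
#' dialect, and a manifest JSON recording the configuration and seed, and
#' returns the loaded cohort. Byte-identical outputs for a fixed
#' configuration.
#'
#' @param config A [phantom_config()].
#' @param dir Output directory (created if needed).
#' @return A `cohort` whose `image_path`s point into `dir`.
#' @export
generate_cohort <- function(config, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("I/O error: cannot create directory: ", dir,
                  call. = FALSE)
  }
  rows <- list()
  for (p in seq_len(config$n_patients)) {
    pseed <- mix_seed(config$seed, 1L, p)
    latent <- sample_identity(mix_seed(pseed, 2L))
    k <- with_seed(mix_seed(pseed, 3L),
                   1L + stats::rpois(1, max(0, config$images_per_patient_mean - 1)))
    demo <- with_seed(mix_seed(pseed, 4L), list(
      sex = sample(c("M", "F"), 1),
      base_age = sample(25:75, 1),
      gaps = cumsum(c(0, sample(0:3, max(0, k - 1), replace = TRUE))),
      flips = stats::runif(k) < config$view_flip_prob,
      new_disease = stats::runif(k) < config$disease_rate
    ))
    marks <- NULL
    for (f in seq_len(k)) {
      iseed <- mix_seed(pseed, 6L, f)
      if (demo$new_disease[f]) {
        mk <- sample_mark(mix_seed(iseed, 7L),
                          if (is.null(marks)) character(0) else marks$label)
        if (!is.null(mk)) marks <- rbind(marks, mk)
      }
      nu <- sample_nuisance(config, iseed, age_gap = demo$gaps[f],
                            view_flip = demo$flips[f],
                            disease_marks = marks)
      img <- render_image(latent, nu, config$side)
      fname <- sprintf("%05d_%03d.png", p, f - 1L)
      png::writePNG(img / 255, file.path(dir, fname))
      rows[[length(rows) + 1L]] <- list(
        fname = fname, patient = sprintf("%d", p), fu = f - 1L,
        age = demo$base_age + demo$gaps[f], sex = demo$sex,
        view = if (demo$flips[f]) "AP" else "PA",
        findings = if (is.null(marks)) "No Finding"
                   else paste(sort(marks$label), collapse = "|"))
    }
  }
  meta <- data.frame(
    check.names = FALSE, stringsAsFactors = FALSE,
    `Image Index` = vapply(rows, `[[`, "", "fname"),
    `Finding Labels` = vapply(rows, `[[`, "", "findings"),
    `Follow-up #` = vapply(rows, `[[`, 0L, "fu"),
    `Patient ID` = vapply(rows, `[[`, "", "patient"),
    `Patient Age` = vapply(rows, function(r) as.integer(r$age), 0L),
    `Patient Gender` = vapply(rows, `[[`, "", "sex"),
    `View Position` = vapply(rows, `[[`, "", "view"))
  csv <- file.path(dir, "metadata.csv")
  utils::write.csv(meta, csv, row.names = FALSE, fileEncoding = "UTF-8")
  manifest <- config
  class(manifest) <- NULL
  jsonlite::write_json(list(config = manifest,
                            package_version =
                              as.character(utils::packageVersion("xrayid"))),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  load_metadata(csv, dialect = "chestxray14", image_dir = dir)
}
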