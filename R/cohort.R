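# Cohort data model: radiograph collections with patient-level grouping,
# metadata readers/writers, image loading and patient-disjoint splitting.

CHESTXRAY14_COLUMNS <- c(
  image = "Image Index", findings = "Finding Labels", follow_up = "Follow-up #",
  patient = "Patient ID", age = "Patient Age", sex = "Patient Gender",
  view = "View Position"
)

#' Construct a cohort from an image record table
#'
#' A cohort is the package's central container: one row per radiograph with
#' the patient identity and acquisition metadata, plus an index grouping
#' image identifiers by patient. Most users will obtain one from
#' [load_metadata()] or [generate_cohort()] rather than building it by hand.
#'
#' @param records data frame with columns `image_id`, `patient_id`,
#'   `follow_up_index`, `age_years`, `sex` (`"M"`, `"F"` or `"unknown"`),
#'   `view` (`"AP"`, `"PA"` or `"unknown"`), `findings` (list column of
#'   character vectors; empty entries are replaced by `"No Finding"`) and
#'   `image_path`.
#' @return An object of class `cohort`: list with elements `records` and
#'   `patient_index` (named list mapping patient id to image ids).
#' @export
new_cohort <- function(records) {
  needed <- c("image_id", "patient_id", "follow_up_index", "age_years",
              "sex", "view", "findings", "image_path")
  missing_cols <- setdiff(needed, names(records))
  assert_that(length(missing_cols) == 0,
              paste0("records is missing column(s): ",
                     paste(missing_cols, collapse = ", ")))
  records$image_id <- as.character(records$image_id)
  records$patient_id <- as.character(records$patient_id)
  records$follow_up_index <- as.integer(records$follow_up_index)
  records$age_years <- as.integer(records$age_years)
  records$sex <- ifelse(records$sex %in% c("M", "F"), records$sex, "unknown")
  records$view <- ifelse(toupper(records$view) %in% c("AP", "PA"),
                         toupper(records$view), "unknown")
  if (!is.list(records$findings)) records$findings <- as.list(records$findings)
  records$findings <- lapply(records$findings, function(f) {
    f <- f[nzchar(f)]
    if (length(f) == 0) "No Finding" else as.character(f)
  })
  if (anyDuplicated(records$image_id)) {
    dup <- unique(records$image_id[duplicated(records$image_id)])
    stop("integrity error: duplicate image_id: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  fu_dup <- tapply(records$follow_up_index, records$patient_id,
                   function(x) anyDuplicated(x) > 0)
  if (any(fu_dup)) {
    stop("integrity error: duplicate follow_up_index within patient(s): ",
         paste(utils::head(names(fu_dup)[fu_dup], 5), collapse = ", "),
         call. = FALSE)
  }
  rownames(records) <- NULL
  structure(
    list(records = records,
         patient_index = split(records$image_id, records$patient_id)),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d images from %d patients\n",
              nrow(x$records), length(x$patient_index)))
  invisible(x)
}

#' Number of images and patients in a cohort
#' @param cohort A `cohort` object.
#' @return Integer count.
#' @export
n_images <- function(cohort) nrow(cohort$records)

#' @rdname n_images
#' @export
n_patients <- function(cohort) length(cohort$patient_index)

#' Read a radiograph metadata table into a cohort
#'
#' Supports the ChestX-ray14 metadata dialect (columns `Image Index`,
#' `Finding Labels` with `"|"`-separated pathology names, `Follow-up #`,
#' `Patient ID`, `Patient Age`, `Patient Gender`, `View Position`) and a
#' generic dialect with an explicit column mapping.
#'
#' @param csv_path Path to the metadata CSV (UTF-8, header row).
#' @param dialect `"chestxray14"` (default) or `"generic"`.
#' @param image_dir Directory holding the image files; defaults to the
#'   directory of `csv_path`.
#' @param columns For `dialect = "generic"`: named character vector mapping
#'   the roles `image`, `findings`, `follow_up`, `patient`, `age`, `sex`,
#'   `view` to column names in the CSV.
#' @param findings_sep Separator inside the findings column (default `"|"`).
#' @return A [new_cohort()] object.
#' @export
load_metadata <- function(csv_path, dialect = c("chestxray14", "generic"),
                          image_dir = dirname(csv_path), columns = NULL,
                          findings_sep = "|") {
  dialect <- match.arg(dialect)
  assert_that(file.exists(csv_path), paste0("file not found: ", csv_path))
  cols <- if (dialect == "chestxray14") CHESTXRAY14_COLUMNS else columns
  assert_that(!is.null(cols) && all(names(CHESTXRAY14_COLUMNS) %in% names(cols)),
              "generic dialect requires a complete `columns` mapping")
  raw <- utils::read.csv(csv_path, check.names = FALSE,
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(unname(cols), names(raw))
  if (length(missing_cols) > 0) {
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  fname <- as.character(raw[[cols[["image"]]]])
  records <- data.frame(
    image_id = sub("\\.[A-Za-z]+$", "", fname),
    patient_id = as.character(raw[[cols[["patient"]]]]),
    follow_up_index = as.integer(raw[[cols[["follow_up"]]]]),
    age_years = as.integer(raw[[cols[["age"]]]]),
    sex = as.character(raw[[cols[["sex"]]]]),
    view = as.character(raw[[cols[["view"]]]]),
    image_path = file.path(image_dir, fname),
    stringsAsFactors = FALSE
  )
  records$findings <- strsplit(as.character(raw[[cols[["findings"]]]]),
                               findings_sep, fixed = TRUE)
  new_cohort(records)
}

#' Write a cohort's metadata as a ChestX-ray14-dialect CSV
#'
#' The written file round-trips through [load_metadata()]: re-loading
#' reproduces every record field exactly.
#'
#' @param cohort A `cohort`.
#' @param csv_path Output path.
#' @return `csv_path`, invisibly.
#' @export
write_metadata <- function(cohort, csv_path) {
  r <- cohort$records
  out <- data.frame(
    check.names = FALSE, stringsAsFactors = FALSE,
    `Image Index` = basename(r$image_path),
    `Finding Labels` = vapply(r$findings, paste, "", collapse = "|"),
    `Follow-up #` = r$follow_up_index,
    `Patient ID` = r$patient_id,
    `Patient Age` = r$age_years,
    `Patient Gender` = r$sex,
    `View Position` = r$view
  )
  utils::write.csv(out, csv_path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(csv_path)
}

#' Load one radiograph as an 8-bit intensity grid
#'
#' Reads a PNG or JPG file and returns a numeric matrix of intensities in
#' `[0, 255]`. Colour images are reduced to a single luminance channel
#' (Rec. 709 weights). No resizing or normalization happens at this stage;
#' see [prepare_model_input()].
#'
#' @param record One-row slice of `cohort$records`, or a list with elements
#'   `image_path` and `image_id`.
#' @return Numeric matrix (height x width), values in `[0, 255]`.
#' @export
load_image <- function(record) {
  path <- record$image_path[[1]]
  id <- record$image_id[[1]]
  if (!file.exists(path)) {
    stop("I/O error for image '", id, "': file not found: ", path,
         call. = FALSE)
  }
  px <- tryCatch({
    lower <- tolower(path)
    if (grepl("\\.png$", lower)) {
      png::readPNG(path)
    } else if (grepl("\\.jpe?g$", lower)) {
      jpeg::readJPEG(path)
    } else {
      stop("unsupported image format")
    }
  }, error = function(e) {
    stop("I/O error for image '", id, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (length(dim(px)) == 3) {
    if (dim(px)[3] >= 3) {
      px <- 0.2126 * px[, , 1] + 0.7152 * px[, , 2] + 0.0722 * px[, , 3]
    } else {
      px <- px[, , 1]
    }
  }
  px * 255
}

#' Prepare a pixel grid as network input
#'
#' Resizes the grid to `side x side` with bilinear interpolation, scales
#' intensities to `[0, 1]`, replicates the single channel to three channels,
#' and standardizes each channel with the given mean and standard deviation
#' (defaults follow the natural-image-pretraining convention).
#'
#' @param pixels Numeric matrix with intensities in `[0, 255]`.
#' @param side Output side length in pixels (>= 8).
#' @param channel_mean,channel_sd Per-channel standardization constants.
#' @return Numeric array of dimension `c(side, side, 3)`.
#' @export
prepare_model_input <- function(pixels, side = 256,
                                channel_mean = c(0.485, 0.456, 0.406),
                                channel_sd = c(0.229, 0.224, 0.225)) {
  assert_that(is.matrix(pixels) && all(dim(pixels) > 0),
              "pixels must be a non-degenerate 2-D grid")
  assert_that(side >= 8, "side must be >= 8")
  x <- pixels / 255
  if (!all(dim(x) == c(side, side))) {
    x <- EBImage::resize(x, w = side, h = side)
  }
  out <- array(0, c(side, side, 3))
  for (ch in 1:3) out[, , ch] <- (x - channel_mean[ch]) / channel_sd[ch]
  out
}

# Stack prepared inputs for a whole cohort into one (side, side, 3, n)
# tensor; used by training and evaluation so each image is read once.
#' Prepare every image of a cohort as a network input tensor
#'
#' @param cohort A `cohort` whose `image_path`s are readable.
#' @param side Input side length.
#' @param ... Passed to [prepare_model_input()].
#' @return List with `ids` (character) and `x` (array `side x side x 3 x n`).
#' @export
cohort_tensor <- function(cohort, side, ...) {
  n <- n_images(cohort)
  x <- array(0, c(side, side, 3, n))
  for (i in seq_len(n)) {
    x[, , , i] <- prepare_model_input(load_image(cohort$records[i, ]),
                                      side = side, ...)
  }
  list(ids = cohort$records$image_id, x = x)
}

#' Restrict a cohort to a set of patients
#' @param cohort A `cohort`.
#' @param patient_ids Character vector of patient ids to keep.
#' @return A new `cohort`.
#' @export
subset_patients <- function(cohort, patient_ids) {
  new_cohort(cohort$records[cohort$records$patient_id %in% patient_ids, ,
                            drop = FALSE])
}

#' Split a cohort into patient-disjoint train/validation/test subsets
#'
#' Assignment is decided at the patient level so that all images of one
#' patient land in the same subset (no identity leakage across subsets).
#' Without an explicit assignment, patients are shuffled by `seed` and
#' partitioned by cumulative fraction of patient counts.
#'
#' @param cohort A `cohort`.
#' @param fractions Positive numeric triple summing to 1
#'   (default `c(0.7, 0.1, 0.2)`).
#' @param seed Integer seed controlling the patient shuffle.
#' @param official_assignment Optional named character vector mapping every
#'   patient id to `"train"`, `"val"` or `"test"`; honored verbatim.
#' @return Object of class `dataset_split`: list with cohorts `train`,
#'   `val`, `test` and the `fractions` used.
#' @export
patient_wise_split <- function(cohort, fractions = c(0.7, 0.1, 0.2),
                               seed = 1, official_assignment = NULL) {
  assert_that(length(fractions) == 3 && all(fractions >= 0) &&
                abs(sum(fractions) - 1) < 1e-8,
              "fractions must be a non-negative triple summing to 1")
  pts <- names(cohort$patient_index)
  if (!is.null(official_assignment)) {
    missing_p <- setdiff(pts, names(official_assignment))
    assert_that(length(missing_p) == 0,
                "official_assignment must cover all patients")
    lab <- official_assignment[pts]
  } else {
    assert_that(length(pts) >= sum(fractions > 0),
                "fewer patients than nonzero fractions")
    ord <- with_seed(seed, sample(pts))
    bounds <- round(cumsum(fractions) * length(pts))
    lab <- character(length(pts))
    lab[seq_len(bounds[1])] <- "train"
    if (bounds[2] > bounds[1]) lab[(bounds[1] + 1):bounds[2]] <- "val"
    if (bounds[3] > bounds[2]) lab[(bounds[2] + 1):bounds[3]] <- "test"
    names(lab) <- ord
    lab <- lab[pts]
  }
  structure(
    list(train = subset_patients(cohort, pts[lab == "train"]),
         val = subset_patients(cohort, pts[lab == "val"]),
         test = subset_patients(cohort, pts[lab == "test"]),
         fractions = fractions),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf(
    "<dataset_split> train %d/%d  val %d/%d  test %d/%d (images/patients)\n",
    n_images(x$train), n_patients(x$train),
    n_images(x$val), n_patients(x$val),
    n_images(x$test), n_patients(x$test)))
  invisible(x)
}

#' Write a split manifest (image_id, subset) as CSV
#' @param split A `dataset_split`.
#' @param csv_path Output path.
#' @return `csv_path`, invisibly.
#' @export
write_split_manifest <- function(split, csv_path) {
  out <- do.call(rbind, lapply(c("train", "val", "test"), function(s) {
    ids <- split[[s]]$records$image_id
    data.frame(image_id = ids, subset = rep(s, length(ids)),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(out, csv_path, row.names = FALSE)
  invisible(csv_path)
}
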