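# Image + manifest I/O and preprocessing for two-class grayscale cohorts.
#
# A cohort is a column-oriented collection of grayscale images, each tagged
# with a patient identifier and a binary class label (0 = negative/healthy,
# 1 = positive/diseased).  All images of a patient carry the same label;
# this invariant is enforced at construction time because violating it
# silently breaks patient-grouped cross-validation.

#' Construct a cohort dataset
#'
#' @param images list of numeric matrices (grayscale pixel arrays).
#' @param label integer vector of 0/1 class labels, one per image.
#' @param patient_id character vector of patient identifiers, one per image.
#' @param sample_id optional character vector of unique sample identifiers;
#'   defaults to `"<patient>_<index-within-patient>"`.
#' @param sequence_tag,view_tag optional per-image metadata strings
#'   (e.g. the CMR sequence type); `NA` when unknown.
#' @param class_names length-2 character vector naming the negative and
#'   positive class, in that order.
#' @return an object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(images, label, patient_id, sample_id = NULL,
                           sequence_tag = NULL, view_tag = NULL,
                           class_names = c("healthy", "cad")) {
  n <- length(images)
  if (n == 0L) stop("a cohort_dataset must contain at least one image")
  label <- as.integer(label)
  patient_id <- as.character(patient_id)
  if (length(label) != n || length(patient_id) != n)
    stop("images, label and patient_id must have equal length")
  if (!all(label %in% c(0L, 1L)))
    stop("labels must be 0 (negative) or 1 (positive)")
  if (length(class_names) != 2L)
    stop("class_names must have exactly two entries")
  # label-consistency invariant: one label per patient
  lab_per_patient <- tapply(label, patient_id, function(x) length(unique(x)))
  bad <- names(lab_per_patient)[lab_per_patient > 1L]
  if (length(bad))
    stop("patient(s) with images in both classes: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  if (is.null(sample_id)) {
    idx <- stats::ave(seq_len(n), patient_id, FUN = seq_along)
    sample_id <- sprintf("%s_%02d", patient_id, idx)
  }
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("sample_id values must be unique")
  ds <- structure(list(
    images       = images,
    label        = label,
    patient_id   = patient_id,
    sample_id    = sample_id,
    sequence_tag = as.character(sequence_tag %||% rep(NA_character_, n)),
    view_tag     = as.character(view_tag %||% rep(NA_character_, n)),
    class_names  = as.character(class_names)
  ), class = "cohort_dataset")
  ds
}

#' @export
length.cohort_dataset <- function(x) length(x$images)

#' Subset a cohort by sample index or sample id
#' @param x a `cohort_dataset`.
#' @param i integer or logical index, or character vector of sample ids.
#' @param ... unused.
#' @export
`[.cohort_dataset` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$sample_id)
  if (anyNA(i)) stop("unknown sample id(s) in subset")
  cohort_dataset(x$images[i], x$label[i], x$patient_id[i], x$sample_id[i],
                 x$sequence_tag[i], x$view_tag[i], x$class_names)
}

#' @export
print.cohort_dataset <- function(x, ...) {
  tab <- table(factor(x$label, levels = 0:1, labels = x$class_names))
  cat(sprintf("<cohort_dataset> %d images, %d patients (%s)\n",
              length(x), length(unique(x$patient_id)),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Number of patients implied by an image count
#'
#' Integer division of the cohort's total image count by the fixed number
#' of images acquired per patient (e.g. 13 slices in each of 4 sequence
#' types = 52 images per patient).
#'
#' @param total_images total number of images in the cohort.
#' @param images_per_patient images acquired per patient (> 0).
#' @return integer patient count; warns when the division has a remainder.
#' @examples
#' count_patients(63648, 52)  # 1224
#' @export
count_patients <- function(total_images, images_per_patient) {
  if (length(images_per_patient) != 1L || is.na(images_per_patient) ||
      images_per_patient <= 0)
    stop("images_per_patient must be a single positive number")
  if (total_images %% images_per_patient != 0)
    warning(sprintf("%d images is not an exact multiple of %d per patient",
                    total_images, images_per_patient))
  as.integer(total_images %/% images_per_patient)
}

# Bilinear resampling with the half-pixel-centre convention: output pixel
# centre (i - 0.5)/Ho maps to input coordinate (i - 0.5) * H/Ho.  Edge
# coordinates are clamped.  Exact for affine-in-(row, col) images.
resize_bilinear <- function(img, out_shape) {
  H <- nrow(img); W <- ncol(img)
  Ho <- out_shape[1]; Wo <- out_shape[2]
  if (H == Ho && W == Wo) return(img)
  sy <- pmin(pmax((seq_len(Ho) - 0.5) * H / Ho - 0.5, 0), H - 1)
  sx <- pmin(pmax((seq_len(Wo) - 0.5) * W / Wo - 0.5, 0), W - 1)
  y0 <- pmin(floor(sy), H - 1); y1 <- pmin(y0 + 1, H - 1); wy <- sy - y0
  x0 <- pmin(floor(sx), W - 1); x1 <- pmin(x0 + 1, W - 1); wx <- sx - x0
  y0 <- y0 + 1; y1 <- y1 + 1; x0 <- x0 + 1; x1 <- x1 + 1
  ((1 - wy) %o% (1 - wx)) * img[y0, x0, drop = FALSE] +
  ((1 - wy) %o% wx)       * img[y0, x1, drop = FALSE] +
  (wy %o% (1 - wx))       * img[y1, x0, drop = FALSE] +
  (wy %o% wx)             * img[y1, x1, drop = FALSE]
}

# Luminance average for multi-channel input (H x W x C array -> H x W).
to_grayscale <- function(raw) {
  if (length(dim(raw)) == 3L) {
    nc <- dim(raw)[3]
    if (nc >= 3L) {
      # equal-weight average; sufficient for near-grayscale medical scans
      (raw[, , 1] + raw[, , 2] + raw[, , 3]) / 3
    } else {
      raw[, , 1]
    }
  } else {
    raw
  }
}

#' Preprocess one raw image: grayscale, scale to [0, 1], resize
#'
#' Multi-channel input is collapsed to a single channel by luminance
#' average.  Intensities are divided by the bit-depth maximum (a fixed
#' global scaling, not per-image min-max, so intensities remain comparable
#' across images), then the image is resampled to `target_shape` by
#' bilinear interpolation.
#'
#' @param raw numeric matrix or H x W x C array, values in `[0, max_value]`.
#' @param target_shape integer pair `(rows, cols)`, default `c(100, 100)`.
#' @param max_value the value that maps to 1.0.  Default: 1 when the input
#'   already lies in `[0, 1]`, otherwise 255 (8-bit convention).
#' @return numeric matrix of dimension `target_shape` with values in `[0, 1]`.
#' @export
preprocess_image <- function(raw, target_shape = c(100L, 100L),
                             max_value = NULL) {
  if (length(raw) == 0L) stop("empty image array")
  if (length(target_shape) != 2L || any(target_shape < 1))
    stop("target_shape must be two positive integers")
  img <- to_grayscale(raw)
  if (is.null(dim(img)) || length(dim(img)) != 2L)
    stop("raw image must be a matrix or an H x W x C array")
  if (anyNA(img) || min(img) < 0) stop("pixel values must be non-negative")
  if (is.null(max_value)) max_value <- if (max(img) > 1) 255 else 1
  if (max(img) > max_value)
    stop(sprintf("pixel values exceed the stated maximum %s", max_value))
  img <- img / max_value
  resize_bilinear(img, as.integer(target_shape))
}

#' Preprocess every image of a cohort
#'
#' @param dataset a `cohort_dataset`.
#' @param target_shape integer pair passed to [preprocess_image()].
#' @return the dataset with every image replaced by its preprocessed form.
#' @export
preprocess_dataset <- function(dataset, target_shape = c(100L, 100L)) {
  dataset$images <- lapply(dataset$images, preprocess_image,
                           target_shape = target_shape)
  dataset
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch({
    if (ext %in% c("png"))
      png::readPNG(path)
    else if (ext %in% c("jpg", "jpeg")) {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("the 'jpeg' package is required to read JPEG files")
      jpeg::readJPEG(path)
    } else stop("unsupported image format: .", ext)
  }, error = function(e) stop("cannot read image '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  to_grayscale(raw)   # values in [0, 1] as returned by png/jpeg readers
}

write_gray_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), target = path)
  path
}

#' Read a tab-separated cohort manifest
#'
#' The manifest has a header row and one row per image with columns
#' `path`, `patient_id`, `label` (0/1), and optionally `sequence_tag`,
#' `view_tag`.  Paths are interpreted relative to the manifest's directory
#' unless absolute.
#'
#' @param manifest path to the TSV file.
#' @return a data.frame, one row per image, in manifest order.
#' @export
read_manifest <- function(manifest) {
  df <- utils::read.delim(manifest, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("path", "patient_id", "label")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  df$label <- as.integer(df$label)
  root <- dirname(normalizePath(manifest, mustWork = TRUE))
  abs <- grepl("^(/|[A-Za-z]:)", df$path)
  df$path[!abs] <- file.path(root, df$path[!abs])
  df
}

#' Load a two-class image cohort from disk
#'
#' Either a TSV manifest (see [read_manifest()]) assigns each image its
#' patient id and label, or — with `manifest = "infer-from-layout"` — the
#' directory must contain exactly two class subfolders and the patient id
#' is extracted from each filename with `patient_regex` (first capture
#' group).  Sample order is deterministic: manifest order, or sorted
#' class-folder then sorted filename.
#'
#' @param image_root directory containing the images (or class subfolders).
#' @param manifest path to a manifest TSV, or `"infer-from-layout"`.
#' @param class_names length-2 character vector: negative then positive
#'   class folder name.  With layout inference, folders not matching are an
#'   error; `NULL` uses the two subfolder names in sorted order.
#' @param patient_regex regex with one capture group applied to filenames
#'   to extract the patient id when inferring from layout.
#' @return a `cohort_dataset`; pixel values are in `[0, 1]` at the file's
#'   native resolution (call [preprocess_dataset()] to resize).
#' @export
load_dataset <- function(image_root, manifest = "infer-from-layout",
                         class_names = NULL, patient_regex = "^([^_]+)_") {
  if (!dir.exists(image_root)) stop("image_root does not exist: ", image_root)
  if (identical(manifest, "infer-from-layout")) {
    dirs <- sort(list.dirs(image_root, recursive = FALSE, full.names = FALSE))
    if (length(dirs) != 2L)
      stop("layout inference needs exactly 2 class subfolders, found ",
           length(dirs))
    if (is.null(class_names)) class_names <- dirs
    if (!setequal(dirs, class_names))
      stop("class subfolders ", paste(dirs, collapse = "/"),
           " do not match class_names ", paste(class_names, collapse = "/"))
    rows <- lapply(seq_along(class_names), function(ci) {
      cls <- class_names[ci]
      files <- sort(list.files(file.path(image_root, cls),
                               pattern = "\\.(png|jpe?g)$", ignore.case = TRUE))
      if (!length(files)) return(NULL)
      m <- regmatches(files, regexec(patient_regex, files))
      pid <- vapply(m, function(g) if (length(g) >= 2) g[2] else NA_character_,
                    character(1))
      pid[is.na(pid)] <- sub("\\.[^.]+$", "", files[is.na(pid)])
      data.frame(path = file.path(image_root, cls, files),
                 patient_id = pid, label = ci - 1L,
                 sequence_tag = NA_character_, view_tag = NA_character_,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    if (is.null(df) || nrow(df) == 0L)
      stop("no images found under ", image_root)
  } else {
    df <- read_manifest(manifest)
    if (nrow(df) == 0L) stop("manifest is empty: ", manifest)
    if (is.null(class_names)) class_names <- c("healthy", "cad")
  }
  images <- lapply(df$path, read_image_file)
  ds <- cohort_dataset(images, df$label, df$patient_id,
                       sequence_tag = df$sequence_tag %||% NULL,
                       view_tag = df$view_tag %||% NULL,
                       class_names = class_names)
  tab <- table(factor(ds$label, levels = 0:1))
  cf_log("loaded %d images from %d patients (%s: %d, %s: %d)",
         length(ds), length(unique(ds$patient_id)),
         class_names[1], tab[1], class_names[2], tab[2])
  ds
}
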