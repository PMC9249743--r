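# Synthetic two-class lesion cohort.
#
# Emulates the statistical structure a CNN-feature forest pipeline relies
# on, without any real scans: patients contribute several grayscale slices
# sharing a patient-specific smooth background; positive-class images
# additionally contain 1-3 bright elliptical lesions.  Pixel noise is
# additive Gaussian, clipped to [0, 1].

#' Configuration of the synthetic cohort generator
#'
#' Defaults give the "desk-scale" separable cohort: 40 + 40 patients,
#' 8 images each at 32 x 32, lesions of peak added intensity 0.8 over a
#' low-frequency background with noise sd 0.05 — small enough that the
#' full cross-validated pipeline runs in minutes on one CPU.
#'
#' @param n_healthy_patients,n_cad_patients patient counts per class (> 0).
#' @param images_per_patient slices generated per patient (> 0).
#' @param image_size integer pair, image height and width in pixels.
#' @param lesion_intensity peak intensity added inside a lesion, in `[0, 1]`;
#'   0 makes the two classes statistically indistinguishable.
#' @param lesion_radius_px typical lesion semi-axis in pixels; must be
#'   smaller than `min(image_size) / 2`.
#' @param noise_sd standard deviation of the additive Gaussian pixel noise.
#' @param background_texture_scale spatial scale (in units of the image
#'   side) of the sinusoidal background texture; larger is smoother.
#' @param seed integer seed; identical configs (including seed) produce
#'   bit-identical cohorts.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_healthy_patients = 40L, n_cad_patients = 40L,
                          images_per_patient = 8L, image_size = c(32L, 32L),
                          lesion_intensity = 0.8, lesion_radius_px = 4L,
                          noise_sd = 0.05, background_texture_scale = 1,
                          seed = 1L) {
  cfg <- list(n_healthy_patients = as.integer(n_healthy_patients),
              n_cad_patients = as.integer(n_cad_patients),
              images_per_patient = as.integer(images_per_patient),
              image_size = as.integer(image_size),
              lesion_intensity = lesion_intensity,
              lesion_radius_px = as.integer(lesion_radius_px),
              noise_sd = noise_sd,
              background_texture_scale = background_texture_scale,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (n_healthy_patients < 1L || n_cad_patients < 1L)
      stop("patient counts must be strictly positive")
    if (images_per_patient < 1L) stop("images_per_patient must be positive")
    if (length(image_size) != 2L || any(image_size < 4L))
      stop("image_size must be two integers >= 4")
    if (lesion_intensity < 0 || lesion_intensity > 1)
      stop("lesion_intensity must lie in [0, 1]")
    if (lesion_radius_px < 1L || lesion_radius_px >= min(image_size) / 2)
      stop("lesion_radius_px must be in [1, min(image_size)/2)")
    if (noise_sd < 0) stop("noise_sd must be non-negative")
    if (background_texture_scale <= 0)
      stop("background_texture_scale must be positive")
  })
  invisible(cfg)
}

# Smooth per-patient background: two low-frequency sinusoids with random
# orientation/phase plus a random DC offset, scaled into [0.15, 0.6].
synth_background <- function(h, w, scale) {
  yy <- matrix(seq_len(h) / h, h, w)
  xx <- matrix(rep(seq_len(w) / w, each = h), h, w)
  bg <- 0.35 + 0.1 * (stats::runif(1) - 0.5)
  for (i in 1:2) {
    f <- stats::runif(1, 0.5, 1.5) / scale
    th <- stats::runif(1, 0, pi)
    ph <- stats::runif(1, 0, 2 * pi)
    bg <- bg + 0.08 * sin(2 * pi * f * (cos(th) * xx + sin(th) * yy) + ph)
  }
  bg
}

# Add 1-3 bright ellipses with a raised-cosine radial profile; peak added
# intensity is `intensity` at the lesion centre.
add_lesions <- function(img, radius, intensity) {
  h <- nrow(img); w <- ncol(img)
  n_les <- sample.int(3L, 1L)
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(rep(seq_len(w), each = h), h, w)
  for (i in seq_len(n_les)) {
    cy <- stats::runif(1, 0.25 * h, 0.75 * h)
    cx <- stats::runif(1, 0.25 * w, 0.75 * w)
    a <- radius * stats::runif(1, 0.6, 1.4)
    b <- radius * stats::runif(1, 0.6, 1.4)
    th <- stats::runif(1, 0, pi)
    u <- (cos(th) * (xx - cx) + sin(th) * (yy - cy)) / a
    v <- (-sin(th) * (xx - cx) + cos(th) * (yy - cy)) / b
    r2 <- u^2 + v^2
    prof <- ifelse(r2 < 1, 0.5 * (1 + cos(pi * sqrt(r2))), 0)
    img <- img + intensity * prof
  }
  img
}

#' Generate a synthetic two-class image cohort
#'
#' Patients are generated in a fixed order (all healthy, then all
#' positive), each from a seed derived from `config$seed` and the patient
#' index, so cohorts are bit-identical across calls and platforms.
#'
#' @param config a [cohort_config()].
#' @return a `cohort_dataset` with
#'   `n_healthy_patients + n_cad_patients` patients, each contributing
#'   `images_per_patient` images in `[0, 1]`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  h <- config$image_size[1]; w <- config$image_size[2]
  seq_types <- c("LGE", "Perfusion", "T2", "SSFP")
  n_pat <- config$n_healthy_patients + config$n_cad_patients
  labels_pat <- rep(c(0L, 1L), c(config$n_healthy_patients,
                                 config$n_cad_patients))
  pids <- sprintf("P%04d", seq_len(n_pat))
  images <- vector("list", n_pat * config$images_per_patient)
  lab <- integer(length(images)); pid <- character(length(images))
  stag <- character(length(images))
  k <- 0L
  for (p in seq_len(n_pat)) {
    imgs <- with_seed(derive_seed(config$seed, "patient", p), {
      bg <- synth_background(h, w, config$background_texture_scale)
      lapply(seq_len(config$images_per_patient), function(j) {
        img <- bg
        if (labels_pat[p] == 1L)
          img <- add_lesions(img, config$lesion_radius_px,
                             config$lesion_intensity)
        img <- img + stats::rnorm(h * w, sd = config$noise_sd)
        pmin(pmax(img, 0), 1)
      })
    })
    for (j in seq_len(config$images_per_patient)) {
      k <- k + 1L
      images[[k]] <- imgs[[j]]
      lab[k] <- labels_pat[p]
      pid[k] <- pids[p]
      stag[k] <- seq_types[(j - 1L) %% 4L + 1L]
    }
  }
  cohort_dataset(images, lab, pid, sequence_tag = stag,
                 class_names = c("healthy", "cad"))
}

#' Write a cohort to disk as PNG images plus a TSV manifest
#'
#' Produces exactly the layout [load_dataset()] consumes: one PNG per
#' image under `<out>/images/` and a `manifest.tsv` with columns `path`,
#' `patient_id`, `label`, `sequence_tag`, `view_tag` (paths relative to
#' the manifest).
#'
#' @param dataset a non-empty `cohort_dataset`.
#' @param out output directory; created if absent.
#' @return the manifest path, invisibly usable with
#'   `load_dataset(out, manifest)`.
#' @export
cohort_manifest <- function(dataset, out) {
  if (!inherits(dataset, "cohort_dataset") || length(dataset) == 0L)
    stop("dataset must be a non-empty cohort_dataset")
  img_dir <- file.path(out, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir)) stop("cannot create output directory: ", out)
  rel <- file.path("images", paste0(dataset$sample_id, ".png"))
  for (i in seq_along(dataset$images))
    write_gray_png(dataset$images[[i]], file.path(out, rel[i]))
  df <- data.frame(path = rel, patient_id = dataset$patient_id,
                   label = dataset$label,
                   sequence_tag = dataset$sequence_tag,
                   view_tag = dataset$view_tag, stringsAsFactors = FALSE)
  manifest <- file.path(out, "manifest.tsv")
  utils::write.table(df, manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  cf_log("wrote %d images + manifest to %s", nrow(df), out)
  manifest
}
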