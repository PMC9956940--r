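#' Reference reflectance spectrum of intact skin
#'
#' Piecewise-linear model through fixed anchors, rising from 0.35 at
#' 465 nm to 0.60 at 630 nm -- the qualitative shape of light skin in the
#' visible range (reflectance grows toward red). The anchors are
#' documented constants chosen for separability, not fits to tissue
#' optics data.
#'
#' @param wavelengths_nm band grid within 400--1000 nm.
#' @return Reflectance vector on the grid, all values in (0, 1),
#'   monotone non-decreasing.
#' @export
skin_spectrum <- function(wavelengths_nm = imec_16band_nm) {
  w <- as.numeric(wavelength_grid(wavelengths_nm))
  anchors_nm <- c(400, 465, 510, 560, 600, 630, 1000)
  anchors_r <- c(0.30, 0.35, 0.41, 0.47, 0.54, 0.60, 0.60)
  stats::approx(anchors_nm, anchors_r, xout = w)$y
}

#' Reference reflectance spectrum of wound tissue
#'
#' The skin spectrum minus a smooth absorption dip of depth 0.25 centered
#' at 560 nm with compact support on 508--612 nm -- a hemoglobin-like
#' motif covering the sensor's 534--586 nm bands, which is what the
#' wound-cluster selection rule keys on. Floored at 0.05.
#'
#' @inheritParams skin_spectrum
#' @return Reflectance vector on the grid.
#' @export
wound_spectrum <- function(wavelengths_nm = imec_16band_nm) {
  w <- as.numeric(wavelength_grid(wavelengths_nm))
  base <- skin_spectrum(w)
  half_width <- 52
  dx <- abs(w - 560)
  dip <- ifelse(dx <= half_width,
                0.25 * cos(pi * dx / (2 * half_width))^2, 0)
  pmax(base - dip, 0.05)
}

#' Phantom generation parameters
#'
#' @param rows,cols raster size in pixels.
#' @param pixel_pitch_cm centimetres per pixel.
#' @param wound_shape `"disk"` (exact digital disk) or `"blob"`
#'   (thresholded smoothed noise, for irregular outlines).
#' @param disk_radius_px disk radius in pixels.
#' @param blob_smoothness smoothing radius (px) of the blob noise field.
#' @param blob_threshold foreground quantile in (0, 1); higher = smaller
#'   wound.
#' @param erythema_halo_px width of the red-swollen ring around the wound
#'   (0 = none).
#' @param noise_sigma additive Gaussian reflectance noise SD.
#' @param illumination_gradient maximum multiplicative deviation of the
#'   illumination plane across the scene (0.05 = +/-5%).
#' @param seed integer seed; the whole scene is deterministic in it.
#' @return An object of class `"phantom_params"`.
#' @export
phantom_params <- function(rows = 96L, cols = 96L, pixel_pitch_cm = 0.05,
                           wound_shape = c("disk", "blob"),
                           disk_radius_px = 20L, blob_smoothness = 6,
                           blob_threshold = 0.85, erythema_halo_px = 0L,
                           noise_sigma = 0.01, illumination_gradient = 0.05,
                           seed = 1L) {
  wound_shape <- match.arg(wound_shape)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (erythema_halo_px < 0) stop("erythema_halo_px must be >= 0",
                                 call. = FALSE)
  if (wound_shape == "blob" &&
      (blob_threshold <= 0 || blob_threshold >= 1)) {
    stop("blob_threshold must lie in (0, 1)", call. = FALSE)
  }
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 pixel_pitch_cm = pixel_pitch_cm, wound_shape = wound_shape,
                 disk_radius_px = as.integer(disk_radius_px),
                 blob_smoothness = blob_smoothness,
                 blob_threshold = blob_threshold,
                 erythema_halo_px = as.integer(erythema_halo_px),
                 noise_sigma = noise_sigma,
                 illumination_gradient = illumination_gradient,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

#' Generate a hyperspectral wound phantom
#'
#' Builds a calibrated 16-band scene with exactly known ground truth:
#' a wound region (digital disk, or largest component of thresholded
#' smoothed noise for `"blob"`) carrying [wound_spectrum()], surrounding
#' skin carrying [skin_spectrum()], an optional erythema halo ring where
#' the two spectra are convexly blended with weight decaying outward, a
#' multiplicative planar illumination gradient, and additive Gaussian
#' sensor noise, clipped to the calibrated range. The true area is the
#' truth-mask pixel count times the pixel area, exactly.
#'
#' @param params a [phantom_params].
#' @return A `"phantom_scene"`: `cube` (calibrated [spectral_cube]),
#'   `truth_mask` ([wound_mask]), `halo_mask`, `true_area_cm2`, `params`.
#' @export
generate_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  withr::with_seed(p$seed, {
    if (p$wound_shape == "disk") {
      if (2L * p$disk_radius_px + 1L > min(p$rows, p$cols)) {
        stop("parameter error: disk does not fit inside the raster",
             call. = FALSE)
      }
      cr <- (p$rows + 1) / 2
      cc <- (p$cols + 1) / 2
      rr <- matrix(seq_len(p$rows), p$rows, p$cols)
      cm <- matrix(seq_len(p$cols), p$rows, p$cols, byrow = TRUE)
      truth <- (rr - cr)^2 + (cm - cc)^2 <= p$disk_radius_px^2
    } else {
      field <- matrix(stats::rnorm(p$rows * p$cols), p$rows, p$cols)
      r <- max(1L, round(p$blob_smoothness))
      for (pass in 1:2) {                      # separable box smoothing
        field <- t(apply(field, 1, .box_smooth, r = r))
        field <- apply(field, 2, .box_smooth, r = r)
      }
      truth <- field >= stats::quantile(field, p$blob_threshold)
      truth <- largest_component(truth)
      if (!any(truth)) {
        stop("parameter error: blob threshold left no wound", call. = FALSE)
      }
    }
    halo <- matrix(FALSE, p$rows, p$cols)
    halo_dist <- NULL
    if (p$erythema_halo_px > 0L) {
      grown <- truth
      halo_dist <- matrix(Inf, p$rows, p$cols)
      for (d in seq_len(p$erythema_halo_px)) {
        nxt <- binary_dilate(grown, 1L)
        halo_dist[nxt & !grown & !truth] <-
          pmin(halo_dist[nxt & !grown & !truth], d)
        grown <- nxt
      }
      halo <- is.finite(halo_dist) & !truth
    }
    sk <- skin_spectrum(imec_16band_nm)
    wd <- wound_spectrum(imec_16band_nm)
    nb <- length(sk)
    values <- array(rep(sk, each = p$rows * p$cols),
                    dim = c(p$rows, p$cols, nb))
    for (b in seq_len(nb)) {
      plane <- values[, , b]
      plane[truth] <- wd[b]
      if (any(halo)) {
        # convex blend: strongest hemoglobin tint next to the wound edge
        alpha <- 0.6 * (1 - halo_dist[halo] / (p$erythema_halo_px + 1))
        plane[halo] <- alpha * wd[b] + (1 - alpha) * sk[b]
      }
      values[, , b] <- plane
    }
    if (p$illumination_gradient > 0) {
      g <- p$illumination_gradient
      rgrid <- (matrix(seq_len(p$rows), p$rows, p$cols) - 1) /
        max(p$rows - 1, 1)
      cgrid <- (matrix(seq_len(p$cols), p$rows, p$cols, byrow = TRUE) - 1) /
        max(p$cols - 1, 1)
      illum <- 1 + g * ((rgrid + cgrid) - 1)   # plane in [1-g, 1+g]
      values <- values * as.vector(illum)
    }
    if (p$noise_sigma > 0) {
      values <- values + array(stats::rnorm(length(values),
                                            sd = p$noise_sigma),
                               dim = dim(values))
    }
    values <- pmin(pmax(values, 0), .reflectance_ceiling)
  })
  cube <- spectral_cube(values, wavelengths_nm = imec_16band_nm,
                        pixel_pitch_cm = p$pixel_pitch_cm, calibrated = TRUE)
  tm <- wound_mask(truth, p$pixel_pitch_cm)
  structure(list(cube = cube, truth_mask = tm, halo_mask = halo,
                 true_area_cm2 = sum(truth) * p$pixel_pitch_cm^2,
                 params = p),
            class = "phantom_scene")
}

.box_smooth <- function(v, r) {
  k <- 2L * r + 1L
  as.numeric(stats::filter(c(rep(v[1], r), v, rep(v[length(v)], r)),
                           rep(1 / k, k), sides = 2))[(r + 1):(r + length(v))]
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("<phantom_scene> %s, %d x %d px, true area %.3f cm^2 (seed %d)\n",
              x$params$wound_shape, x$params$rows, x$params$cols,
              x$true_area_cm2, x$params$seed))
  invisible(x)
}

#' Simulate a nurse's ruler measurement of a phantom
#'
#' Emulates the bedside LW-rule measurement: length and width are the
#' bounding-box extents of the true wound -- optionally including the
#' erythema halo, since nurses tend to integrate the red, swollen
#' surround into the "wound area" -- each perturbed by an independent
#' uniform ruler error of up to `jitter_cm`, then multiplied.
#'
#' @param scene a `"phantom_scene"`.
#' @param include_halo include the halo ring in the measured extent.
#' @param jitter_cm maximum absolute ruler error per dimension (cm).
#' @param seed seed for the jitter draw.
#' @return An [area_measurement] with method `"nurse_lw"`.
#' @export
simulate_nurse_measurement <- function(scene, include_halo = TRUE,
                                       jitter_cm = 0, seed = 1L) {
  stopifnot(inherits(scene, "phantom_scene"))
  m <- scene$truth_mask$mask
  if (include_halo && any(scene$halo_mask)) m <- m | scene$halo_mask
  idx <- which(m, arr.ind = TRUE)
  pitch <- scene$truth_mask$pixel_pitch_cm
  len <- (max(idx[, 1]) - min(idx[, 1]) + 1L) * pitch
  wid <- (max(idx[, 2]) - min(idx[, 2]) + 1L) * pitch
  if (jitter_cm > 0) {
    withr::with_seed(as.integer(seed), {
      len <- max(len + stats::runif(1, -jitter_cm, jitter_cm), pitch)
      wid <- max(wid + stats::runif(1, -jitter_cm, jitter_cm), pitch)
    })
  }
  area_measurement("nurse_lw", len * wid,
                   provenance = list(include_halo = include_halo,
                                     jitter_cm = jitter_cm, seed = seed,
                                     pixel_pitch_cm = pitch))
}
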