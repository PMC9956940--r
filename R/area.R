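#' Construct an area measurement
#'
#' @param method one of `"nurse_lw"`, `"machine_lw"`, `"machine_morph"`.
#' @param area_cm2 area in square centimetres (>= 0).
#' @param provenance named list of the parameters that produced the value
#'   (pitch, morphology settings, seed, ...).
#' @return An object of class `"area_measurement"`.
#' @export
area_measurement <- function(method = c("machine_lw", "machine_morph",
                                        "nurse_lw"),
                             area_cm2, provenance = list()) {
  method <- match.arg(method)
  if (!is.numeric(area_cm2) || length(area_cm2) != 1L || area_cm2 < 0) {
    stop("area_cm2 must be a single non-negative number", call. = FALSE)
  }
  structure(list(method = method, area_cm2 = area_cm2,
                 provenance = provenance),
            class = "area_measurement")
}

#' @export
print.area_measurement <- function(x, ...) {
  cat(sprintf("<area_measurement> %s: %.2f cm^2\n", x$method, x$area_cm2))
  invisible(x)
}

#' Length-by-width (LW rule) area of a wound mask
#'
#' The bedside ruler convention: maximal extent along rows times maximal
#' extent along columns, i.e. the axis-aligned bounding box of the wound
#' pixels, in cm^2.
#'
#' @param mask a [wound_mask] with at least one wound pixel.
#' @param method tag recorded on the result; `"machine_lw"` by default.
#' @return An [area_measurement].
#' @export
lw_area <- function(mask, method = "machine_lw") {
  stopifnot(inherits(mask, "wound_mask"))
  idx <- which(mask$mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    stop("empty-wound error: mask has no wound pixels", call. = FALSE)
  }
  p <- mask$pixel_pitch_cm
  len <- (max(idx[, 1]) - min(idx[, 1]) + 1L) * p
  wid <- (max(idx[, 2]) - min(idx[, 2]) + 1L) * p
  area_measurement(method, len * wid,
                   provenance = list(pixel_pitch_cm = p,
                                     length_cm = len, width_cm = wid))
}

#' Planimetric (pixel-count) area of a wound mask
#'
#' @param mask a [wound_mask] with at least one wound pixel.
#' @return An [area_measurement] with method `"machine_morph"`.
#' @export
planimetric_area <- function(mask) {
  stopifnot(inherits(mask, "wound_mask"))
  n <- sum(mask$mask)
  if (n == 0L) {
    stop("empty-wound error: mask has no wound pixels", call. = FALSE)
  }
  area_measurement("machine_morph", n * mask$pixel_pitch_cm^2,
                   provenance = list(pixel_pitch_cm = mask$pixel_pitch_cm,
                                     n_pixels = n))
}

#' Measure one case end to end
#'
#' Runs the full measurement pipeline on a calibrated cube: ROI extraction,
#' k-means spectral clustering, wound-cluster selection, then both area
#' estimates -- the LW bounding-box area on the raw wound mask and the
#' planimetric area on the morphology-cleaned mask.
#'
#' @param cube calibrated [spectral_cube].
#' @param region optional [roi]; `NULL` uses the full frame.
#' @param k number of clusters (default 2: wound vs healthy skin).
#' @param seed integer seed for the clustering.
#' @param rule wound-selection rule, see [select_wound_cluster()].
#' @param opening_radius morphology opening radius, see [clean_mask()].
#' @param restarts,max_iter,tol,normalize passed to [kmeans_fit()].
#' @return List with elements `machine_lw` and `machine_morph` (both
#'   [area_measurement]), the raw and cleaned [wound_mask]s (`mask_raw`,
#'   `mask_clean`), and the fitted `model`.
#' @export
measure_case <- function(cube, region = NULL, k = 2L, seed = 1L,
                         rule = "hemoglobin_dip", opening_radius = 1L,
                         restarts = 10L, max_iter = 300L, tol = 1e-6,
                         normalize = FALSE) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (!cube$calibrated) {
    stop("measure_case needs a calibrated cube; run calibrate_reflectance",
         call. = FALSE)
  }
  sub <- if (is.null(region)) cube else extract_roi(cube, region)
  d <- dim(sub$values)
  model <- kmeans_fit(cube_spectra(sub), k = k, seed = seed,
                      restarts = restarts, max_iter = max_iter, tol = tol,
                      normalize = normalize)
  widx <- select_wound_cluster(model, sub$wavelengths_nm, rule = rule)
  mask_raw <- labels_to_mask(model$labels, d[1:2], as.integer(widx),
                             sub$pixel_pitch_cm)
  if (!any(mask_raw$mask)) {
    stop("empty-wound error at the segmentation stage", call. = FALSE)
  }
  mask_clean <- clean_mask(mask_raw, opening_radius = opening_radius)
  prov <- list(k = k, seed = seed, rule = attr(widx, "rule"),
               opening_radius = opening_radius, restarts = restarts,
               pixel_pitch_cm = sub$pixel_pitch_cm)
  lw <- lw_area(mask_raw)
  lw$provenance <- c(lw$provenance, prov)
  morph <- planimetric_area(mask_clean)
  morph$provenance <- c(morph$provenance, prov)
  list(machine_lw = lw, machine_morph = morph,
       mask_raw = mask_raw, mask_clean = mask_clean, model = model)
}
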