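#' Construct a spectral cube
#'
#' A spectral cube is a rows x cols x bands array of sensor counts or
#' reflectance values together with its wavelength grid and the physical
#' size of a pixel. Calibrated cubes hold relative reflectance in
#' [0, 1.10]; the small headroom above 1 absorbs specular noise from
#' uncontrolled bedside lighting.
#'
#' @param values numeric array, rows x cols x bands.
#' @param wavelengths_nm band-center wavelengths (nm); defaults to the
#'   16-band sensor constant [imec_16band_nm] when the band count matches.
#' @param pixel_pitch_cm physical side length of one pixel, in cm.
#' @param calibrated logical; `TRUE` once white-reference calibration has
#'   been applied.
#' @return An object of class `"spectral_cube"`.
#' @export
spectral_cube <- function(values, wavelengths_nm = NULL, pixel_pitch_cm,
                          calibrated = FALSE) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("cube values must be a rows x cols x bands array", call. = FALSE)
  }
  nb <- dim(values)[3L]
  if (is.null(wavelengths_nm)) {
    if (nb != length(imec_16band_nm)) {
      stop("no wavelengths given and band count (", nb,
           ") does not match the bundled 16-band grid", call. = FALSE)
    }
    wavelengths_nm <- imec_16band_nm
  }
  grid <- wavelength_grid(wavelengths_nm)
  if (length(grid) != nb) {
    stop("dimension error: cube has ", nb, " bands but grid lists ",
         length(grid), " wavelengths", call. = FALSE)
  }
  if (!is.numeric(pixel_pitch_cm) || length(pixel_pitch_cm) != 1L ||
      !is.finite(pixel_pitch_cm) || pixel_pitch_cm <= 0) {
    stop("pixel_pitch_cm must be a single positive number", call. = FALSE)
  }
  if (isTRUE(calibrated)) {
    if (any(!is.finite(values)) || any(values < 0) || any(values > 1.10)) {
      stop("calibrated cube values must be finite and in [0, 1.10]",
           call. = FALSE)
    }
  }
  structure(
    list(values = values, wavelengths_nm = as.numeric(grid),
         pixel_pitch_cm = pixel_pitch_cm, calibrated = isTRUE(calibrated)),
    class = "spectral_cube"
  )
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<spectral_cube> %d x %d pixels, %d bands (%g-%g nm), pitch %g cm, %s\n",
              d[1], d[2], d[3], min(x$wavelengths_nm), max(x$wavelengths_nm),
              x$pixel_pitch_cm,
              if (x$calibrated) "calibrated reflectance" else "raw counts"))
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$values)

#' Imaging geometry of an acquisition
#'
#' Captures the acquisition constants of the bedside protocol: the
#' camera-to-surface working distance, the reflectance of the white
#' calibration board, and the physical pixel pitch at that distance.
#' Defaults follow the study protocol: a 98%-reflectance whiteboard imaged
#' at 70 cm.
#'
#' @param working_distance_cm camera-to-surface distance (cm).
#' @param white_reflectance_factor reflectance of the calibration board,
#'   a fraction in (0, 1].
#' @param pixel_pitch_cm centimetres per pixel side.
#' @return An object of class `"imaging_geometry"`.
#' @export
imaging_geometry <- function(working_distance_cm = 70,
                             white_reflectance_factor = 0.98,
                             pixel_pitch_cm = 0.05) {
  if (!is.numeric(white_reflectance_factor) ||
      white_reflectance_factor <= 0 || white_reflectance_factor > 1) {
    stop("white_reflectance_factor must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(working_distance_cm) || working_distance_cm <= 0) {
    stop("working_distance_cm must be positive", call. = FALSE)
  }
  if (!is.numeric(pixel_pitch_cm) || pixel_pitch_cm <= 0) {
    stop("pixel_pitch_cm must be positive", call. = FALSE)
  }
  structure(list(working_distance_cm = working_distance_cm,
                 white_reflectance_factor = white_reflectance_factor,
                 pixel_pitch_cm = pixel_pitch_cm),
            class = "imaging_geometry")
}

# reflectance ceiling: tolerate small specular excursions above 1 by
# clipping rather than erroring
.reflectance_ceiling <- 1.10

#' Construct a binary wound mask
#'
#' @param mask logical matrix (rows x cols), `TRUE` on wound pixels.
#' @param pixel_pitch_cm centimetres per pixel side.
#' @return An object of class `"wound_mask"`.
#' @export
wound_mask <- function(mask, pixel_pitch_cm) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  storage.mode(mask) <- "logical"
  if (anyNA(mask)) stop("mask must not contain NA", call. = FALSE)
  if (!is.numeric(pixel_pitch_cm) || pixel_pitch_cm <= 0) {
    stop("pixel_pitch_cm must be positive", call. = FALSE)
  }
  structure(list(mask = mask, pixel_pitch_cm = pixel_pitch_cm),
            class = "wound_mask")
}

#' @export
print.wound_mask <- function(x, ...) {
  cat(sprintf("<wound_mask> %d x %d, %d wound px, pitch %g cm\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$pixel_pitch_cm))
  invisible(x)
}
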