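#' Convert raw sensor counts to relative reflectance
#'
#' Flat-field (white-reference) calibration: per pixel and band,
#' \deqn{R = f \cdot (raw - dark) / (white - dark)}
#' where `f` is the known reflectance of the calibration board (0.98 for
#' the study's whiteboard) and the dark frame defaults to zero when the
#' device provides none. Values are clipped to \[0, 1.10\]; the headroom
#' above 1 tolerates specular noise in uncontrolled bedside lighting.
#'
#' @param raw uncalibrated [spectral_cube] of sensor counts.
#' @param white white-reference [spectral_cube]: either a frame with the
#'   same dimensions as `raw`, or a 1 x 1 x bands cube (a single reference
#'   spectrum broadcast over the scene).
#' @param dark optional dark frame, same shapes accepted as `white`;
#'   `NULL` means zero dark current.
#' @param geometry an [imaging_geometry]; supplies the board reflectance.
#' @return A calibrated [spectral_cube].
#' @export
calibrate_reflectance <- function(raw, white, dark = NULL,
                                  geometry = imaging_geometry()) {
  stopifnot(inherits(raw, "spectral_cube"), inherits(white, "spectral_cube"))
  d <- dim(raw$values)
  if (!identical(raw$wavelengths_nm, white$wavelengths_nm)) {
    stop("calibration error: raw and white wavelength grids differ",
         call. = FALSE)
  }
  wv <- .broadcast_frame(white$values, d, "white")
  dv <- if (is.null(dark)) {
    array(0, dim = d)
  } else {
    stopifnot(inherits(dark, "spectral_cube"))
    .broadcast_frame(dark$values, d, "dark")
  }
  denom <- wv - dv
  bad <- sum(denom <= 0)
  if (bad > 0) {
    stop("calibration error: white - dark is non-positive at ", bad,
         " pixel-band entries", call. = FALSE)
  }
  refl <- geometry$white_reflectance_factor * (raw$values - dv) / denom
  refl <- pmin(pmax(refl, 0), .reflectance_ceiling)
  spectral_cube(refl, wavelengths_nm = raw$wavelengths_nm,
                pixel_pitch_cm = raw$pixel_pitch_cm, calibrated = TRUE)
}

.broadcast_frame <- function(v, d, what) {
  dv <- dim(v)
  if (identical(dv, d)) return(v)
  if (dv[1] == 1L && dv[2] == 1L && dv[3] == d[3]) {
    return(aperm(array(v[1, 1, ], dim = c(d[3], d[1], d[2])), c(2, 3, 1)))
  }
  stop("calibration error: ", what,
       " frame dimensions match neither the raw cube nor 1 x 1 x bands",
       call. = FALSE)
}

#' Demosaic a snapshot-mosaic frame into a spectral cube
#'
#' A snapshot mosaic sensor tiles the focal plane with a repeating
#' `pattern_size` x `pattern_size` grid of spectral filters (4 x 4 = 16
#' bands here). Band `b` (0-based, row-major over the tile: offsets
#' `b %/% pattern_size`, `b %% pattern_size`) is the sub-sampled image at
#' that tile offset; bands map to the sorted wavelength grid in tile
#' row-major order. The output is `pattern_size`-fold smaller spatially and
#' its pixel pitch correspondingly larger.
#'
#' @param mosaic numeric matrix, the single-plane raw frame; both
#'   dimensions must be divisible by `pattern_size`.
#' @param pattern_size tile side length; `pattern_size^2` bands.
#' @param wavelengths_nm band wavelengths; defaults to the 16-band grid.
#' @param geometry an [imaging_geometry]; its pitch is the mosaic pixel
#'   pitch, scaled by `pattern_size` in the result.
#' @return An uncalibrated [spectral_cube].
#' @seealso [snapshot_mosaic()] for the inverse tiling.
#' @export
demosaic_snapshot <- function(mosaic, pattern_size = 4L,
                              wavelengths_nm = imec_16band_nm,
                              geometry = imaging_geometry()) {
  if (!is.matrix(mosaic)) stop("mosaic must be a matrix", call. = FALSE)
  p <- as.integer(pattern_size)
  if (nrow(mosaic) %% p != 0L || ncol(mosaic) %% p != 0L) {
    stop("dimension error: mosaic ", nrow(mosaic), " x ", ncol(mosaic),
         " is not divisible by pattern size ", p, call. = FALSE)
  }
  nb <- p * p
  if (length(wavelengths_nm) != nb) {
    stop("dimension error: pattern size ", p, " implies ", nb,
         " bands but grid lists ", length(wavelengths_nm), call. = FALSE)
  }
  rows <- nrow(mosaic) %/% p
  cols <- ncol(mosaic) %/% p
  values <- array(0, dim = c(rows, cols, nb))
  for (b in 0:(nb - 1L)) {
    ro <- b %/% p
    co <- b %% p
    values[, , b + 1L] <- mosaic[seq(ro + 1L, nrow(mosaic), by = p),
                                 seq(co + 1L, ncol(mosaic), by = p)]
  }
  spectral_cube(values, wavelengths_nm = wavelengths_nm,
                pixel_pitch_cm = geometry$pixel_pitch_cm * p)
}

#' Re-interleave a cube into its snapshot mosaic frame
#'
#' Exact inverse of [demosaic_snapshot()] for cubes whose band count is a
#' perfect square.
#'
#' @param cube a [spectral_cube] with `p^2` bands.
#' @return Numeric matrix of the tiled single-plane frame.
#' @export
snapshot_mosaic <- function(cube) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$values)
  p <- as.integer(round(sqrt(d[3])))
  if (p * p != d[3]) {
    stop("band count ", d[3], " is not a perfect square", call. = FALSE)
  }
  mosaic <- matrix(0, nrow = d[1] * p, ncol = d[2] * p)
  for (b in 0:(d[3] - 1L)) {
    ro <- b %/% p
    co <- b %% p
    mosaic[seq(ro + 1L, nrow(mosaic), by = p),
           seq(co + 1L, ncol(mosaic), by = p)] <- cube$values[, , b + 1L]
  }
  mosaic
}
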