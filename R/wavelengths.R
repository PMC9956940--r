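#' Band-center wavelengths of the 16-band snapshot mosaic sensor
#'
#' The visible-range band centers (nm) of the 4x4 snapshot mosaic
#' hyperspectral sensor used for bedside wound imaging.
#'
#' @format Numeric vector of 16 wavelengths in nanometres, strictly increasing.
#' @export
imec_16band_nm <- c(465, 474, 485, 496, 510, 522, 534, 546,
                    548, 562, 578, 586, 600, 608, 624, 630)

#' Validate a wavelength grid
#'
#' A wavelength grid is a strictly increasing numeric vector of band-center
#' wavelengths in nanometres, restricted to 400--1000 nm (the sensor class
#' targeted here is visible/near-infrared).
#'
#' @param wavelengths_nm numeric vector of band centers (nm).
#' @return The validated numeric vector, with class `"wavelength_grid"`.
#' @examples
#' wavelength_grid(imec_16band_nm)
#' @export
wavelength_grid <- function(wavelengths_nm) {
  w <- as.numeric(wavelengths_nm)
  if (length(w) < 1L || anyNA(w)) {
    stop("wavelength grid must be non-empty and free of NA", call. = FALSE)
  }
  if (any(diff(w) <= 0)) {
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  }
  if (any(w < 400) || any(w > 1000)) {
    stop("wavelengths must lie in [400, 1000] nm", call. = FALSE)
  }
  structure(w, class = "wavelength_grid")
}
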