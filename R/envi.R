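#' Read a hyperspectral cube from an ENVI header + flat binary raster
#'
#' Supports band-sequential (`bsq`), band-interleaved-by-line (`bil`) and
#' band-interleaved-by-pixel (`bip`) layouts with `uint16`, `int16`,
#' `float32` or `float64` samples. Wavelengths are taken from the header's
#' `wavelength` block when present, otherwise the bundled 16-band sensor
#' grid is assumed (and the band count must then be 16).
#'
#' @param header_path path to the `.hdr` text header.
#' @param data_path path to the flat binary raster; defaults to the header
#'   path with its extension dropped.
#' @param geometry an [imaging_geometry] supplying the pixel pitch.
#' @return An uncalibrated [spectral_cube].
#' @seealso [write_envi_cube()], [read_tiff_cube()]
#' @export
read_envi_cube <- function(header_path, data_path = NULL,
                           geometry = imaging_geometry()) {
  hdr <- .parse_envi_header(header_path)
  for (f in c("samples", "lines", "bands", "interleave", "data type")) {
    if (is.null(hdr[[f]])) {
      stop("format error: ENVI header is missing field '", f, "'",
           call. = FALSE)
    }
  }
  samples <- as.integer(hdr$samples)
  lines <- as.integer(hdr$lines)
  bands <- as.integer(hdr$bands)
  interleave <- tolower(hdr$interleave)
  if (!interleave %in% c("bsq", "bil", "bip")) {
    stop("format error: unsupported interleave '", interleave, "'",
         call. = FALSE)
  }
  dtype <- as.integer(hdr[["data type"]])
  spec <- switch(as.character(dtype),
    "2"  = list(what = "integer", size = 2L, signed = TRUE),
    "4"  = list(what = "numeric", size = 4L, signed = TRUE),
    "5"  = list(what = "numeric", size = 8L, signed = TRUE),
    "12" = list(what = "integer", size = 2L, signed = FALSE),
    stop("format error: unsupported ENVI data type ", dtype, call. = FALSE))
  wl <- NULL
  if (!is.null(hdr$wavelength)) {
    wl <- as.numeric(strsplit(hdr$wavelength, ",")[[1]])
    if (length(wl) != bands) {
      stop("dimension error: header declares ", bands, " bands but lists ",
           length(wl), " wavelengths", call. = FALSE)
    }
  }
  if (is.null(data_path)) {
    data_path <- sub("\\.hdr$", "", header_path)
  }
  if (!file.exists(data_path)) {
    stop("format error: raster file not found: ", data_path, call. = FALSE)
  }
  n <- samples * lines * bands
  con <- file(data_path, "rb")
  on.exit(close(con))
  raw_v <- readBin(con, what = spec$what, n = n, size = spec$size,
                   signed = spec$signed, endian = "little")
  if (length(raw_v) != n) {
    stop("format error: raster holds ", length(raw_v),
         " values, header implies ", n, call. = FALSE)
  }
  values <- switch(interleave,
    # bsq: sample fastest, then line, then band
    bsq = aperm(array(raw_v, dim = c(samples, lines, bands)), c(2, 1, 3)),
    # bil: sample fastest, then band, then line
    bil = aperm(array(raw_v, dim = c(samples, bands, lines)), c(3, 1, 2)),
    # bip: band fastest, then sample, then line
    bip = aperm(array(raw_v, dim = c(bands, samples, lines)), c(3, 2, 1)))
  spectral_cube(values, wavelengths_nm = wl,
                pixel_pitch_cm = geometry$pixel_pitch_cm)
}

#' Write a spectral cube as an ENVI header + flat binary raster
#'
#' @param cube a [spectral_cube].
#' @param header_path output path for the `.hdr` header; the raster is
#'   written next to it with the extension dropped.
#' @param interleave one of `"bsq"`, `"bil"`, `"bip"`.
#' @param data_type ENVI type code: 2 (int16), 4 (float32, default),
#'   5 (float64) or 12 (uint16). Integer types round-trip bit-exactly.
#' @return Invisibly, the raster path.
#' @export
write_envi_cube <- function(cube, header_path, interleave = "bsq",
                            data_type = 4L) {
  stopifnot(inherits(cube, "spectral_cube"))
  interleave <- match.arg(tolower(interleave), c("bsq", "bil", "bip"))
  d <- dim(cube$values)
  v <- switch(interleave,
    bsq = aperm(cube$values, c(2, 1, 3)),
    bil = aperm(cube$values, c(2, 3, 1)),
    bip = aperm(cube$values, c(3, 2, 1)))
  data_path <- sub("\\.hdr$", "", header_path)
  con <- file(data_path, "wb")
  on.exit(close(con))
  if (data_type %in% c(2L, 12L)) {
    iv <- as.integer(round(as.vector(v)))
    if (data_type == 12L) {
      if (any(iv < 0L | iv > 65535L)) {
        stop("values out of uint16 range", call. = FALSE)
      }
      iv <- ifelse(iv > 32767L, iv - 65536L, iv)  # two's-complement low bytes
    } else if (any(iv < -32768L | iv > 32767L)) {
      stop("values out of int16 range", call. = FALSE)
    }
    writeBin(iv, con, size = 2L, endian = "little")
  } else if (data_type == 4L) {
    writeBin(as.numeric(as.vector(v)), con, size = 4L, endian = "little")
  } else if (data_type == 5L) {
    writeBin(as.numeric(as.vector(v)), con, size = 8L, endian = "little")
  } else {
    stop("unsupported ENVI data type ", data_type, call. = FALSE)
  }
  hdr <- c(
    "ENVI",
    "description = {hsiwound spectral cube}",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", data_type),
    paste0("interleave = ", interleave),
    "byte order = 0",
    paste0("wavelength = {", paste(cube$wavelengths_nm, collapse = ", "), "}"))
  writeLines(hdr, header_path)
  invisible(data_path)
}

# Parse an ENVI header into a named list; brace-delimited values may span
# lines and are returned as a single comma-separated string.
.parse_envi_header <- function(path) {
  if (!file.exists(path)) {
    stop("format error: header file not found: ", path, call. = FALSE)
  }
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  out <- list()
  # brace values first (may contain newlines)
  m <- gregexpr("([a-zA-Z ][a-zA-Z0-9 ]*?)\\s*=\\s*\\{([^}]*)\\}", txt)[[1]]
  if (m[1] != -1L) {
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    pieces <- substring(txt, starts, starts + lens - 1L)
    for (piece in pieces) {
      key <- trimws(sub("=.*", "", piece))
      val <- sub("^[^{]*\\{", "", piece)
      val <- gsub("\\}\\s*$", "", val)
      out[[tolower(key)]] <- gsub("\\s+", " ", trimws(val))
    }
    for (piece in pieces) txt <- sub(piece, "", txt, fixed = TRUE)
  }
  for (line in strsplit(txt, "\n")[[1]]) {
    if (!grepl("=", line, fixed = TRUE)) next
    key <- tolower(trimws(sub("=.*", "", line)))
    val <- trimws(sub("^[^=]*=", "", line))
    if (nzchar(key)) {
      if (!is.null(out[[key]])) {
        stop("format error: duplicate header field '", key, "'",
             call. = FALSE)
      }
      out[[key]] <- val
    }
  }
  out
}

#' Read a multi-band TIFF as a spectral cube
#'
#' Alternate input path for cubes exported as multi-page TIFF, one page per
#' band in wavelength order.
#'
#' @inheritParams read_envi_cube
#' @param path TIFF file path.
#' @param wavelengths_nm band wavelengths; defaults to the 16-band grid.
#' @return An uncalibrated [spectral_cube].
#' @export
read_tiff_cube <- function(path, wavelengths_nm = imec_16band_nm,
                           geometry = imaging_geometry()) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(wavelengths_nm)) {
    stop("dimension error: TIFF has ", length(pages),
         " pages but grid lists ", length(wavelengths_nm), " wavelengths",
         call. = FALSE)
  }
  values <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                             length(pages)))
  for (b in seq_along(pages)) values[, , b] <- pages[[b]]
  spectral_cube(values, wavelengths_nm = wavelengths_nm,
                pixel_pitch_cm = geometry$pixel_pitch_cm)
}
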