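# Shared fixture builders. Everything is generated in code at test time.

# small cube with reproducible pseudo-random values
make_test_cube <- function(rows = 4L, cols = 4L, bands = 16L, seed = 42L,
                           pitch = 0.05, integer_values = FALSE,
                           calibrated = FALSE) {
  vals <- withr::with_seed(seed, {
    if (integer_values) {
      array(sample.int(4000L, rows * cols * bands, replace = TRUE),
            dim = c(rows, cols, bands))
    } else {
      array(stats::runif(rows * cols * bands, 0, 1), dim = c(rows, cols, bands))
    }
  })
  spectral_cube(vals, wavelengths_nm = imec_16band_nm[seq_len(bands)],
                pixel_pitch_cm = pitch, calibrated = calibrated)
}

# constant-valued cube
const_cube <- function(value, rows = 3L, cols = 3L, bands = 16L,
                       pitch = 0.05, calibrated = FALSE) {
  spectral_cube(array(value, dim = c(rows, cols, bands)),
                pixel_pitch_cm = pitch, calibrated = calibrated)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# exhaustive-partition optimum of 2-means: enumerate every binary labeling
exhaustive_2means_inertia <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (code in 0:(2^n - 1)) {
    lab <- as.integer(intToBits(code))[1:n]
    if (length(unique(lab)) < 2L) next
    v <- 0
    for (j in 0:1) {
      xs <- x[lab == j, , drop = FALSE]
      v <- v + sum(sweep(xs, 2, colMeans(xs))^2)
    }
    if (v < best) best <- v
  }
  best
}

random_mask <- function(rows = 20L, cols = 20L, p = 0.3, seed = 1L,
                        pitch = 0.05) {
  m <- withr::with_seed(seed,
    matrix(stats::runif(rows * cols) < p, rows, cols))
  wound_mask(m, pitch)
}
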