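#' Rectangular region of interest
#'
#' Frames the wound and drops unrelated content (sheets, clothing) before
#' clustering. Indices are 1-based and inclusive, matching R's matrix
#' indexing.
#'
#' @param r0,r1 first and last row.
#' @param c0,c1 first and last column.
#' @return An object of class `"roi"`.
#' @export
roi <- function(r0, r1, c0, c1) {
  v <- as.integer(c(r0, r1, c0, c1))
  if (anyNA(v) || v[1] < 1L || v[3] < 1L || v[1] > v[2] || v[3] > v[4]) {
    stop("bounds error: need 1 <= r0 <= r1 and 1 <= c0 <= c1", call. = FALSE)
  }
  structure(list(r0 = v[1], r1 = v[2], c0 = v[3], c1 = v[4]), class = "roi")
}

#' Extract a sub-cube
#'
#' @param cube a [spectral_cube].
#' @param region an [roi]; must lie within the cube.
#' @return The sub-[spectral_cube]; wavelength grid, pitch and calibration
#'   flag are unchanged.
#' @export
extract_roi <- function(cube, region) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(region, "roi"))
  d <- dim(cube$values)
  if (region$r1 > d[1] || region$c1 > d[2]) {
    stop("bounds error: roi [", region$r0, ",", region$r1, "]x[",
         region$c0, ",", region$c1, "] exceeds cube ", d[1], " x ", d[2],
         call. = FALSE)
  }
  sub <- cube$values[region$r0:region$r1, region$c0:region$c1, ,
                     drop = FALSE]
  spectral_cube(sub, wavelengths_nm = cube$wavelengths_nm,
                pixel_pitch_cm = cube$pixel_pitch_cm,
                calibrated = cube$calibrated)
}

#' Flatten a cube into a pixel-spectra matrix
#'
#' @param cube a [spectral_cube].
#' @return Matrix with one row per pixel in row-major (row, then column)
#'   order and one column per band.
#' @export
cube_spectra <- function(cube) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$values)
  # row-major pixel order: transpose the spatial plane of each band
  m <- matrix(aperm(cube$values, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
  colnames(m) <- paste0("nm", cube$wavelengths_nm)
  m
}

#' Fit k-means to pixel spectra
#'
#' Plain Lloyd iterations with k-means++ initialization, run `restarts`
#' times from the given seed; the run with the lowest within-cluster sum
#' of squares (inertia) is returned. Iteration stops when the largest
#' centroid shift drops below `tol` or after `max_iter` sweeps. If a
#' cluster empties during iteration, its centroid is re-seeded at the
#' point currently farthest from its own centroid, so k is never silently
#' reduced. Deterministic for a given seed.
#'
#' @param spectra numeric matrix, one spectrum per row.
#' @param k number of clusters (>= 1).
#' @param seed integer seed; all randomness (initialization, restarts)
#'   derives from it.
#' @param restarts independent k-means++ starts (>= 1).
#' @param max_iter Lloyd sweep cap per start.
#' @param tol convergence threshold on the largest centroid displacement
#'   (Euclidean, reflectance units).
#' @param normalize if `TRUE`, each spectrum is divided by its own mean
#'   before clustering (brightness-invariant mode); off by default, since
#'   plain distance on reflectance is what separates dark wound tissue
#'   from bright skin.
#' @return A `"cluster_model"`: `k`, `centroids` (k x bands), 1-based
#'   `labels`, `inertia`, `inertia_trace` of the winning run, `seed`,
#'   `n_iter`, `normalize`.
#' @export
kmeans_fit <- function(spectra, k, seed = 1L, restarts = 10L,
                       max_iter = 300L, tol = 1e-6, normalize = FALSE) {
  x <- as.matrix(spectra)
  storage.mode(x) <- "double"
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (restarts < 1L) stop("restarts must be >= 1", call. = FALSE)
  n_distinct <- nrow(unique(x))
  if (k > n_distinct) {
    stop("degenerate input: k = ", k, " exceeds the ", n_distinct,
         " distinct spectra", call. = FALSE)
  }
  if (normalize) {
    mu <- rowMeans(x)
    if (any(mu == 0)) stop("cannot mean-normalize all-zero spectra",
                           call. = FALSE)
    x <- x / mu
  }
  best <- NULL
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(restarts)) {
      fit <- .lloyd_once(x, k, max_iter, tol)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  structure(list(k = k, centroids = best$centroids, labels = best$labels,
                 inertia = best$inertia, inertia_trace = best$trace,
                 seed = as.integer(seed), n_iter = best$n_iter,
                 normalize = normalize),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d, n = %d, inertia = %.6g, %d iterations (seed %d)\n",
              x$k, length(x$labels), x$inertia, x$n_iter, x$seed))
  invisible(x)
}

# squared Euclidean distances from every row of x to every row of centers
.sqdist <- function(x, centers) {
  xc <- x %*% t(centers)
  outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * xc
}

# greedy k-means++: at each step draw several candidates with probability
# proportional to squared distance from the chosen centers and keep the one
# that most reduces the total potential
.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, nrow = k, ncol = ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  if (k > 1L) {
    n_trials <- 2L + as.integer(ceiling(log(k)))
    d2 <- pmax(.sqdist(x, centers[1L, , drop = FALSE])[, 1L], 0)
    for (j in 2:k) {
      cand <- if (sum(d2) > 0) {
        sample.int(n, min(n_trials, n), prob = pmax(d2, 0))
      } else {
        sample.int(n, 1L)
      }
      pots <- vapply(cand, function(ci) {
        sum(pmin(d2, pmax(.sqdist(x, x[ci, , drop = FALSE])[, 1L], 0)))
      }, numeric(1))
      pick <- cand[which.min(pots)]
      centers[j, ] <- x[pick, ]
      d2 <- pmin(d2, pmax(.sqdist(x, x[pick, , drop = FALSE])[, 1L], 0))
    }
  }
  centers
}

.lloyd_once <- function(x, k, max_iter, tol) {
  centers <- .kmeanspp_init(x, k)
  labels <- integer(nrow(x))
  trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- .sqdist(x, centers)
    labels <- max.col(-d2, ties.method = "first")
    # re-seed any emptied cluster at the worst-fitted point
    for (j in which(tabulate(labels, nbins = k) == 0L)) {
      far <- which.max(d2[cbind(seq_len(nrow(x)), labels)])
      centers[j, ] <- x[far, ]
      d2[, j] <- .sqdist(x, centers[j, , drop = FALSE])[, 1L]
      labels <- max.col(-d2, ties.method = "first")
    }
    new_centers <- centers
    for (j in seq_len(k)) {
      new_centers[j, ] <- colMeans(x[labels == j, , drop = FALSE])
    }
    trace <- c(trace, sum(pmax(
      .sqdist(x, new_centers)[cbind(seq_len(nrow(x)), labels)], 0)))
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol || iter >= max_iter) break
  }
  d2 <- .sqdist(x, centers)
  labels <- max.col(-d2, ties.method = "first")
  polished <- .hartigan_polish(x, centers, labels)
  d2 <- .sqdist(x, polished$centers)
  inertia <- sum(pmax(d2[cbind(seq_len(nrow(x)), polished$labels)], 0))
  list(centroids = polished$centers, labels = polished$labels,
       inertia = inertia, trace = trace, n_iter = iter)
}

# Hartigan-style refinement after Lloyd convergence: while some single
# point can be reassigned with a net drop in total within-cluster SSE
# (accounting for the centroid shifts its move causes), apply the best
# such move. Strictly inertia-decreasing, so Lloyd's guarantees are kept;
# escapes the fixed points Lloyd cannot leave.
.hartigan_polish <- function(x, centers, labels, max_moves = 200L) {
  n <- nrow(x)
  k <- nrow(centers)
  sizes <- tabulate(labels, nbins = k)
  for (move in seq_len(max_moves)) {
    d2 <- pmax(.sqdist(x, centers), 0)
    own <- d2[cbind(seq_len(n), labels)]
    # SSE released by removing the point from its cluster
    release <- ifelse(sizes[labels] > 1L,
                      sizes[labels] / (sizes[labels] - 1L) * own, 0)
    cost <- sweep(d2, 2, sizes / (sizes + 1L), "*")  # SSE added on arrival
    cost[cbind(seq_len(n), labels)] <- Inf
    gain <- release - apply(cost, 1, min)
    gain[sizes[labels] == 1L] <- -Inf               # never empty a cluster
    i <- which.max(gain)
    if (gain[i] <= 1e-12) break
    from <- labels[i]
    to <- which.min(cost[i, ])
    centers[from, ] <- (centers[from, ] * sizes[from] - x[i, ]) /
      (sizes[from] - 1L)
    centers[to, ] <- (centers[to, ] * sizes[to] + x[i, ]) / (sizes[to] + 1L)
    sizes[from] <- sizes[from] - 1L
    sizes[to] <- sizes[to] + 1L
    labels[i] <- to
  }
  # final Lloyd sweeps so centroids equal their cluster means exactly
  for (sweep_i in 1:100) {
    d2 <- .sqdist(x, centers)
    new_labels <- max.col(-d2, ties.method = "first")
    if (all(tabulate(new_labels, nbins = k) > 0L)) labels <- new_labels
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(x[labels == j, , drop = FALSE])
    }
    if (identical(new_labels, labels) || any(tabulate(new_labels, k) == 0L))
      break
  }
  list(centers = centers, labels = labels)
}

#' Identify the wound cluster
#'
#' Wound tissue (granulation, erythema) absorbs strongly in the
#' oxy-hemoglobin bands of the green-yellow range while healthy skin stays
#' comparatively flat, so the default `"hemoglobin_dip"` rule picks the
#' cluster whose centroid minimizes the ratio of mean reflectance over
#' 534--586 nm to mean reflectance over 600--630 nm. The `"darkest"` rule
#' instead picks the centroid with the lowest overall mean reflectance.
#'
#' @param model a `"cluster_model"` from [kmeans_fit()] (k >= 2).
#' @param wavelengths_nm wavelengths the model was fitted on.
#' @param rule `"hemoglobin_dip"` (default) or `"darkest"`.
#' @return The 1-based index of the wound cluster, with the rule and the
#'   per-cluster scores attached as attributes.
#' @export
select_wound_cluster <- function(model, wavelengths_nm = imec_16band_nm,
                                 rule = c("hemoglobin_dip", "darkest")) {
  stopifnot(inherits(model, "cluster_model"))
  rule <- match.arg(rule)
  if (model$k < 2L) {
    stop("selection error: need k >= 2 to contrast wound and skin",
         call. = FALSE)
  }
  w <- wavelengths_nm
  if (length(w) != ncol(model$centroids)) {
    stop("wavelength grid length does not match centroid bands",
         call. = FALSE)
  }
  scores <- if (rule == "hemoglobin_dip") {
    dip <- w >= 534 & w <= 586
    ref <- w >= 600 & w <= 630
    if (!any(dip) || !any(ref)) {
      stop("grid has no bands in the 534-586 or 600-630 nm windows",
           call. = FALSE)
    }
    rowMeans(model$centroids[, dip, drop = FALSE]) /
      rowMeans(model$centroids[, ref, drop = FALSE])
  } else {
    rowMeans(model$centroids)
  }
  idx <- which.min(scores)
  structure(idx, rule = rule, scores = scores)
}

#' Turn cluster labels into a wound mask
#'
#' @param labels per-pixel 1-based cluster labels in row-major pixel order
#'   (as produced by [kmeans_fit()] on [cube_spectra()] output).
#' @param shape `c(rows, cols)` of the source raster.
#' @param wound_index cluster index to mark as wound.
#' @param pixel_pitch_cm centimetres per pixel.
#' @return A [wound_mask].
#' @export
labels_to_mask <- function(labels, shape, wound_index, pixel_pitch_cm) {
  shape <- as.integer(shape)
  if (length(labels) != prod(shape)) {
    stop("labels length ", length(labels), " does not equal rows x cols = ",
         prod(shape), call. = FALSE)
  }
  k <- max(labels)
  if (wound_index < 1L || wound_index > k) {
    stop("index error: wound_index ", wound_index, " outside 1..", k,
         call. = FALSE)
  }
  m <- matrix(labels == wound_index, nrow = shape[1], ncol = shape[2],
              byrow = TRUE)
  wound_mask(m, pixel_pitch_cm)
}
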