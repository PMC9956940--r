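# Binary morphology on logical matrices. All operations use the cross
# (plus-shaped) structuring element and 4-connectivity; implemented by
# vectorized shifts so semantics are exact and explicit.

.shift_mat <- function(m, dr, dc, fill = FALSE) {
  out <- matrix(fill, nrow = nrow(m), ncol = ncol(m))
  rs <- seq_len(nrow(m)) - dr
  cs <- seq_len(ncol(m)) - dc
  ok_r <- rs >= 1L & rs <= nrow(m)
  ok_c <- cs >= 1L & cs <= ncol(m)
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

.cross_offsets <- function(radius) {
  off <- cbind(0L, 0L)
  for (i in seq_len(radius)) {
    off <- rbind(off, c(i, 0L), c(-i, 0L), c(0L, i), c(0L, -i))
  }
  off
}

#' Binary erosion with a cross structuring element
#'
#' Pixels outside the image count as background, so objects shrink at the
#' frame edge.
#'
#' @param m logical matrix.
#' @param radius arm length of the cross (pixels).
#' @return Logical matrix.
#' @export
binary_erode <- function(m, radius = 1L) {
  out <- m
  for (i in seq_len(nrow(.cross_offsets(radius)))) {
    off <- .cross_offsets(radius)[i, ]
    out <- out & .shift_mat(m, off[1], off[2], fill = FALSE)
  }
  out
}

#' Binary dilation with a cross structuring element
#' @inheritParams binary_erode
#' @return Logical matrix.
#' @export
binary_dilate <- function(m, radius = 1L) {
  out <- m
  for (i in seq_len(nrow(.cross_offsets(radius)))) {
    off <- .cross_offsets(radius)[i, ]
    out <- out | .shift_mat(m, off[1], off[2], fill = FALSE)
  }
  out
}

#' Binary opening (erosion then dilation)
#'
#' Removes speckle smaller than the structuring element without growing
#' the remaining object; anti-extensive (output is a subset of the input).
#'
#' @inheritParams binary_erode
#' @return Logical matrix.
#' @export
binary_opening <- function(m, radius = 1L) {
  binary_dilate(binary_erode(m, radius), radius)
}

#' Label 4-connected components
#'
#' Iterative minimum-label propagation; components are numbered 1..n in
#' order of their smallest row-major pixel index.
#'
#' @param m logical matrix.
#' @return Integer matrix of component labels, 0 on background.
#' @export
label_components <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  lab[m] <- seq_len(sum(m))
  lab[!m] <- NA_integer_
  repeat {
    nb <- pmin(.shift_mat(lab, 1L, 0L, fill = NA),
               .shift_mat(lab, -1L, 0L, fill = NA),
               .shift_mat(lab, 0L, 1L, fill = NA),
               .shift_mat(lab, 0L, -1L, fill = NA), na.rm = TRUE)
    new <- pmin(lab, nb, na.rm = TRUE)
    new[!m] <- NA_integer_
    if (identical(new, lab)) break
    lab <- new
  }
  lab[!m] <- 0L
  ids <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], ids)
  lab
}

#' Keep the largest 4-connected component
#'
#' Ties on pixel count are broken by the smaller top-left bounding-box
#' corner (row first, then column).
#'
#' @param m logical matrix with at least one `TRUE` pixel.
#' @return Logical matrix retaining only the winning component.
#' @export
largest_component <- function(m) {
  lab <- label_components(m)
  n <- max(lab)
  if (n == 0L) stop("empty-wound error: no components to keep", call. = FALSE)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1L) {
    corners <- t(vapply(cand, function(j) {
      idx <- which(lab == j, arr.ind = TRUE)
      c(min(idx[, 1]), min(idx[, 2]))
    }, numeric(2)))
    cand <- cand[order(corners[, 1], corners[, 2])][1L]
  }
  lab == cand[1L]
}

#' Fill fully enclosed holes
#'
#' Background pixels not 4-connected to the image border are holes and are
#' set to foreground.
#'
#' @param m logical matrix.
#' @return Logical matrix with holes filled.
#' @export
fill_holes <- function(m) {
  bg <- !m
  reach <- matrix(FALSE, nrow(m), ncol(m))
  reach[1L, ] <- bg[1L, ]
  reach[nrow(m), ] <- bg[nrow(m), ]
  reach[, 1L] <- reach[, 1L] | bg[, 1L]
  reach[, ncol(m)] <- reach[, ncol(m)] | bg[, ncol(m)]
  repeat {
    grown <- reach |
      (.shift_mat(reach, 1L, 0L) & bg) |
      (.shift_mat(reach, -1L, 0L) & bg) |
      (.shift_mat(reach, 0L, 1L) & bg) |
      (.shift_mat(reach, 0L, -1L) & bg)
    grown <- grown & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  m | (bg & !reach)
}

#' Clean a wound mask for planimetry
#'
#' The morphology chain applied before pixel-count area measurement:
#' opening with a cross of `opening_radius` (speckle removal), then the
#' single largest 4-connected component (one wound per case), then filling
#' of fully enclosed holes. Apart from hole filling the result is a subset
#' of the input.
#'
#' @param mask a [wound_mask].
#' @param opening_radius cross arm length in pixels (default 1).
#' @param min_component minimum pixel count the surviving component must
#'   reach; smaller results raise an empty-wound error.
#' @return A cleaned [wound_mask].
#' @export
clean_mask <- function(mask, opening_radius = 1L, min_component = 1L) {
  stopifnot(inherits(mask, "wound_mask"))
  m <- binary_opening(mask$mask, opening_radius)
  if (!any(m)) {
    stop("empty-wound error: mask emptied at the opening stage",
         call. = FALSE)
  }
  m <- largest_component(m)
  if (sum(m) < min_component) {
    stop("empty-wound error: largest component (", sum(m),
         " px) is below min_component at the component stage",
         call. = FALSE)
  }
  m <- fill_holes(m)
  wound_mask(m, mask$pixel_pitch_cm)
}
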