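#' Detect nucleus-like spots in a single-channel frame
#'
#' Band-pass blob detection: difference of Gaussians at scale `sigma_px`,
#' local maxima above `threshold_rel` of the filtered maximum, non-maximum
#' suppression at `min_sep_px`, and sub-pixel refinement by intensity-weighted
#' centroid in a window of radius `2 * sigma_px`.
#'
#' @param image Numeric matrix, `image[i, j]` the pixel at x-index i,
#'   y-index j; pixel centre of `[i, j]` is `((i - 0.5) px, (j - 0.5) px)`.
#' @param pixel_size_um Pixel size, micrometres.
#' @param sigma_px Spot scale for the band-pass filter.
#' @param threshold_rel Relative intensity threshold in `(0, 1)`.
#' @param min_sep_px Minimum separation between detections, pixels.
#' @return Tibble with `x_um`, `y_um`, `intensity`; empty for a blank frame.
#' @export
detect_nuclei <- function(image, pixel_size_um = 1, sigma_px = 2,
                          threshold_rel = 0.2, min_sep_px = 5) {
  stopifnot(is.matrix(image), sigma_px > 0, min_sep_px >= 1)
  bp <- EBImage::gblur(image, sigma = sigma_px) -
    EBImage::gblur(image, sigma = 2 * sigma_px)
  mx <- max(bp)
  if (!is.finite(mx) || mx <= 0) return(empty_detections())
  thr <- threshold_rel * mx
  cand <- local_maxima(bp, floor(min_sep_px / 2))
  cand <- cand[bp[cand] >= thr, , drop = FALSE]
  if (nrow(cand) == 0) return(empty_detections())
  # non-maximum suppression at min_sep_px
  ord <- order(bp[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!keep[k]) next
    if (k < nrow(cand)) {
      d2 <- (cand[-(1:k), 1] - cand[k, 1])^2 + (cand[-(1:k), 2] - cand[k, 2])^2
      keep[-(1:k)][d2 < min_sep_px^2] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  refined <- refine_centroids(image, cand, radius = ceiling(2 * sigma_px))
  tibble::tibble(x_um = (refined[, 1] - 0.5) * pixel_size_um,
                 y_um = (refined[, 2] - 0.5) * pixel_size_um,
                 intensity = bp[cand])
}

empty_detections <- function() {
  tibble::tibble(x_um = numeric(), y_um = numeric(), intensity = numeric())
}

# strict local maxima in a (2r+1)^2 neighbourhood, returned as index matrix
local_maxima <- function(img, r = 2) {
  r <- max(1, r)
  nx <- nrow(img); ny <- ncol(img)
  is_max <- matrix(TRUE, nx, ny)
  for (dx in -r:r) for (dy in -r:r) {
    if (dx == 0 && dy == 0) next
    sx <- seq(max(1, 1 + dx), min(nx, nx + dx))
    sy <- seq(max(1, 1 + dy), min(ny, ny + dy))
    tx <- sx - dx; ty <- sy - dy
    is_max[tx, ty] <- is_max[tx, ty] & (img[tx, ty] >= img[sx, sy])
  }
  which(is_max, arr.ind = TRUE)
}

# intensity-weighted centroid refinement in a square window (pixel indices)
refine_centroids <- function(image, idx, radius = 4) {
  out <- matrix(NA_real_, nrow(idx), 2)
  nx <- nrow(image); ny <- ncol(image)
  for (k in seq_len(nrow(idx))) {
    i0 <- max(1, idx[k, 1] - radius); i1 <- min(nx, idx[k, 1] + radius)
    j0 <- max(1, idx[k, 2] - radius); j1 <- min(ny, idx[k, 2] + radius)
    w <- image[i0:i1, j0:j1, drop = FALSE]
    w <- pmax(w - min(w), 0)  # local background subtraction
    tw <- sum(w)
    if (tw <= 0) {
      out[k, ] <- idx[k, ]
    } else {
      out[k, 1] <- sum(row(w) * w) / tw + i0 - 1
      out[k, 2] <- sum(col(w) * w) / tw + j0 - 1
    }
  }
  out
}

#' Segment blobs in a single-channel image by global threshold
#'
#' Otsu (or fixed) global threshold, connected-component labelling, removal
#' of components smaller than `min_area_px`, intensity-weighted centroids.
#' Merged objects are not split; a count mismatch against an expected count
#' is the caller's QC signal.
#'
#' @param image Numeric matrix (see [detect_nuclei()] for conventions).
#' @param pixel_size_um Pixel size, micrometres.
#' @param threshold_method `"otsu"` or a numeric threshold in image units.
#' @param min_area_px Minimum component area, pixels.
#' @return Tibble with `x_um`, `y_um`, `area_px`.
#' @export
segment_blobs <- function(image, pixel_size_um = 1, threshold_method = "otsu",
                          min_area_px = 4) {
  stopifnot(is.matrix(image))
  rng <- range(image)
  if (diff(rng) <= 0) return(tibble::tibble(x_um = numeric(),
                                            y_um = numeric(),
                                            area_px = numeric()))
  norm <- (image - rng[1]) / diff(rng)
  thr <- if (identical(threshold_method, "otsu")) {
    EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  } else {
    (as.numeric(threshold_method) - rng[1]) / diff(rng)
  }
  lab <- EBImage::bwlabel(norm > thr)
  nlab <- max(lab)
  if (nlab == 0) return(tibble::tibble(x_um = numeric(), y_um = numeric(),
                                       area_px = numeric()))
  px_idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  w <- norm[lab > 0]
  agg <- tibble::tibble(lab = as.integer(labs),
                        i = px_idx[, 1], j = px_idx[, 2], w = w) |>
    dplyr::group_by(.data$lab) |>
    dplyr::summarise(area_px = dplyr::n(),
                     x_px = sum(.data$i * .data$w) / sum(.data$w),
                     y_px = sum(.data$j * .data$w) / sum(.data$w),
                     .groups = "drop") |>
    dplyr::filter(.data$area_px >= min_area_px)
  tibble::tibble(x_um = (agg$x_px - 0.5) * pixel_size_um,
                 y_um = (agg$y_px - 0.5) * pixel_size_um,
                 area_px = agg$area_px)
}
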