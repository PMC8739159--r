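#' Construct an oriented wound edge
#'
#' A wound edge is an oriented line: a reference point on the edge, the unit
#' edge direction `e`, and the unit inward normal `n` pointing *into* the
#' cell-free wound area. All polarity and perpendicularity angles are signed
#' against this frame via [signed_angle_deg()].
#'
#' @param point Length-2 numeric, a point on the edge (micrometres).
#' @param normal_deg Direction of the inward normal, degrees.
#' @return Object of class `wound_edge` with fields `point`, `e`, `n`.
#' @examples
#' wound_edge(c(100, 0), normal_deg = 0)  # vertical edge, wound at +x
#' @export
wound_edge <- function(point = c(0, 0), normal_deg = 0) {
  stopifnot(length(point) == 2, all(is.finite(point)), is.finite(normal_deg))
  n <- unit_vec(normal_deg)
  e <- unit_vec(normal_deg - 90)  # e rotated -90 from n so (e, n) right-handed
  structure(list(point = as.numeric(point), e = e, n = n,
                 normal_deg = wrap_angle_deg(normal_deg)),
            class = "wound_edge")
}

#' @export
print.wound_edge <- function(x, ...) {
  cat(sprintf("<wound_edge> point (%.2f, %.2f) um, inward normal %.2f deg\n",
              x$point[1], x$point[2], x$normal_deg))
  invisible(x)
}

#' Signed distance of points to a wound edge
#'
#' Positive on the wound (cell-free) side, negative on the monolayer side.
#'
#' @param x,y Point coordinates in micrometres.
#' @param edge A [wound_edge()].
#' @return Numeric vector of signed distances (micrometres).
#' @export
edge_signed_distance <- function(x, y, edge) {
  stopifnot(inherits(edge, "wound_edge"))
  (x - edge$point[1]) * edge$n[1] + (y - edge$point[2]) * edge$n[2]
}

#' Estimate the wound edge from nucleus positions
#'
#' Emulates drawing the leading edge on a scratch-wound image: positions are
#' binned along an approximate edge axis, the wound-most occupied coordinate
#' per bin defines frontier points, and a total-least-squares line is fitted
#' through them. The inward normal is oriented toward the side with lower
#' cell occupancy (the cell-free scratch).
#'
#' @param data Data frame of cell positions with columns `x_um`, `y_um`
#'   (a `nx_um`/`ny_um` pair is also accepted).
#' @param bin_width_um Lateral bin width for frontier extraction.
#' @param approx_normal_deg Rough direction of the wound relative to the
#'   monolayer (degrees); only its half-plane matters, the fitted edge refines
#'   the direction. Default 0 (wound toward +x).
#' @param field_um Optional known field extent `c(width, height)`. When
#'   given, a frontier hugging the field border (cells everywhere, no
#'   scratch in view) is reported as an explicit failure.
#' @return A [wound_edge()].
#' @export
estimate_wound_edge <- function(data, bin_width_um = 20,
                                approx_normal_deg = 0, field_um = NULL) {
  if (all(c("nx_um", "ny_um") %in% names(data)) && !("x_um" %in% names(data))) {
    data <- dplyr::rename(data, x_um = "nx_um", y_um = "ny_um")
  }
  stopifnot(all(c("x_um", "y_um") %in% names(data)), bin_width_um > 0)
  n0 <- unit_vec(approx_normal_deg)
  e0 <- unit_vec(approx_normal_deg - 90)
  # rotate into the approximate frame: u along edge, w toward wound
  u <- data$x_um * e0[1] + data$y_um * e0[2]
  w <- data$x_um * n0[1] + data$y_um * n0[2]
  bins <- floor(u / bin_width_um)
  front <- tibble::tibble(u = u, w = w, bin = bins) |>
    dplyr::group_by(.data$bin) |>
    dplyr::slice_max(.data$w, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  if (nrow(front) < 10) {
    abort("estimate_wound_edge(): fewer than 10 frontier points; cannot fit an edge.")
  }
  # span check: frontier must not be degenerate (cells everywhere -> all bins
  # reach the field border and the fit is meaningless only if w has no spread
  # relative to the cloud; detect the 'cells everywhere' case by occupancy)
  pts <- cbind(front$u, front$w)
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  dir_uw <- sv$v[, 1]           # total least squares: principal direction
  nrm_uw <- c(-dir_uw[2], dir_uw[1])
  # orient normal toward lower occupancy (fewer cells on that side)
  side <- sign((u - ctr[1]) * nrm_uw[1] + (w - ctr[2]) * nrm_uw[2])
  if (sum(side > 0) > sum(side < 0)) nrm_uw <- -nrm_uw
  # cells everywhere -> no frontier: either many cells sit beyond the fitted
  # line, or (when the field extent is known) the frontier hugs the border
  d_line <- (u - ctr[1]) * nrm_uw[1] + (w - ctr[2]) * nrm_uw[2]
  if (mean(d_line > bin_width_um / 2) > 0.25) {
    abort("estimate_wound_edge(): frontier undefined - cells occupy both sides of every candidate edge.")
  }
  if (!is.null(field_um)) {
    corners <- rbind(c(0, 0), c(field_um[1], 0), c(0, field_um[2]), field_um)
    w_max <- max(corners %*% n0)
    if (mean(front$w) > w_max - bin_width_um) {
      abort("estimate_wound_edge(): frontier undefined - cells reach the field border everywhere (no scratch in view).")
    }
  }
  # map back to xy frame
  to_xy <- function(v) v[1] * e0 + v[2] * n0
  point_xy <- to_xy(ctr)
  normal_xy <- to_xy(nrm_uw)
  wound_edge(point_xy, normal_deg = rad2deg(atan2(normal_xy[2], normal_xy[1])))
}
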