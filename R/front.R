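#' Local tangent and inward normal of a front polyline
#'
#' The tangent at a vertex is the principal (total-least-squares) direction
#' of the vertices within `half_window` positions of it; the inward normal
#' is the perpendicular oriented toward `inward_point` (a point on the
#' avascular side of the front).
#'
#' @param front Data frame of ordered vertices with columns `x_um`, `y_um`.
#' @param vertex_index Vertex at which to evaluate (1-based).
#' @param half_window Window half-width in vertices (>= 1).
#' @param inward_point Length-2 point on the avascular side.
#' @return List with unit vectors `tangent` and `normal`.
#' @export
front_tangent <- function(front, vertex_index, half_window = 5,
                          inward_point) {
  stopifnot(nrow(front) >= 2, half_window >= 1)
  if (vertex_index < 1 || vertex_index > nrow(front)) {
    abort("vertex_index out of range.")
  }
  # keep the window symmetric about the vertex (shrinking near the ends
  # avoids a one-sided curvature bias in the fitted tangent)
  hw <- min(half_window, vertex_index - 1, nrow(front) - vertex_index)
  hw <- max(hw, 1)
  lo <- max(1, vertex_index - hw)
  hi <- min(nrow(front), vertex_index + hw)
  pts <- cbind(front$x_um[lo:hi], front$y_um[lo:hi])
  ctr <- colMeans(pts)
  centred <- sweep(pts, 2, ctr)
  if (all(abs(centred) < 1e-12)) {
    abort("front_tangent(): window collapses to a point.")
  }
  tangent <- svd(centred)$v[, 1]
  normal <- c(-tangent[2], tangent[1])
  v <- front[vertex_index, ]
  if (sum((inward_point - c(v$x_um, v$y_um)) * normal) < 0) normal <- -normal
  # orient the tangent so (tangent, normal) is right-handed, like (e, n)
  if (tangent[1] * normal[2] - tangent[2] * normal[1] < 0) tangent <- -tangent
  list(tangent = tangent, normal = normal)
}

#' Orientation of tip cells relative to the vascular front
#'
#' Each tip's direction vector is scored by its signed angle to the local
#' front frame at the nearest polyline vertex; a tip is oriented when the
#' angle lies in the closed window (default 60-120 degrees, i.e. pointing
#' into the avascular area perpendicular to the front).
#'
#' @param tips Data frame with `x_um`, `y_um`, `dir_x`, `dir_y`.
#' @param front Front polyline (`x_um`, `y_um`).
#' @param inward_point Length-2 point on the avascular side.
#' @param window_deg Closed angular window.
#' @param half_window Tangent window half-width (vertices).
#' @return Tips tibble with `theta_deg` and `oriented` added; zero direction
#'   vectors are dropped with a warning.
#' @export
tip_orientation <- function(tips, front, inward_point,
                            window_deg = c(60, 120), half_window = 5) {
  zero <- tips$dir_x == 0 & tips$dir_y == 0
  if (any(zero)) {
    warn(sprintf("%d tip(s) with zero direction vector excluded.", sum(zero)))
    tips <- tips[!zero, , drop = FALSE]
  }
  if (nrow(tips) == 0) {
    return(dplyr::mutate(tips, theta_deg = numeric(0), oriented = logical(0)))
  }
  theta <- vapply(seq_len(nrow(tips)), function(k) {
    d2 <- (front$x_um - tips$x_um[k])^2 + (front$y_um - tips$y_um[k])^2
    frame <- front_tangent(front, which.min(d2), half_window, inward_point)
    signed_angle_deg(tips$dir_x[k], tips$dir_y[k], frame$tangent,
                     frame$normal)
  }, numeric(1))
  dplyr::mutate(tips, theta_deg = theta,
                oriented = in_window(theta, window_deg))
}

#' Fraction of front-oriented tip cells
#'
#' @param scene A `front_scene` from [generate_front_scene()], or a tips
#'   tibble already carrying an `oriented` column.
#' @param window_deg Closed angular window.
#' @param half_window Tangent window half-width (vertices).
#' @return A `fraction_result` (see [perpendicular_fraction()]).
#' @export
oriented_tip_fraction <- function(scene, window_deg = c(60, 120),
                                  half_window = 5) {
  tips <- if (inherits(scene, "front_scene")) {
    tip_orientation(scene$tips, scene$front, scene$inward_point, window_deg,
                    half_window)
  } else scene
  if (!("oriented" %in% names(tips))) {
    abort("supply a front_scene or tips scored by tip_orientation().")
  }
  if (nrow(tips) == 0) warn("oriented_tip_fraction(): no valid tips.")
  flags <- tibble::tibble(tip_id = tips$tip_id %||% seq_len(nrow(tips)),
                          alpha_deg = tips$theta_deg,
                          perpendicular = tips$oriented)
  new_fraction_result(sum(tips$oriented), nrow(tips), window_deg, flags,
                      what = "oriented tips")
}

#' Count and measure filopodia on a tip-cell mask
#'
#' The mask is skeletonized (Zhang-Suen thinning); candidate filopodia are
#' skeleton branches that terminate in an endpoint and whose mean local
#' width - twice the Euclidean distance-transform value along the branch -
#' is below `diameter_max_um`. The reported length is the straight
#' base-to-tip chord (base = the branch pixel adjoining the cell body or a
#' skeleton junction), in micrometres.
#'
#' @param tip_mask Logical or 0/1 matrix of one tip cell.
#' @param pixel_size_um Pixel size; must resolve `diameter_max_um`
#'   (`pixel_size_um <= diameter_max_um`), otherwise an error.
#' @param diameter_max_um Maximum filopodium diameter (default 0.1 um).
#' @return List with `count`, `lengths_um`, and `branches` (tibble with
#'   per-branch `mean_width_um`, `length_um`, `n_px`, `accepted`).
#' @export
count_filopodia <- function(tip_mask, pixel_size_um,
                            diameter_max_um = 0.1) {
  stopifnot(is.matrix(tip_mask), pixel_size_um > 0)
  if (pixel_size_um > diameter_max_um) {
    abort(sprintf(
      "pixel size %.3g um cannot resolve the %.3g um diameter cut-off.",
      pixel_size_um, diameter_max_um))
  }
  mask <- tip_mask != 0
  empty <- list(count = 0L, lengths_um = numeric(0),
                branches = tibble::tibble(mean_width_um = numeric(),
                                          length_um = numeric(),
                                          n_px = integer(),
                                          accepted = logical()))
  if (!any(mask)) return(empty)
  skel <- skeletonize(mask)
  dt <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1)))
  width_um <- 2 * dt * pixel_size_um
  ncnt <- skeleton_neighbour_count(skel)
  endpoints <- which(skel & ncnt == 1, arr.ind = TRUE)
  if (nrow(endpoints) == 0) return(empty)
  branches <- purrr::map_dfr(seq_len(nrow(endpoints)), function(k) {
    path <- walk_branch(skel, width_um, as.integer(endpoints[k, ]),
                        width_stop = diameter_max_um)
    w <- mean(width_um[path])
    base <- path[nrow(path), ]
    tip <- path[1, ]
    tibble::tibble(
      mean_width_um = w,
      length_um = sqrt(sum((tip - base)^2)) * pixel_size_um,
      n_px = nrow(path),
      accepted = w < diameter_max_um & nrow(path) >= 2)
  })
  ok <- branches$accepted
  list(count = sum(ok), lengths_um = branches$length_um[ok],
       branches = branches)
}

#' Sprout count and lengths from a spheroid mask
#'
#' The spheroid body radius is estimated from the radial occupancy profile
#' about the mask centroid (the outermost radius at which at least
#' `body_quantile` of the annulus is occupied); sprouts are the connected
#' angular components of mask pixels beyond the body radius, each measured
#' as maximum radial extent minus body radius.
#'
#' @param spheroid_mask Logical or 0/1 matrix containing one spheroid.
#' @param pixel_size_um Pixel size, micrometres.
#' @param body_quantile Occupancy level defining the body edge (default
#'   0.95).
#' @param reference_mean_um Optional reference-condition mean sprout length;
#'   when given, `relative_length = mean(lengths) / reference_mean_um`.
#' @param min_sprout_length_um Minimum radial extent beyond the body for a
#'   component to count as a sprout; default 3 pixels, which discards the
#'   sub-pixel rim left by rasterising the body edge.
#' @return A `sprout_result`: list with `n_sprouts`, `sprout_lengths_um`,
#'   `body_radius_um`, `relative_length`.
#' @export
sprout_metrics <- function(spheroid_mask, pixel_size_um = 1,
                           body_quantile = 0.95, reference_mean_um = NULL,
                           min_sprout_length_um = 3 * pixel_size_um) {
  stopifnot(is.matrix(spheroid_mask), pixel_size_um > 0,
            body_quantile > 0, body_quantile <= 1)
  mask <- spheroid_mask != 0
  if (!any(mask)) {
    return(new_sprout_result(0L, numeric(0), NA_real_, reference_mean_um))
  }
  idx <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  r <- sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2)
  ang <- atan2(idx[, 2] - ctr[2], idx[, 1] - ctr[1])
  # annulus occupancy: occupied pixels per 1-px annulus / annulus pixel count
  rmax <- max(r)
  shell <- floor(r)
  occ_cnt <- tabulate(shell + 1L, nbins = floor(rmax) + 1L)
  # exact per-annulus pixel counts from the full grid as the denominator
  gi <- expand.grid(i = seq_len(nrow(mask)), j = seq_len(ncol(mask)))
  rg <- sqrt((gi$i - ctr[1])^2 + (gi$j - ctr[2])^2)
  ann_cnt <- tabulate(floor(rg) + 1L, nbins = floor(rmax) + 1L)
  occ <- occ_cnt / pmax(ann_cnt, 1)
  full <- which(occ >= body_quantile)
  body_r <- if (length(full) == 0) 0 else max(full)  # outer edge of body, px
  # pixels closer than the minimum sprout length are rasterisation rim, not
  # sprout material; including them would bridge unrelated angular components
  rim_px <- min_sprout_length_um / pixel_size_um
  beyond <- r > body_r + rim_px
  if (!any(beyond)) {
    return(new_sprout_result(0L, numeric(0), body_r * pixel_size_um,
                             reference_mean_um))
  }
  # connected angular components (1-degree bins, wrap-around)
  bins <- floor(((rad2deg(ang[beyond]) %% 360)))
  present <- sort(unique(bins))
  occupied <- rep(FALSE, 360)
  occupied[present + 1] <- TRUE
  comp <- integer(360)
  cid <- 0L
  for (b in seq_len(360)) {
    if (!occupied[b]) next
    if (b > 1 && occupied[b - 1]) comp[b] <- comp[b - 1]
    else { cid <- cid + 1L; comp[b] <- cid }
  }
  # wrap-around merge
  if (occupied[1] && occupied[360] && comp[1] != comp[360]) {
    comp[comp == comp[360]] <- comp[1]
  }
  comp_of_pixel <- comp[bins + 1]
  lengths_um <- (as.numeric(tapply(r[beyond], comp_of_pixel, max)) - body_r) *
    pixel_size_um
  lengths_um <- lengths_um[lengths_um >= min_sprout_length_um]
  new_sprout_result(length(lengths_um), lengths_um,
                    body_r * pixel_size_um, reference_mean_um)
}

new_sprout_result <- function(n, lengths_um, body_radius_um,
                              reference_mean_um) {
  rel <- if (!is.null(reference_mean_um) && length(lengths_um) > 0) {
    mean(lengths_um) / reference_mean_um
  } else NA_real_
  structure(list(n_sprouts = as.integer(n), sprout_lengths_um = lengths_um,
                 body_radius_um = body_radius_um, relative_length = rel),
            class = "sprout_result")
}

#' @export
print.sprout_result <- function(x, ...) {
  cat(sprintf("<sprout_result> %d sprouts, mean length %s um\n",
              x$n_sprouts,
              ifelse(x$n_sprouts > 0,
                     sprintf("%.1f", mean(x$sprout_lengths_um)), "-")))
  invisible(x)
}

#' Vessel density within a region
#'
#' @param mask A `vessel_mask` (from [generate_retina_mask()]) or a list
#'   with logical matrices `vessel` and `retina`.
#' @param region Optional logical matrix restricting the denominator; must
#'   be a subset of the retina region. Default: the whole retina region.
#' @return Vessel pixel fraction of the region, or `NA` (with a warning)
#'   for an empty region.
#' @export
vessel_density <- function(mask, region = NULL) {
  region <- region %||% mask$retina
  if (any(region & !mask$retina)) {
    abort("region must lie inside the retina mask.")
  }
  n <- sum(region)
  if (n == 0) {
    warn("vessel_density(): empty region, density undefined.")
    return(NA_real_)
  }
  sum(mask$vessel & region) / n
}

#' Vaso-obliterated (avascular) area fraction of a retina
#'
#' The vessel raster is morphologically closed (dilated then eroded with a
#' disc of radius `closing_radius_um`) so that normal inter-capillary gaps
#' are bridged without shrinking a genuine lesion; avascular pixels are the
#' retina pixels left uncovered, connected avascular regions smaller than
#' `min_region_area_um2` are discarded, and the fraction is kept avascular
#' area over total retina area.
#'
#' @param mask A `vessel_mask` or a list with `vessel`, `retina`,
#'   `pixel_size_um`.
#' @param closing_radius_um Gap-closing radius for the vessel raster (>= 0);
#'   gaps narrower than twice this radius are bridged.
#' @param min_region_area_um2 Minimum avascular region area kept.
#' @param central_mask Optional logical matrix restricting avascular regions
#'   to a central zone.
#' @return List with `vo_fraction`, `avascular_area_um2`,
#'   `retina_area_um2`, and `labels` (integer matrix of kept regions).
#' @export
avascular_fraction <- function(mask, closing_radius_um = 0,
                               min_region_area_um2 = 0,
                               central_mask = NULL) {
  if (closing_radius_um < 0) abort("closing_radius_um must be >= 0.")
  px <- mask$pixel_size_um
  vessel <- mask$vessel
  if (closing_radius_um > 0) {
    rad_px <- max(1, round(closing_radius_um / px))
    brush <- EBImage::makeBrush(2 * rad_px + 1, shape = "disc")
    vessel <- as.matrix(EBImage::closing(EBImage::Image(vessel * 1),
                                         brush)) > 0
  }
  avas <- mask$retina & !vessel
  if (!is.null(central_mask)) avas <- avas & central_mask
  lab <- as.matrix(EBImage::bwlabel(avas))
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0]) * px^2
    drop <- which(areas < min_region_area_um2)
    lab[lab %in% drop] <- 0L
  }
  kept <- sum(lab > 0)
  list(vo_fraction = kept / sum(mask$retina),
       avascular_area_um2 = kept * px^2,
       retina_area_um2 = sum(mask$retina) * px^2,
       labels = lab)
}
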