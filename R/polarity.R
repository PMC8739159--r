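#' Pair Golgi centroids to nucleus centroids
#'
#' Mutual-nearest-neighbour pairing under a distance gate: a nucleus and a
#' Golgi are paired only when each is the other's nearest neighbour and
#' their distance is within `max_pair_dist_um`. A Golgi equidistant (within
#' 1e-6 um) to two nuclei is paired to the lower-index nucleus and flagged
#' ambiguous. Unpaired nuclei produce no record; unpaired Golgi are returned
#' in the `unpaired_golgi` attribute for QC.
#'
#' @param nuclei,golgi Data frames with `x_um`, `y_um` in the same frame.
#' @param max_pair_dist_um Pairing gate (> 0).
#' @return Tibble of polarity records: `cell_id` (nucleus row index),
#'   `nx_um`, `ny_um`, `gx_um`, `gy_um`, `vx_um`, `vy_um`,
#'   `ambiguous_pairing`.
#' @export
pair_golgi_to_nuclei <- function(nuclei, golgi, max_pair_dist_um = 10) {
  if (!is.finite(max_pair_dist_um) || max_pair_dist_um <= 0) {
    abort("max_pair_dist_um must be positive.")
  }
  empty <- tibble::tibble(cell_id = integer(), nx_um = numeric(),
                          ny_um = numeric(), gx_um = numeric(),
                          gy_um = numeric(), vx_um = numeric(),
                          vy_um = numeric(), ambiguous_pairing = logical())
  if (nrow(nuclei) == 0 || nrow(golgi) == 0) {
    attr(empty, "unpaired_golgi") <- seq_len(nrow(golgi))
    return(empty)
  }
  d <- sqrt(outer(nuclei$x_um, golgi$x_um, "-")^2 +
            outer(nuclei$y_um, golgi$y_um, "-")^2)
  tol <- 1e-6
  # nearest golgi for each nucleus and vice versa; ties resolved to the
  # lower index (which.min already picks the first minimum)
  nn_of_nuc <- apply(d, 1, which.min)
  nn_of_gol <- apply(d, 2, which.min)
  amb_gol <- apply(d, 2, function(col) sum(col <= min(col) + tol) > 1)
  i <- seq_len(nrow(nuclei))
  g <- nn_of_nuc
  mutual <- nn_of_gol[g] == i & d[cbind(i, g)] <= max_pair_dist_um
  i <- i[mutual]; g <- g[mutual]
  rec <- tibble::tibble(
    cell_id = i,
    nx_um = nuclei$x_um[i], ny_um = nuclei$y_um[i],
    gx_um = golgi$x_um[g], gy_um = golgi$y_um[g],
    vx_um = golgi$x_um[g] - nuclei$x_um[i],
    vy_um = golgi$y_um[g] - nuclei$y_um[i],
    ambiguous_pairing = amb_gol[g])
  attr(rec, "unpaired_golgi") <- setdiff(seq_len(nrow(golgi)), g)
  rec
}

#' Signed polarization angle of nucleus-to-Golgi vectors
#'
#' Adds `alpha_deg` (the signed angle of the Golgi offset relative to the
#' wound frame; +90 = pointing straight into the wound) and
#' `distance_to_edge_um` (positive distance from the edge on the monolayer
#' side) to each record. Records with a zero polarity vector are dropped
#' with a warning.
#'
#' @param records Output of [pair_golgi_to_nuclei()] (columns `vx_um`,
#'   `vy_um`, `nx_um`, `ny_um`).
#' @param edge A [wound_edge()].
#' @return Records tibble with `alpha_deg` and `distance_to_edge_um` added.
#' @export
polarization_angle <- function(records, edge) {
  stopifnot(inherits(edge, "wound_edge"))
  zero <- records$vx_um == 0 & records$vy_um == 0
  if (any(zero)) {
    warn(sprintf("%d record(s) with zero polarity vector excluded.",
                 sum(zero)))
    records <- records[!zero, , drop = FALSE]
  }
  dplyr::mutate(records,
    alpha_deg = signed_angle_deg(.data$vx_um, .data$vy_um, edge$e, edge$n),
    distance_to_edge_um = -edge_signed_distance(.data$nx_um, .data$ny_um,
                                                edge))
}

#' Assign cell-layer indices from the wound edge
#'
#' Operationalises "the first 2-3 cell layers": layer index is
#' `ceiling(distance_to_edge / layer_width_um)` (minimum 1) for cells on the
#' monolayer side; cells beyond `n_layers` or on the wound side are flagged
#' excluded (`included = FALSE`) and do not enter the polarity denominator.
#'
#' @param records Output of [polarization_angle()].
#' @param edge A [wound_edge()] (used for cells lacking
#'   `distance_to_edge_um`).
#' @param layer_width_um Width of one cell layer, micrometres (default 20,
#'   one typical endothelial cell diameter).
#' @param n_layers Number of layers kept (2 or 3 typically).
#' @return Records tibble with `layer_index` (NA when on the wound side) and
#'   `included`.
#' @export
assign_layers <- function(records, edge, layer_width_um = 20, n_layers = 3) {
  stopifnot(layer_width_um > 0, n_layers >= 1)
  if (!("distance_to_edge_um" %in% names(records))) {
    records <- dplyr::mutate(records,
      distance_to_edge_um = -edge_signed_distance(.data$nx_um, .data$ny_um,
                                                  edge))
  }
  dplyr::mutate(records,
    layer_index = dplyr::if_else(
      .data$distance_to_edge_um >= 0,
      pmax(1, ceiling(.data$distance_to_edge_um / layer_width_um)),
      NA_real_),
    included = !is.na(.data$layer_index) & .data$layer_index <= n_layers)
}

#' Fraction of polarized (wound-oriented) cells
#'
#' A cell is oriented when its polarization angle lies in the closed window
#' (default 60-120 degrees, the Golgi pointing into the wound). Only records
#' surviving the layer filter (`included`, when present) enter the
#' denominator.
#'
#' @param records Output of [polarization_angle()] or [assign_layers()].
#' @param window_deg Closed angular window.
#' @return A `polarity_result`: list with `n_cells_considered`,
#'   `n_oriented`, `oriented_fraction`, `window_deg`, `n_layers_used`,
#'   `records` (with an `oriented` column), `empty` flag.
#' @export
polarized_fraction <- function(records, window_deg = c(60, 120)) {
  stopifnot("alpha_deg" %in% names(records))
  used <- if ("included" %in% names(records)) {
    records[records$included, , drop = FALSE]
  } else records
  used <- dplyr::mutate(used, oriented = in_window(.data$alpha_deg,
                                                   window_deg))
  n <- nrow(used)
  if (n == 0) warn("polarized_fraction(): no records survive the layer filter.")
  structure(list(
    n_cells_considered = n,
    n_oriented = sum(used$oriented),
    oriented_fraction = if (n > 0) mean(used$oriented) else NA_real_,
    window_deg = window_deg,
    n_layers_used = if ("layer_index" %in% names(used) && n > 0) {
      max(used$layer_index)
    } else NA_real_,
    records = used, empty = n == 0),
    class = "polarity_result")
}

#' @export
print.polarity_result <- function(x, ...) {
  cat(sprintf(
    "<polarity_result> %d / %d cells oriented (%s) in window [%g, %g] deg\n",
    x$n_oriented, x$n_cells_considered,
    ifelse(x$empty, "undefined", sprintf("%.3f", x$oriented_fraction)),
    x$window_deg[1], x$window_deg[2]))
  invisible(x)
}

#' Full polarity analysis of a two-channel scene
#'
#' Convenience wrapper chaining [segment_blobs()] on both channels,
#' [pair_golgi_to_nuclei()], [polarization_angle()], [assign_layers()] and
#' [polarized_fraction()].
#'
#' @param image Two-channel array from [render_scene()] (or with the same
#'   attributes).
#' @param edge A [wound_edge()]; if `NULL` it is estimated from the nucleus
#'   centroids via [estimate_wound_edge()].
#' @param max_pair_dist_um,layer_width_um,n_layers,window_deg,min_area_px
#'   Passed to the respective stages.
#' @return A `polarity_result`.
#' @export
analyze_polarity_image <- function(image, edge = NULL, max_pair_dist_um = 10,
                                   layer_width_um = 20, n_layers = 3,
                                   window_deg = c(60, 120), min_area_px = 4) {
  px <- attr(image, "pixel_size_um") %||% 1
  nuclei <- segment_blobs(image[, , 1], px, min_area_px = min_area_px)
  golgi <- segment_blobs(image[, , 2], px, min_area_px = min_area_px)
  if (is.null(edge)) edge <- estimate_wound_edge(nuclei)
  pair_golgi_to_nuclei(nuclei, golgi, max_pair_dist_um) |>
    polarization_angle(edge) |>
    assign_layers(edge, layer_width_um, n_layers) |>
    polarized_fraction(window_deg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
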