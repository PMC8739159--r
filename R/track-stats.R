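#' Per-track displacement and persistence statistics
#'
#' For each track: total displacement (path length, the sum of consecutive
#' Euclidean distances), net displacement (start-to-end distance),
#' persistence (net / total, the standard directionality ratio: 1 for a
#' perfectly straight path), and the direction of the net displacement
#' vector. Persistence is undefined (NA, `valid = FALSE`) when the total
#' displacement is zero; such tracks are excluded from group means.
#'
#' @param tracks Data frame with columns `track_id`, `frame`, `x_um`, `y_um`.
#' @return Tibble, one row per track: `track_id`, `n_frames`,
#'   `total_um`, `net_um`, `persistence`, `net_direction_deg`, `valid`.
#' @examples
#' tr <- tibble::tibble(track_id = 1, frame = 1:3,
#'                      x_um = c(0, 3, 3), y_um = c(0, 0, 4))
#' track_statistics(tr)  # total 7, net 5, persistence 5/7
#' @export
track_statistics <- function(tracks) {
  stopifnot(all(c("track_id", "frame", "x_um", "y_um") %in% names(tracks)))
  stopifnot(all(is.finite(tracks$x_um)), all(is.finite(tracks$y_um)))
  tracks |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      n_frames = dplyr::n(),
      total_um = sum(sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2)),
      net_um = sqrt((dplyr::last(.data$x_um) - dplyr::first(.data$x_um))^2 +
                    (dplyr::last(.data$y_um) - dplyr::first(.data$y_um))^2),
      net_direction_deg = rad2deg(atan2(
        dplyr::last(.data$y_um) - dplyr::first(.data$y_um),
        dplyr::last(.data$x_um) - dplyr::first(.data$x_um))),
      .groups = "drop") |>
    dplyr::filter(.data$n_frames >= 2) |>
    dplyr::mutate(
      persistence = dplyr::if_else(.data$total_um > 0,
                                   .data$net_um / .data$total_um, NA_real_),
      valid = .data$total_um > 0,
      net_direction_deg = dplyr::if_else(.data$net_um > 0,
                                         .data$net_direction_deg, NA_real_)) |>
    dplyr::select("track_id", "n_frames", "total_um", "net_um",
                  "persistence", "net_direction_deg", "valid")
}

#' Rose-plot histogram of net migration directions
#'
#' @param stats Output of [track_statistics()] (or any data frame with a
#'   `net_direction_deg` column).
#' @param n_bins Number of angular bins; must be >= 4 and divide 360.
#' @return Object of class `angular_histogram`: tibble with `bin_start_deg`,
#'   `bin_end_deg`, `bin_mid_deg`, `count`; attributes `n_excluded`
#'   (zero-length nets) and `empty` (TRUE when no track contributed).
#' @export
rose_histogram <- function(stats, n_bins = 12) {
  stopifnot("net_direction_deg" %in% names(stats))
  if (n_bins < 4 || 360 %% n_bins != 0) {
    abort("n_bins must be >= 4 and divide 360 evenly.")
  }
  ang <- stats$net_direction_deg
  excluded <- sum(is.na(ang))
  ang <- ang[!is.na(ang)] %% 360
  width <- 360 / n_bins
  idx <- floor(ang / width) %% n_bins
  counts <- tabulate(idx + 1L, nbins = n_bins)
  h <- tibble::tibble(bin_start_deg = (seq_len(n_bins) - 1) * width,
                      bin_end_deg = seq_len(n_bins) * width,
                      bin_mid_deg = (seq_len(n_bins) - 0.5) * width,
                      count = counts)
  if (length(ang) == 0) {
    warn("rose_histogram(): no tracks with a defined net direction.")
  }
  structure(h, class = c("angular_histogram", class(h)),
            n_excluded = excluded, empty = length(ang) == 0)
}

#' Fraction of tracks migrating perpendicular to the wound edge
#'
#' Per track the net displacement vector is scored by its signed angle to
#' the wound frame ([signed_angle_deg()]); a track counts as perpendicular
#' when the angle falls in the closed window (default 60-120 degrees, i.e.
#' toward the wound). Tracks with zero net displacement are excluded from
#' the denominator.
#'
#' @param stats Output of [track_statistics()].
#' @param edge A [wound_edge()].
#' @param window_deg Closed angular window, default `c(60, 120)`.
#' @return List of class `fraction_result`: `fraction`, `n_flagged`,
#'   `n_valid`, `window_deg`, and `flags` (tibble with `track_id`,
#'   `alpha_deg`, `perpendicular`).
#' @export
perpendicular_fraction <- function(stats, edge, window_deg = c(60, 120)) {
  stopifnot(inherits(edge, "wound_edge"))
  ok <- !is.na(stats$net_direction_deg)
  # the input is already an angle, so subtract the edge direction in degrees
  # directly: exact at window boundaries, unlike a vector round trip
  alpha <- wrap_angle_deg(stats$net_direction_deg[ok] -
                            (edge$normal_deg - 90))
  flag <- in_window(alpha, window_deg)
  flags <- tibble::tibble(track_id = stats$track_id[ok], alpha_deg = alpha,
                          perpendicular = flag)
  new_fraction_result(sum(flag), sum(ok), window_deg, flags,
                      what = "perpendicular tracks")
}

new_fraction_result <- function(n_flagged, n_valid, window_deg, flags, what) {
  structure(list(fraction = if (n_valid > 0) n_flagged / n_valid else NA_real_,
                 n_flagged = n_flagged, n_valid = n_valid,
                 window_deg = window_deg, flags = flags, what = what,
                 empty = n_valid == 0),
            class = "fraction_result")
}

#' @export
print.fraction_result <- function(x, ...) {
  cat(sprintf("<fraction_result> %s: %d / %d = %s (window [%g, %g] deg)\n",
              x$what, x$n_flagged, x$n_valid,
              ifelse(x$empty, "undefined", sprintf("%.3f", x$fraction)),
              x$window_deg[1], x$window_deg[2]))
  invisible(x)
}

#' Keep tracks that start near the wound edge
#'
#' The leading-edge restriction used when tracking scratch-wound movies:
#' only tracks whose initial position lies within `band_um` of the edge (on
#' the monolayer side) are retained.
#'
#' @param tracks Track tibble (`track_id`, `frame`, `x_um`, `y_um`).
#' @param edge A [wound_edge()].
#' @param band_um Band width from the edge, default 30 (about two nucleus
#'   spacings).
#' @return Filtered track tibble.
#' @export
leading_edge_filter <- function(tracks, edge, band_um = 30) {
  stopifnot(inherits(edge, "wound_edge"), band_um > 0)
  first <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::slice_min(.data$frame, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(d = edge_signed_distance(.data$x_um, .data$y_um, edge))
  keep <- first$track_id[first$d <= 0 & first$d >= -band_um]
  dplyr::filter(tracks, .data$track_id %in% keep)
}
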