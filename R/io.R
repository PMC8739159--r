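#' Read and write track tables
#'
#' Tracks serialise as plain CSV with one row per detection:
#' `track_id, frame, x_um, y_um`.
#'
#' @param tracks Track tibble.
#' @param path File path.
#' @return `write_tracks_csv()` returns `path` invisibly;
#'   `read_tracks_csv()` returns the track tibble.
#' @export
write_tracks_csv <- function(tracks, path) {
  readr::write_csv(tracks[c("track_id", "frame", "x_um", "y_um")], path)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    track_id = readr::col_integer(), frame = readr::col_integer(),
    x_um = readr::col_double(), y_um = readr::col_double()))
}

#' Read and write polarity scene coordinate tables
#'
#' One row per cell: `cell_id, nx_um, ny_um, gx_um, gy_um`; the wound edge
#' ground truth is written alongside as `<path>.edge.csv`
#' (`point_x_um, point_y_um, normal_deg`).
#'
#' @param scene A `polarity_scene`.
#' @param path CSV path for the cell table.
#' @return `write_scene_csv()` returns `path` invisibly; `read_scene_csv()`
#'   returns a list with `cells` and `edge` (NULL when no sidecar exists).
#' @export
write_scene_csv <- function(scene, path) {
  readr::write_csv(scene$cells[c("cell_id", "nx_um", "ny_um", "gx_um",
                                 "gy_um")], path)
  readr::write_csv(tibble::tibble(point_x_um = scene$edge$point[1],
                                  point_y_um = scene$edge$point[2],
                                  normal_deg = scene$edge$normal_deg),
                   paste0(path, ".edge.csv"))
  invisible(path)
}

#' @rdname write_scene_csv
#' @export
read_scene_csv <- function(path) {
  cells <- readr::read_csv(path, show_col_types = FALSE)
  edge_path <- paste0(path, ".edge.csv")
  edge <- NULL
  if (file.exists(edge_path)) {
    e <- readr::read_csv(edge_path, show_col_types = FALSE)
    edge <- wound_edge(c(e$point_x_um[1], e$point_y_um[1]), e$normal_deg[1])
  }
  list(cells = cells, edge = edge)
}

#' Write a multi-channel or multi-frame image stack as multi-page TIFF
#'
#' Pages are written frame-major, channel-minor: for a time series of
#' two-channel images the page order is frame 1 channel 1, frame 1
#' channel 2, frame 2 channel 1, and so on. Intensities are rescaled to
#' `[0, 1]` (32-bit float pages).
#'
#' @param images A matrix, a 3-d array (`x, y, channel`), or a list of such.
#' @param path TIFF path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(images, path) {
  if (!is.list(images)) images <- list(images)
  pages <- list()
  for (img in images) {
    if (length(dim(img)) == 3) {
      for (ch in seq_len(dim(img)[3])) pages <- c(pages, list(img[, , ch]))
    } else {
      pages <- c(pages, list(img))
    }
  }
  pages <- lapply(pages, function(m) {
    rng <- range(m)
    m <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
    t(m)[rev(seq_len(ncol(m))), , drop = FALSE]  # x right, y up -> row-major
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  invisible(path)
}

#' @rdname write_image_tiff
#' @param n_channels Channels per frame used to regroup pages on read.
#' @export
read_image_tiff <- function(path, n_channels = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  mats <- lapply(pages, function(p) {
    t(p[rev(seq_len(nrow(p))), , drop = FALSE])
  })
  if (n_channels == 1) return(mats)
  stopifnot(length(mats) %% n_channels == 0)
  lapply(seq_len(length(mats) / n_channels), function(f) {
    array(unlist(mats[((f - 1) * n_channels + 1):(f * n_channels)]),
          dim = c(dim(mats[[1]]), n_channels))
  })
}
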