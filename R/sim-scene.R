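#' Configuration for synthetic monolayer polarity scenes
#'
#' Generates a confluent monolayer on one side of a scratch wound: nucleus
#' centroids with hard-core spacing, and a Golgi centroid for each nucleus
#' offset by `golgi_offset_um` at an angle drawn from a von Mises
#' distribution about the inward wound normal with concentration
#' `polarity_kappa` (0 = unpolarized null, uniform angles).
#'
#' @param n_cells Number of cells.
#' @param field_um Length-2 `c(width, height)` of the field, micrometres.
#' @param pixel_size_um Pixel size used when the scene is rendered.
#' @param edge A [wound_edge()]; cells are placed on the monolayer side
#'   (opposite the inward normal).
#' @param golgi_offset_um Mean nucleus-to-Golgi centroid distance.
#' @param golgi_offset_sd_um Standard deviation of the offset distance
#'   (truncated at 0).
#' @param polarity_kappa Von Mises concentration of the Golgi-offset angle
#'   about the inward normal (>= 0, may be `Inf`).
#' @param nucleus_spacing_min_um Hard-core minimum distance between nucleus
#'   centroids (> 0).
#' @param seed Integer seed.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(n_cells = 200, field_um = c(400, 400),
                         pixel_size_um = 1,
                         edge = wound_edge(c(field_um[1] * 0.75, 0),
                                           normal_deg = 0),
                         golgi_offset_um = 5, golgi_offset_sd_um = 0.5,
                         polarity_kappa = 2, nucleus_spacing_min_um = 15,
                         seed = 1L) {
  stopifnot(inherits(edge, "wound_edge"))
  if (is.na(polarity_kappa) || polarity_kappa < 0) {
    abort("polarity_kappa must be >= 0.")
  }
  if (!is.finite(nucleus_spacing_min_um) || nucleus_spacing_min_um <= 0) {
    abort("nucleus_spacing_min_um must be > 0.")
  }
  structure(list(n_cells = as.integer(n_cells),
                 field_um = as.numeric(field_um),
                 pixel_size_um = pixel_size_um, edge = edge,
                 golgi_offset_um = golgi_offset_um,
                 golgi_offset_sd_um = golgi_offset_sd_um,
                 polarity_kappa = polarity_kappa,
                 nucleus_spacing_min_um = nucleus_spacing_min_um,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Generate a monolayer polarity scene with known ground truth
#'
#' Nuclei are placed on a jittered grid on the monolayer side of the wound
#' edge, which guarantees the hard-core spacing; Golgi centroids are offset
#' from their nucleus at a von Mises angle about the inward normal. The true
#' offset angle of every cell is retained, so the analytically expected
#' oriented fraction is available downstream.
#'
#' @param cfg A [scene_config()].
#' @return Object of class `polarity_scene`: list with `cells` (tibble:
#'   `cell_id, nx_um, ny_um, gx_um, gy_um, true_alpha_deg`), `edge`, and
#'   `config`.
#' @export
generate_monolayer_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  set.seed(cfg$seed)
  s <- cfg$nucleus_spacing_min_um
  margin <- cfg$golgi_offset_um + 4 * cfg$golgi_offset_sd_um + 1
  # jittered grid: cell pitch g with jitter j per axis keeps min distance
  # g - 2j >= s; choose j = 0.2 g, g = s / 0.6
  g <- s / 0.6
  j <- 0.2 * g
  gx <- seq(margin + g / 2, cfg$field_um[1] - margin - g / 2, by = g)
  gy <- seq(margin + g / 2, cfg$field_um[2] - margin - g / 2, by = g)
  grid <- expand.grid(x = gx, y = gy)
  # keep monolayer side only, at least half a pitch from the edge
  keep <- edge_signed_distance(grid$x, grid$y, cfg$edge) <= -g / 2
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) < cfg$n_cells) {
    abort(sprintf(
      "field too small: %d cells requested but only %d placeable at spacing %.1f um.",
      cfg$n_cells, nrow(grid), s))
  }
  idx <- sample.int(nrow(grid), cfg$n_cells)
  nx <- grid$x[idx] + runif(cfg$n_cells, -j, j)
  ny <- grid$y[idx] + runif(cfg$n_cells, -j, j)
  alpha <- rvonmises_deg(cfg$n_cells, 90, cfg$polarity_kappa)
  # alpha is the signed angle in the (e, n) frame; map to absolute direction
  dir_abs <- deg2rad(alpha + cfg$edge$normal_deg - 90)
  off <- rtrunc_speed(cfg$n_cells, cfg$golgi_offset_um, cfg$golgi_offset_sd_um)
  cells <- tibble::tibble(
    cell_id = seq_len(cfg$n_cells),
    nx_um = nx, ny_um = ny,
    gx_um = nx + off * cos(dir_abs),
    gy_um = ny + off * sin(dir_abs),
    true_alpha_deg = alpha)
  structure(list(cells = cells, edge = cfg$edge, config = cfg),
            class = "polarity_scene")
}

#' @export
print.polarity_scene <- function(x, ...) {
  cat(sprintf("<polarity_scene> %d cells, field %.0f x %.0f um, kappa = %s\n",
              nrow(x$cells), x$config$field_um[1], x$config$field_um[2],
              format(x$config$polarity_kappa)))
  invisible(x)
}

# Render point emitters as isotropic Gaussian spots on a pixel grid.
# Image matrices are indexed [ix, iy] with pixel centre of m[i, j] at
# x = (i - 0.5) * px, y = (j - 0.5) * px.
render_spots <- function(x_um, y_um, dim_px, pixel_size_um, psf_sigma_px,
                         amplitude = 1) {
  img <- matrix(0, nrow = dim_px[1], ncol = dim_px[2])
  if (length(x_um) == 0) return(img)
  halo <- ceiling(4 * psf_sigma_px)
  for (k in seq_along(x_um)) {
    cx <- x_um[k] / pixel_size_um + 0.5  # pixel-index coordinates
    cy <- y_um[k] / pixel_size_um + 0.5
    i0 <- max(1, floor(cx - halo)); i1 <- min(dim_px[1], ceiling(cx + halo))
    j0 <- max(1, floor(cy - halo)); j1 <- min(dim_px[2], ceiling(cy + halo))
    if (i0 > i1 || j0 > j1) next
    ii <- i0:i1; jj <- j0:j1
    gx <- exp(-((ii - cx)^2) / (2 * psf_sigma_px^2))
    gy <- exp(-((jj - cy)^2) / (2 * psf_sigma_px^2))
    img[ii, jj] <- img[ii, jj] + amplitude * outer(gx, gy)
  }
  img
}

#' Render simulated tracks as a time-lapse movie
#'
#' One single-channel frame per time point, each nucleus a Gaussian spot --
#' the synthetic stand-in for a scratch-wound time-lapse acquisition.
#'
#' @param tracks Track tibble (`track_id`, `frame`, `x_um`, `y_um`).
#' @param field_um Length-2 field size, micrometres.
#' @param pixel_size_um Pixel size.
#' @param psf_sigma_px Gaussian spot sigma, pixels.
#' @param snr Peak signal-to-noise ratio; `Inf` for noise-free frames.
#' @param seed Seed for the noise draw.
#' @return List of matrices, one per frame, with attribute `pixel_size_um`.
#' @export
render_track_movie <- function(tracks, field_um, pixel_size_um = 1,
                               psf_sigma_px = 2, snr = Inf, seed = 1L) {
  stopifnot(psf_sigma_px > 0)
  dim_px <- ceiling(field_um / pixel_size_um)
  if (any(dim_px < 1)) abort("zero-size field cannot be rendered.")
  set.seed(seed)
  frames <- sort(unique(tracks$frame))
  out <- lapply(frames, function(f) {
    sub <- tracks[tracks$frame == f, ]
    img <- render_spots(sub$x_um, sub$y_um, dim_px, pixel_size_um,
                        psf_sigma_px)
    if (is.finite(snr)) {
      img <- img + matrix(rnorm(length(img), 0, 1 / snr), nrow(img))
    }
    img
  })
  names(out) <- frames
  attr(out, "pixel_size_um") <- pixel_size_um
  out
}

#' Render a polarity scene as a two-channel image
#'
#' Each centroid becomes an isotropic Gaussian spot. Channel order is fixed:
#' channel 1 = nucleus, channel 2 = Golgi. Additive Gaussian noise with
#' standard deviation `peak / snr` is applied per channel (`snr = Inf` for
#' noise-free renders).
#'
#' @param scene A `polarity_scene` from [generate_monolayer_scene()].
#' @param psf_sigma_px Gaussian spot sigma in pixels (> 0).
#' @param snr Peak signal-to-noise ratio; `Inf` disables noise.
#' @param seed Seed for the noise draw.
#' @return Numeric array `dim = c(nx, ny, 2)` with attributes
#'   `pixel_size_um` and `channels = c("nucleus", "golgi")`. Pixel centre of
#'   `[i, j]` is at `((i - 0.5) px, (j - 0.5) px)`.
#' @export
render_scene <- function(scene, psf_sigma_px = 2, snr = Inf, seed = 1L) {
  stopifnot(inherits(scene, "polarity_scene"), psf_sigma_px > 0)
  px <- scene$config$pixel_size_um
  dim_px <- ceiling(scene$config$field_um / px)
  if (any(dim_px < 1)) abort("zero-size field cannot be rendered.")
  nuc <- render_spots(scene$cells$nx_um, scene$cells$ny_um, dim_px, px,
                      psf_sigma_px)
  gol <- render_spots(scene$cells$gx_um, scene$cells$gy_um, dim_px, px,
                      psf_sigma_px * 0.75)
  img <- array(c(nuc, gol), dim = c(dim_px, 2))
  if (is.finite(snr)) {
    set.seed(seed)
    img <- img + array(rnorm(length(img), 0, 1 / snr), dim = dim(img))
  }
  attr(img, "pixel_size_um") <- px
  attr(img, "channels") <- c("nucleus", "golgi")
  img
}
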