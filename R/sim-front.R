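#' Configuration for synthetic vascular-front scenes
#'
#' Emulates the growing retinal vascular front: a sinusoidal front polyline,
#' tip cells positioned on the front with direction vectors drawn from a von
#' Mises distribution about the local inward normal (pointing into the
#' avascular area ahead of the front), and per-tip filopodia with Poisson
#' counts and truncated-normal lengths.
#'
#' @param front_length_um Lateral extent of the front polyline.
#' @param front_amplitude_um,front_wavelength_um Sinusoidal front geometry.
#' @param vertex_step_um Polyline vertex spacing.
#' @param n_tips Number of tip cells (>= 0).
#' @param tip_kappa Von Mises concentration of the tip direction about the
#'   local inward normal (>= 0, may be `Inf`).
#' @param filopodia_lambda Poisson mean filopodia per tip.
#' @param filopodia_len_um,filopodia_len_sd_um Filopodium length
#'   distribution (micrometres, truncated at 0).
#' @param seed Integer seed.
#' @return A list of class `front_sim_config`.
#' @export
front_sim_config <- function(front_length_um = 500, front_amplitude_um = 20,
                             front_wavelength_um = 150, vertex_step_um = 2,
                             n_tips = 50, tip_kappa = 2,
                             filopodia_lambda = 5, filopodia_len_um = 8,
                             filopodia_len_sd_um = 2, seed = 1L) {
  if (n_tips < 0) abort("n_tips must be >= 0.")
  if (is.na(tip_kappa) || tip_kappa < 0) abort("tip_kappa must be >= 0.")
  if (filopodia_lambda < 0) abort("filopodia_lambda must be >= 0.")
  if (front_length_um <= 0 || vertex_step_um <= 0) {
    abort("front polyline must have positive length.")
  }
  structure(list(front_length_um = front_length_um,
                 front_amplitude_um = front_amplitude_um,
                 front_wavelength_um = front_wavelength_um,
                 vertex_step_um = vertex_step_um, n_tips = as.integer(n_tips),
                 tip_kappa = tip_kappa, filopodia_lambda = filopodia_lambda,
                 filopodia_len_um = filopodia_len_um,
                 filopodia_len_sd_um = filopodia_len_sd_um,
                 seed = as.integer(seed)),
            class = "front_sim_config")
}

#' Generate a vascular-front scene with known ground truth
#'
#' The front runs laterally along +x with the avascular side at +y. Tip
#' directions are drawn so that the ground-truth signed angle to the local
#' front frame is von Mises with mean 90 degrees (straight into the
#' avascular area) and concentration `tip_kappa`.
#'
#' @param cfg A [front_sim_config()].
#' @return Object of class `front_scene`: list with `front` (tibble
#'   `x_um, y_um`, ordered vertices), `tips` (tibble `tip_id, x_um, y_um,
#'   dir_x, dir_y, true_theta_deg, filopodia_count`), `filopodia` (tibble
#'   `tip_id, length_um`), `inward_point` (a point on the avascular side),
#'   and `config`.
#' @export
generate_front_scene <- function(cfg) {
  stopifnot(inherits(cfg, "front_sim_config"))
  set.seed(cfg$seed)
  xs <- seq(0, cfg$front_length_um, by = cfg$vertex_step_um)
  ys <- cfg$front_amplitude_um * sin(2 * pi * xs / cfg$front_wavelength_um)
  front <- tibble::tibble(x_um = xs, y_um = ys)
  n <- cfg$n_tips
  if (n > 0) {
    vidx <- sort(sample(seq_along(xs), n, replace = TRUE))
    theta <- rvonmises_deg(n, 90, cfg$tip_kappa)
    # local analytic frame: tangent of the sine curve, inward normal = +y side
    slope <- (2 * pi * cfg$front_amplitude_um / cfg$front_wavelength_um) *
      cos(2 * pi * xs[vidx] / cfg$front_wavelength_um)
    tang <- cbind(1, slope) / sqrt(1 + slope^2)
    nrm <- cbind(-tang[, 2], tang[, 1])          # rotate +90: points to +y
    a <- deg2rad(theta)
    dir <- cbind(cos(a) * tang[, 1] + sin(a) * nrm[, 1],
                 cos(a) * tang[, 2] + sin(a) * nrm[, 2])
    counts <- rpois(n, cfg$filopodia_lambda)
    tips <- tibble::tibble(tip_id = seq_len(n), x_um = xs[vidx],
                           y_um = ys[vidx], dir_x = dir[, 1], dir_y = dir[, 2],
                           true_theta_deg = theta, filopodia_count = counts)
    filo <- tibble::tibble(
      tip_id = rep(tips$tip_id, counts),
      length_um = rtrunc_speed(sum(counts), cfg$filopodia_len_um,
                               cfg$filopodia_len_sd_um))
  } else {
    tips <- tibble::tibble(tip_id = integer(), x_um = numeric(),
                           y_um = numeric(), dir_x = numeric(),
                           dir_y = numeric(), true_theta_deg = numeric(),
                           filopodia_count = integer())
    filo <- tibble::tibble(tip_id = integer(), length_um = numeric())
  }
  structure(list(front = front, tips = tips, filopodia = filo,
                 # far on the +y (avascular) side: a distant reference keeps
                 # the normal orientation consistent even at the polyline
                 # ends, where a nearby point's lateral offset could flip it
                 inward_point = c(cfg$front_length_um / 2,
                                  cfg$front_amplitude_um + 1e6),
                 config = cfg),
            class = "front_scene")
}

#' @export
print.front_scene <- function(x, ...) {
  cat(sprintf("<front_scene> %d front vertices, %d tips, kappa = %s\n",
              nrow(x$front), nrow(x$tips), format(x$config$tip_kappa)))
  invisible(x)
}
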