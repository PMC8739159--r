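#' Configuration for the biased persistent random-walk track simulator
#'
#' Defaults emulate a scratch-wound time-lapse acquisition: one frame every
#' 10 minutes over a 6 h migration period (37 frames). The walk model is a
#' biased persistent random walk: at each step the heading is drawn from a
#' von Mises distribution centred on the circular weighted mean of the
#' previous heading (weight 1) and the inward wound normal (weight
#' `bias_weight`), with concentration `persistence_kappa`; the step length is
#' drawn from a normal distribution truncated at zero.
#'
#' @param n_cells Number of cells (tracks).
#' @param n_frames Frames per track (>= 2).
#' @param dt_min Frame interval, minutes.
#' @param speed_mean_um,speed_sd_um Step-length distribution per frame
#'   (micrometres; truncated normal, `speed_sd_um >= 0`).
#' @param persistence_kappa Von Mises concentration of turning noise
#'   (>= 0; `Inf` gives a deterministic heading).
#' @param bias_weight Weight (>= 0, may be `Inf`) of attraction toward the
#'   inward wound normal; 0 gives an unbiased persistent walk.
#' @param wound_normal_deg Direction of the inward wound normal, degrees.
#' @param start_box Length-4 numeric `c(xmin, xmax, ymin, ymax)` for uniform
#'   initial positions (micrometres).
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A list of class `track_sim_config`.
#' @export
track_sim_config <- function(n_cells = 60, n_frames = 37, dt_min = 10,
                             speed_mean_um = 10, speed_sd_um = 2,
                             persistence_kappa = 2, bias_weight = 0,
                             wound_normal_deg = 90,
                             start_box = c(0, 500, 0, 100), seed = 1L) {
  cfg <- list(n_cells = as.integer(n_cells), n_frames = as.integer(n_frames),
              dt_min = dt_min, speed_mean_um = speed_mean_um,
              speed_sd_um = speed_sd_um,
              persistence_kappa = persistence_kappa,
              bias_weight = bias_weight,
              wound_normal_deg = wound_normal_deg,
              start_box = as.numeric(start_box), seed = as.integer(seed))
  validate_track_sim_config(cfg)
  structure(cfg, class = "track_sim_config")
}

validate_track_sim_config <- function(cfg) {
  if (cfg$n_frames < 2) abort("n_frames must be >= 2.")
  if (cfg$n_cells < 1) abort("n_cells must be >= 1.")
  if (!is.finite(cfg$speed_sd_um) || cfg$speed_sd_um < 0) {
    abort("speed_sd_um must be finite and >= 0.")
  }
  if (!is.finite(cfg$speed_mean_um) || cfg$speed_mean_um < 0) {
    abort("speed_mean_um must be finite and >= 0.")
  }
  if (is.na(cfg$persistence_kappa) || cfg$persistence_kappa < 0) {
    abort("persistence_kappa must be >= 0.")
  }
  if (is.na(cfg$bias_weight) || cfg$bias_weight < 0) {
    abort("bias_weight must be >= 0.")
  }
  invisible(cfg)
}

rtrunc_speed <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < 0)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < 0]
  }
  out
}

#' Simulate nucleus-centroid tracks from a biased persistent random walk
#'
#' @param cfg A [track_sim_config()].
#' @return Tibble with columns `track_id`, `frame` (1-based), `t_min`,
#'   `x_um`, `y_um`; the config is attached as attribute `config`.
#' @examples
#' tr <- simulate_tracks(track_sim_config(n_cells = 5, seed = 7))
#' dplyr::count(tr, track_id)
#' @export
simulate_tracks <- function(cfg) {
  stopifnot(inherits(cfg, "track_sim_config"))
  validate_track_sim_config(cfg)
  set.seed(cfg$seed)
  normal_deg <- cfg$wound_normal_deg
  bw <- cfg$bias_weight
  res <- purrr::map_dfr(seq_len(cfg$n_cells), function(id) {
    x <- numeric(cfg$n_frames); y <- numeric(cfg$n_frames)
    x[1] <- runif(1, cfg$start_box[1], cfg$start_box[2])
    y[1] <- runif(1, cfg$start_box[3], cfg$start_box[4])
    heading <- if (is.infinite(bw)) normal_deg else runif(1, -180, 180)
    for (k in 2:cfg$n_frames) {
      mu <- heading_mean_deg(heading, normal_deg, bw)
      heading <- rvonmises_deg(1, mu, cfg$persistence_kappa)
      step <- rtrunc_speed(1, cfg$speed_mean_um, cfg$speed_sd_um)
      x[k] <- x[k - 1] + step * cos(deg2rad(heading))
      y[k] <- y[k - 1] + step * sin(deg2rad(heading))
    }
    tibble::tibble(track_id = id, frame = seq_len(cfg$n_frames),
                   t_min = (seq_len(cfg$n_frames) - 1) * cfg$dt_min,
                   x_um = x, y_um = y)
  })
  attr(res, "config") <- cfg
  res
}

# circular weighted mean of (prev heading, weight 1) and (normal, weight w)
heading_mean_deg <- function(heading_deg, normal_deg, w) {
  if (is.infinite(w)) return(wrap_angle_deg(normal_deg))
  vx <- cos(deg2rad(heading_deg)) + w * cos(deg2rad(normal_deg))
  vy <- sin(deg2rad(heading_deg)) + w * sin(deg2rad(normal_deg))
  if (vx == 0 && vy == 0) return(wrap_angle_deg(heading_deg))
  rad2deg(atan2(vy, vx))
}
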