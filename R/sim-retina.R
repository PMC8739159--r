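#' Configuration for synthetic retinal vessel masks
#'
#' Emulates an isolectin-B4 flat-mount mask: a circular retina region filled
#' with a capillary-mesh vessel texture (a jittered rectangular grid of
#' vessel strands, so inter-vessel gaps are small enclosed pockets) and a
#' central avascular (vaso-obliterated) region whose analytic area fraction
#' of the retina equals `vo_fraction_target`.
#'
#' @param retina_radius_px Retina disc radius, pixels.
#' @param pixel_size_um Pixel size, micrometres.
#' @param vessel_spacing_px,vessel_thickness_px Capillary grid geometry;
#'   analytic vessel fill of the texture is
#'   `1 - (1 - thickness/spacing)^2`.
#' @param vo_fraction_target Target avascular area / retina area in `[0, 1]`.
#' @param vo_shape `"disc"` (central disc) or `"sector"` (annulus sector
#'   spanning `sector_deg` between half and full retina radius).
#' @param sector_deg Angular span for `vo_shape = "sector"`.
#' @param jitter_px Grid line jitter amplitude, pixels.
#' @param seed Integer seed.
#' @return A list of class `retina_mask_config`.
#' @export
retina_mask_config <- function(retina_radius_px = 200, pixel_size_um = 2,
                               vessel_spacing_px = 14,
                               vessel_thickness_px = 4,
                               vo_fraction_target = 0.1,
                               vo_shape = c("disc", "sector"),
                               sector_deg = 90, jitter_px = 2, seed = 1L) {
  vo_shape <- match.arg(vo_shape)
  if (is.na(vo_fraction_target) || vo_fraction_target < 0 ||
      vo_fraction_target > 1) {
    abort("vo_fraction_target must lie in [0, 1].")
  }
  max_frac <- if (vo_shape == "disc") 1 else (sector_deg / 360) * (1 - 0.25)
  if (vo_fraction_target > max_frac + 1e-12) {
    abort(sprintf(
      "vo_fraction_target %.3f exceeds the %.3f achievable by shape '%s'.",
      vo_fraction_target, max_frac, vo_shape))
  }
  structure(list(retina_radius_px = as.integer(retina_radius_px),
                 pixel_size_um = pixel_size_um,
                 vessel_spacing_px = vessel_spacing_px,
                 vessel_thickness_px = vessel_thickness_px,
                 vo_fraction_target = vo_fraction_target,
                 vo_shape = vo_shape, sector_deg = sector_deg,
                 jitter_px = jitter_px, seed = as.integer(seed)),
            class = "retina_mask_config")
}

#' Generate a binary retinal vessel mask with a known avascular fraction
#'
#' @param cfg A [retina_mask_config()].
#' @return Object of class `vessel_mask`: list with logical matrices
#'   `vessel`, `retina` and `avascular` (ground truth; `vessel` a subset of
#'   `retina`), `pixel_size_um`, `vo_fraction_true` (rasterised
#'   avascular/retina area), `vessel_fill_analytic` (grid-texture fill
#'   fraction away from the avascular border), and `config`.
#' @export
generate_retina_mask <- function(cfg) {
  stopifnot(inherits(cfg, "retina_mask_config"))
  set.seed(cfg$seed)
  R <- cfg$retina_radius_px
  side <- 2 * R + 1
  ctr <- R + 1
  ix <- matrix(seq_len(side), side, side)
  iy <- matrix(seq_len(side), side, side, byrow = TRUE)
  r2 <- (ix - ctr)^2 + (iy - ctr)^2
  retina <- r2 <= R^2
  # avascular region
  if (cfg$vo_fraction_target <= 0) {
    avascular <- matrix(FALSE, side, side)
  } else if (cfg$vo_shape == "disc") {
    rv <- R * sqrt(cfg$vo_fraction_target)
    avascular <- retina & (r2 <= rv^2)
  } else {
    # annulus sector between r = R/2 and r = r_out, centred on +x axis
    frac <- cfg$vo_fraction_target
    span <- deg2rad(cfg$sector_deg)
    r_out <- sqrt(frac * 2 * pi * R^2 / span + (R / 2)^2)
    ang <- atan2(iy - ctr, ix - ctr)
    avascular <- retina & r2 >= (R / 2)^2 & r2 <= r_out^2 &
      abs(ang) <= span / 2
  }
  # capillary mesh: jittered grid strands spanning the retina
  s <- cfg$vessel_spacing_px
  t <- cfg$vessel_thickness_px
  vessel <- matrix(FALSE, side, side)
  for (x0 in seq(1, side, by = s)) {
    off <- round(runif(1, -cfg$jitter_px, cfg$jitter_px))
    lo <- max(1, x0 + off); hi <- min(side, x0 + off + t - 1)
    if (lo <= hi) vessel[lo:hi, ] <- TRUE
  }
  for (y0 in seq(1, side, by = s)) {
    off <- round(runif(1, -cfg$jitter_px, cfg$jitter_px))
    lo <- max(1, y0 + off); hi <- min(side, y0 + off + t - 1)
    if (lo <= hi) vessel[, lo:hi] <- TRUE
  }
  # ring the avascular border with vessel (the VO margin is vessel-bounded),
  # so mesh gap pockets stay enclosed and do not merge into the hole
  if (any(avascular)) {
    brush <- EBImage::makeBrush(2 * ceiling(t) + 1, shape = "disc")
    border <- as.matrix(EBImage::dilate(EBImage::Image(avascular * 1),
                                        brush)) > 0 & !avascular
    vessel <- vessel | border
  }
  vessel <- vessel & retina & !avascular
  structure(list(vessel = vessel, retina = retina, avascular = avascular,
                 pixel_size_um = cfg$pixel_size_um,
                 vo_fraction_true = sum(avascular & retina) / sum(retina),
                 vessel_fill_analytic = 1 - (1 - t / s)^2,
                 config = cfg),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf(
    "<vessel_mask> %d x %d px at %.2f um/px, vessel fill %.3f, true VO %.3f\n",
    nrow(x$vessel), ncol(x$vessel), x$pixel_size_um,
    sum(x$vessel) / sum(x$retina), x$vo_fraction_true))
  invisible(x)
}
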