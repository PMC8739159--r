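test_that("front tangent frames are right-handed and inward-oriented", {
  # straight horizontal front, avascular side above
  line <- tibble::tibble(x_um = seq(0, 100, by = 2), y_um = 0)
  fr <- front_tangent(line, 26, half_window = 5, inward_point = c(50, 100))
  expect_equal(fr$normal, c(0, 1), tolerance = 1e-12)
  expect_equal(fr$tangent, c(1, 0), tolerance = 1e-12)
  # avascular side below flips both vectors (frame stays right-handed)
  fr2 <- front_tangent(line, 26, half_window = 5, inward_point = c(50, -100))
  expect_equal(fr2$normal, c(0, -1), tolerance = 1e-12)
  expect_equal(fr2$tangent, c(-1, 0), tolerance = 1e-12)
  # circle: normal at each vertex points along the radius toward the centre
  th <- seq(0, 2 * pi, length.out = 400)[-400]
  circ <- tibble::tibble(x_um = 50 * cos(th), y_um = 50 * sin(th))
  for (k in c(30, 150, 300)) {
    fr3 <- front_tangent(circ, k, half_window = 4, inward_point = c(0, 0))
    radial <- -c(circ$x_um[k], circ$y_um[k]) / 50
    expect_lt(sum(abs(fr3$normal - radial)), 0.02)
  }
  expect_error(front_tangent(line, 0, inward_point = c(0, 1)), "range")
})

test_that("tip orientation scores signed angles against the local front", {
  line <- tibble::tibble(x_um = seq(0, 100, by = 2), y_um = 0)
  tips <- tibble::tibble(tip_id = 1:4, x_um = c(10, 30, 50, 70), y_um = 1,
                         dir_x = c(0, 1, cos(5 * pi / 12), 0),
                         dir_y = c(1, 0, sin(5 * pi / 12), -1))
  out <- tip_orientation(tips, line, inward_point = c(50, 100))
  expect_equal(out$theta_deg, c(90, 0, 75, -90), tolerance = 1e-9)
  expect_equal(out$oriented, c(TRUE, FALSE, TRUE, FALSE))
  # zero direction vectors are dropped with a warning
  expect_warning(
    z <- tip_orientation(dplyr::mutate(tips, dir_x = 0, dir_y = 0), line,
                         inward_point = c(50, 100)),
    "zero direction")
  expect_equal(nrow(z), 0)
})

test_that("oriented tip fraction hits its degenerate and uniform limits", {
  # perfectly concentrated tips all point along the inward normal
  sc <- generate_front_scene(front_sim_config(n_tips = 40, tip_kappa = Inf,
                                              seed = 4))
  res <- oriented_tip_fraction(sc)
  expect_equal(res$fraction, 1)
  # uniform tips: expected window mass is 60/360
  sc0 <- generate_front_scene(front_sim_config(
    front_length_um = 4000, n_tips = 4000, tip_kappa = 0, seed = 9))
  res0 <- oriented_tip_fraction(sc0)
  expect_within_3se(res0$fraction, 1 / 6, 4000)
})

test_that("filopodia are counted by the sub-diameter skeleton branches", {
  px <- 0.04  # 40 nm pixels resolve the 0.1 um diameter cut-off
  # axis-aligned spurs rasterise without stair-step skeleton artefacts
  m <- disc_mask(161, c(81, 81), 20)
  for (a in c(0, 90, 180)) m <- add_spur(m, c(81, 81), a, 18, 45)
  out <- count_filopodia(m, pixel_size_um = px)
  expect_equal(out$count, 3L)
  # straight base-to-tip chords: about (45 - 20) px beyond the body
  expect_true(all(abs(out$lengths_um - 25 * px) <= 2.5 * px))
  # a thick protrusion is skeletonised but rejected by its width
  m2 <- add_spur(m, c(81, 81), 270, 18, 45, width_px = 5)
  out2 <- count_filopodia(m2, pixel_size_um = px)
  expect_equal(out2$count, 3L)
  expect_true(any(!out2$branches$accepted))
  # relaxing the diameter cut-off can only add branches
  out3 <- count_filopodia(m2, pixel_size_um = px, diameter_max_um = 0.5)
  expect_gte(out3$count, out2$count)
  # a pixel grid coarser than the cut-off cannot support the measurement
  expect_error(count_filopodia(m, pixel_size_um = 0.2), "resolve")
  expect_equal(count_filopodia(matrix(FALSE, 10, 10), 0.04)$count, 0L)
})

test_that("sprout metrics recover body radius and radial extents", {
  m <- disc_mask(201, c(101, 101), 40)
  for (a in c(0, 120, 240)) m <- add_spur(m, c(101, 101), a, 38, 60,
                                          width_px = 3)
  res <- sprout_metrics(m, pixel_size_um = 1)
  expect_equal(res$n_sprouts, 3L)
  expect_lt(abs(res$body_radius_um - 40), 1.5)
  expect_true(all(abs(res$sprout_lengths_um - (60 - res$body_radius_um))
                  <= 1.5))
  # relative length against a reference mean
  res_rel <- sprout_metrics(m, 1, reference_mean_um =
                              mean(res$sprout_lengths_um))
  expect_equal(res_rel$relative_length, 1)
  # a bare disc has no sprouts; an empty mask is handled
  expect_equal(sprout_metrics(disc_mask(101, c(51, 51), 30), 1)$n_sprouts, 0L)
  empty <- sprout_metrics(matrix(FALSE, 20, 20), 1)
  expect_equal(empty$n_sprouts, 0L)
  expect_true(is.na(empty$body_radius_um))
})

test_that("sprout lengths in micrometres are stable under pixel size halving", {
  build <- function(scale) {
    ctr <- 100 * scale + 1
    m <- disc_mask(200 * scale + 1, c(ctr, ctr), 40 * scale)
    for (a in c(0, 120, 240)) {
      m <- add_spur(m, c(ctr, ctr), a, 38 * scale, 60 * scale,
                    width_px = 3 * scale)
    }
    m
  }
  r1 <- sprout_metrics(build(1), pixel_size_um = 1)
  r2 <- sprout_metrics(build(2), pixel_size_um = 0.5)
  expect_equal(r1$n_sprouts, r2$n_sprouts)
  # tip extents (body + length) are the scale-stable quantity; the body
  # radius itself is quantised to the annulus grid (half a coarse pixel)
  ext1 <- r1$body_radius_um + mean(r1$sprout_lengths_um)
  ext2 <- r2$body_radius_um + mean(r2$sprout_lengths_um)
  expect_lt(abs(ext1 - ext2) / ext1, 0.02)
  expect_lt(abs(mean(r1$sprout_lengths_um) - mean(r2$sprout_lengths_um)), 1)
})

test_that("vessel density matches the analytic mesh fill on a hole-free retina", {
  cfg <- retina_mask_config(vo_fraction_target = 0, seed = 2)
  mk <- generate_retina_mask(cfg)
  expect_lt(abs(vessel_density(mk) - mk$vessel_fill_analytic), 0.02)
  # hand-built mask: vessels cover exactly half of the region
  toy <- list(vessel = rbind(c(TRUE, TRUE), c(FALSE, FALSE)),
              retina = matrix(TRUE, 2, 2))
  expect_equal(vessel_density(toy), 0.5)
  expect_error(vessel_density(list(vessel = toy$vessel,
                                   retina = matrix(FALSE, 2, 2)),
                              region = matrix(TRUE, 2, 2)), "inside")
  expect_warning(d0 <- vessel_density(toy, region = matrix(FALSE, 2, 2)),
                 "empty")
  expect_true(is.na(d0))
})

test_that("avascular fraction recovers the generated vaso-obliterated area", {
  cfg <- retina_mask_config(vo_fraction_target = 0.1, seed = 7)
  mk <- generate_retina_mask(cfg)
  res <- avascular_fraction(mk, closing_radius_um = 12,
                            min_region_area_um2 = 500)
  expect_lt(abs(res$vo_fraction - mk$vo_fraction_true), 0.01)
  expect_equal(res$retina_area_um2, sum(mk$retina) * cfg$pixel_size_um^2)
  # determinism: identical config gives identical masks
  mk2 <- generate_retina_mask(cfg)
  expect_identical(mk$vessel, mk2$vessel)
  # degenerate limits with no dilation or filtering
  novessel <- list(vessel = matrix(FALSE, 11, 11),
                   retina = disc_mask(11, c(6, 6), 5), pixel_size_um = 1)
  expect_equal(avascular_fraction(novessel)$vo_fraction, 1)
  allvessel <- list(vessel = disc_mask(11, c(6, 6), 5),
                    retina = disc_mask(11, c(6, 6), 5), pixel_size_um = 1)
  expect_equal(avascular_fraction(allvessel)$vo_fraction, 0)
  # sector-shaped lesions hit the target area too
  cfgs <- retina_mask_config(vo_fraction_target = 0.08, vo_shape = "sector",
                             sector_deg = 120, seed = 3)
  mks <- generate_retina_mask(cfgs)
  expect_lt(abs(mks$vo_fraction_true - 0.08), 0.01)
})

test_that("filopodia counts per tip follow the configured Poisson mean", {
  sc <- generate_front_scene(front_sim_config(
    front_length_um = 2000, n_tips = 2000, filopodia_lambda = 5, seed = 13))
  expect_lt(abs(mean(sc$tips$filopodia_count) - 5), 3 * sqrt(5 / 2000))
  expect_equal(nrow(sc$filopodia), sum(sc$tips$filopodia_count))
  expect_true(all(sc$filopodia$length_um > 0))
})
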