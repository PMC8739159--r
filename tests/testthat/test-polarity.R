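test_that("monolayer generator respects spacing, side, and seeding", {
  cfg <- scene_config(n_cells = 150, field_um = c(400, 400),
                      edge = wound_edge(c(300, 0), 0),
                      polarity_kappa = 1, seed = 3)
  sc <- generate_monolayer_scene(cfg)
  d <- as.matrix(dist(cbind(sc$cells$nx_um, sc$cells$ny_um)))
  diag(d) <- Inf
  expect_gte(min(d), cfg$nucleus_spacing_min_um)
  expect_true(all(edge_signed_distance(sc$cells$nx_um, sc$cells$ny_um,
                                       sc$edge) <= 0))
  sc2 <- generate_monolayer_scene(cfg)
  expect_identical(sc$cells, sc2$cells)
  # infeasible request names the achievable count
  expect_error(generate_monolayer_scene(
    scene_config(n_cells = 10000, field_um = c(100, 100),
                 edge = wound_edge(c(80, 0), 0))), "placeable")
})

test_that("perfectly concentrated scenes give oriented fraction 1", {
  sc <- generate_monolayer_scene(scene_config(n_cells = 60,
                                              polarity_kappa = Inf,
                                              seed = 2))
  expect_true(all(sc$cells$true_alpha_deg == 90))
  res <- pair_golgi_to_nuclei(
    dplyr::rename(sc$cells, x_um = nx_um, y_um = ny_um),
    dplyr::rename(sc$cells, x_um = gx_um, y_um = gy_um), 7.5) |>
    polarization_angle(sc$edge) |>
    polarized_fraction()
  expect_equal(res$oriented_fraction, 1)
})

test_that("pairing follows mutual nearest neighbours under the gate", {
  nuc <- tibble::tibble(x_um = c(0, 20), y_um = 0)
  gol <- tibble::tibble(x_um = 2, y_um = 0)
  rec <- pair_golgi_to_nuclei(nuc, gol, 5)
  expect_equal(nrow(rec), 1)
  expect_equal(c(rec$vx_um, rec$vy_um), c(2, 0))
  # beyond the gate: no pairing
  expect_equal(nrow(pair_golgi_to_nuclei(nuc, tibble::tibble(x_um = 6,
                                                             y_um = 0), 5)),
               1 - 1)
  # equidistant golgi pairs to the lower index and is flagged
  nuc2 <- tibble::tibble(x_um = c(-2, 2), y_um = 0)
  rec2 <- pair_golgi_to_nuclei(nuc2, tibble::tibble(x_um = 0, y_um = 0), 5)
  expect_equal(rec2$cell_id, 1)
  expect_true(rec2$ambiguous_pairing)
  expect_error(pair_golgi_to_nuclei(nuc, gol, -1), "positive")
})

test_that("pairing recovers the generator ground truth exactly when offsets are small", {
  sc <- generate_monolayer_scene(scene_config(n_cells = 100,
                                              polarity_kappa = 0.5,
                                              golgi_offset_um = 5,
                                              nucleus_spacing_min_um = 15,
                                              field_um = c(500, 400),
                                              edge = wound_edge(c(400, 0), 0),
                                              seed = 10))
  rec <- pair_golgi_to_nuclei(
    dplyr::rename(sc$cells, x_um = nx_um, y_um = ny_um),
    dplyr::rename(sc$cells, x_um = gx_um, y_um = gy_um), 7.5)
  expect_equal(nrow(rec), 100)
  expect_equal(rec$cell_id, sc$cells$cell_id)
  expect_equal(rec$vx_um, sc$cells$gx_um - sc$cells$nx_um)
})

test_that("polarization angles match the schematic conventions", {
  edge <- wound_edge(c(0, 0), normal_deg = 90)
  rec <- tibble::tibble(cell_id = 1:3, nx_um = 0, ny_um = -10,
                        vx_um = c(0, 0, sqrt(0.5)),
                        vy_um = c(1, -1, sqrt(0.5)))
  out <- polarization_angle(rec, edge)
  expect_equal(out$alpha_deg, c(90, -90, 45))
  expect_equal(out$distance_to_edge_um, rep(10, 3))
  # zero vector dropped with a warning
  expect_warning(
    z <- polarization_angle(tibble::tibble(cell_id = 1, nx_um = 0, ny_um = 0,
                                           vx_um = 0, vy_um = 0), edge),
    "zero polarity")
  expect_equal(nrow(z), 0)
})

test_that("layer assignment uses ceiling bands and excludes deep or wound-side cells", {
  edge <- wound_edge(c(100, 0), normal_deg = 0)
  rec <- tibble::tibble(cell_id = 1:4,
                        nx_um = c(95, 55, 0, 110), ny_um = 0,
                        vx_um = 1, vy_um = 0)
  out <- assign_layers(polarization_angle(rec, edge), edge,
                       layer_width_um = 20, n_layers = 3)
  expect_equal(out$layer_index, c(1, 3, 5, NA))  # 5, 45, 100 um; wound side
  expect_equal(out$included, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("oriented fraction matches the analytic von Mises window mass", {
  sc <- generate_monolayer_scene(
    scene_config(n_cells = 5000, field_um = c(2200, 1800),
                 edge = wound_edge(c(1900, 0), 0),
                 polarity_kappa = 2, seed = 6))
  res <- pair_golgi_to_nuclei(
    dplyr::rename(sc$cells, x_um = nx_um, y_um = ny_um),
    dplyr::rename(sc$cells, x_um = gx_um, y_um = gy_um), 7.5) |>
    polarization_angle(sc$edge) |>
    polarized_fraction()
  expect_within_3se(res$oriented_fraction, riemann_vm_mass(2), 5000)
})

test_that("angles are rotation-equivariant and reflect correctly", {
  sc <- generate_monolayer_scene(scene_config(n_cells = 80,
                                              polarity_kappa = 1, seed = 12))
  rec <- pair_golgi_to_nuclei(
    dplyr::rename(sc$cells, x_um = nx_um, y_um = ny_um),
    dplyr::rename(sc$cells, x_um = gx_um, y_um = gy_um), 7.5) |>
    polarization_angle(sc$edge)
  for (phi in c(17, 90, 233)) {
    a <- phi * pi / 180
    Rm <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
    rot <- function(x, y) cbind(x, y) %*% t(Rm)
    cells_r <- rot(sc$cells$nx_um, sc$cells$ny_um)
    golgi_r <- rot(sc$cells$gx_um, sc$cells$gy_um)
    pr <- rot(sc$edge$point[1], sc$edge$point[2])
    edge_r <- wound_edge(pr, sc$edge$normal_deg + phi)
    rec_r <- tibble::tibble(cell_id = sc$cells$cell_id,
                            nx_um = cells_r[, 1], ny_um = cells_r[, 2],
                            vx_um = golgi_r[, 1] - cells_r[, 1],
                            vy_um = golgi_r[, 2] - cells_r[, 2]) |>
      polarization_angle(edge_r)
    expect_lt(max(abs(wrap_angle_deg(rec_r$alpha_deg - rec$alpha_deg))),
              1e-6)
  }
  # the scene edge is the vertical line x = ex with inward normal +x
  ex <- sc$edge$point[1]
  # mirror across the edge line itself: the normal component of every
  # polarity vector flips, so alpha -> -alpha
  mirror <- polarization_angle(
    dplyr::transmute(rec, cell_id, nx_um = 2 * ex - nx_um, ny_um,
                     vx_um = -vx_um, vy_um),
    sc$edge)
  expect_equal(mirror$alpha_deg, -rec$alpha_deg, tolerance = 1e-9)
  # mirror across the normal axis (y = 0): alpha -> 180 - alpha, mapped to
  # the signed range
  mirror2 <- polarization_angle(
    dplyr::transmute(rec, cell_id, nx_um, ny_um = -ny_um,
                     vx_um, vy_um = -vy_um),
    sc$edge)
  expect_equal(wrap_angle_deg(180 - mirror2$alpha_deg), rec$alpha_deg,
               tolerance = 1e-9)
})

test_that("wound edge estimation recovers an analytic half-plane frontier", {
  set.seed(33)
  pts <- tibble::tibble(x_um = runif(600, 0, 99.5), y_um = runif(600, 0, 300))
  edge <- estimate_wound_edge(pts, bin_width_um = 20, approx_normal_deg = 0)
  expect_lt(abs(wrap_angle_deg(edge$normal_deg - 0)), 1)
  expect_lt(abs(edge$point[1] - 100), 15)
  # jittered frontier: direction recovered within 2 degrees
  set.seed(34)
  pts2 <- tibble::tibble(x_um = c(runif(400, 0, 90),
                                  95 + rnorm(60, 0, 0.5)),
                         y_um = c(runif(400, 0, 300), seq(1, 300, length.out = 60)))
  edge2 <- estimate_wound_edge(pts2, bin_width_um = 5)
  expect_lt(abs(wrap_angle_deg(edge2$normal_deg)), 2)
  # cells everywhere -> explicit failure
  set.seed(35)
  expect_error(estimate_wound_edge(
    tibble::tibble(x_um = runif(500, 0, 100), y_um = runif(500, 0, 100)),
    bin_width_um = 10, field_um = c(100, 100)), "frontier")
})

test_that("rendered two-channel scenes segment to the generating centroids", {
  sc <- generate_monolayer_scene(
    scene_config(n_cells = 20, field_um = c(200, 200),
                 edge = wound_edge(c(150, 0), 0), polarity_kappa = 2,
                 nucleus_spacing_min_um = 18, seed = 8))
  img <- render_scene(sc, psf_sigma_px = 2, snr = Inf)
  expect_equal(attr(img, "channels"), c("nucleus", "golgi"))
  nuc <- segment_blobs(img[, , 1])
  expect_equal(nrow(nuc), 20)
  ord <- order(nuc$x_um, nuc$y_um)
  ord_t <- order(sc$cells$nx_um, sc$cells$ny_um)
  expect_lt(max(abs(nuc$x_um[ord] - sc$cells$nx_um[ord_t])), 0.5)
  # empty scene renders to background and segments to nothing
  sc0 <- sc
  sc0$cells <- sc0$cells[0, ]
  img0 <- render_scene(sc0, psf_sigma_px = 2, snr = Inf)
  expect_equal(nrow(segment_blobs(img0[, , 1])), 0)
  expect_equal(nrow(detect_nuclei(img0[, , 1])), 0)
  # speckles below min_area_px are dropped
  sp <- matrix(0, 50, 50); sp[10, 10] <- 1; sp[30:34, 30:34] <- 1
  expect_equal(nrow(segment_blobs(sp, min_area_px = 4)), 1)
})
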