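test_that("track statistics reproduce hand-computed displacement ratios", {
  tr <- tibble::tibble(
    track_id = rep(1:3, each = 3), frame = rep(1:3, 3),
    x_um = c(0, 1, 2,  0, 1, 0,  0, 3, 3),
    y_um = c(0, 0, 0,  0, 0, 0,  0, 0, 4))
  st <- track_statistics(tr)
  expect_equal(st$total_um, c(2, 2, 7))
  expect_equal(st$net_um, c(2, 0, 5))
  expect_equal(st$persistence, c(1, 0, 5 / 7))
  # zero total displacement -> undefined, flagged invalid
  still <- track_statistics(tibble::tibble(track_id = 1, frame = 1:3,
                                           x_um = 0, y_um = 0))
  expect_false(still$valid)
  expect_true(is.na(still$persistence))
})

test_that("spot detection recovers rendered centroids to sub-pixel accuracy", {
  tr <- tibble::tibble(track_id = 1, frame = 1, x_um = 10, y_um = 20)
  img <- render_track_movie(tr, field_um = c(64, 64), psf_sigma_px = 2)[[1]]
  d <- detect_nuclei(img)
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$x_um - 10), 0.5)
  expect_lt(abs(d$y_um - 20), 0.5)
  # blank frame -> empty, not an error
  expect_equal(nrow(detect_nuclei(matrix(0, 32, 32))), 0)
  # two spots 20 px apart at min_sep 5 -> exactly 2
  tr2 <- tibble::tibble(track_id = 1:2, frame = 1, x_um = c(20, 40),
                        y_um = c(30, 30))
  img2 <- render_track_movie(tr2, field_um = c(64, 64))[[1]]
  expect_equal(nrow(detect_nuclei(img2, min_sep_px = 5)), 2)
})

test_that("linking preserves identities of well-separated trajectories", {
  # two parallel tracks 10 um apart moving 1 um per frame, gate 2 um
  det <- tibble::tibble(frame = rep(1:8, each = 2),
                        x_um = rep(1:8, each = 2) + c(0, 0),
                        y_um = rep(c(0, 10), 8))
  lt <- link_tracks(det, max_disp_um = 2)
  expect_equal(length(unique(lt$track_id)), 2)
  by_tr <- split(lt$y_um, lt$track_id)
  expect_true(all(vapply(by_tr, function(y) length(unique(y)) == 1,
                         logical(1))))
  # single drifting detection -> one full-length track
  one <- tibble::tibble(frame = 1:10, x_um = (1:10) * 1.0, y_um = 0)
  lt1 <- link_tracks(one, max_disp_um = 2)
  expect_equal(unique(lt1$track_id), 1L)
  expect_equal(nrow(lt1), 10)
  # empty input and bad gate
  expect_equal(nrow(link_tracks(one[0, ], 2)), 0)
  expect_error(link_tracks(one, -1), "gate")
})

test_that("linking equals exhaustive-assignment tracking on random instances", {
  set.seed(314)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    # crossing-free tracks: starts far apart relative to the max step
    start <- cbind(runif(n, 0, 200), runif(n, 0, 200))
    while (min(dist(start)) < 30) {
      start <- cbind(runif(n, 0, 200), runif(n, 0, 200))
    }
    steps <- 10
    det <- purrr::map_dfr(seq_len(steps), function(f) {
      tibble::tibble(frame = f,
                     x_um = start[, 1] + cumsum(rep(0, n)) +
                       runif(n, -2, 2) + f * runif(1, -1, 1),
                     y_um = start[, 2] + runif(n, -2, 2))
    })
    gate <- 12
    got <- canonical_tracks(link_tracks(det, gate))
    want <- canonical_tracks(oracle_link(as.data.frame(det), gate))
    expect_equal(got, want)
  }
})

test_that("rose histogram bins net directions and flags empty input", {
  st <- tibble::tibble(net_direction_deg = rep(90, 7))
  h <- rose_histogram(st, n_bins = 12)
  expect_equal(sum(h$count), 7)
  expect_equal(h$count[h$bin_start_deg == 90], 7)
  # opposite directions in equal measure -> two equal bins
  h2 <- rose_histogram(tibble::tibble(net_direction_deg = rep(c(0, 180), 5)),
                       n_bins = 12)
  expect_equal(sort(h2$count[h2$count > 0]), c(5, 5))
  # uniform directions fill bins multinomially
  set.seed(8)
  h3 <- rose_histogram(tibble::tibble(
    net_direction_deg = runif(10000, 0, 360)), n_bins = 12)
  expect_true(all(abs(h3$count - 10000 / 12) <
                    3 * sqrt(10000 * (1 / 12) * (11 / 12))))
  expect_equal(sum(h3$count), 10000)
  # undefined directions excluded and counted
  h4 <- suppressWarnings(rose_histogram(
    tibble::tibble(net_direction_deg = NA_real_), 12))
  expect_true(attr(h4, "empty"))
  expect_equal(attr(h4, "n_excluded"), 1)
  expect_error(rose_histogram(st, n_bins = 7), "divide 360")
})

test_that("perpendicular classification follows the signed-angle window", {
  edge <- wound_edge(c(0, 0), normal_deg = 90)
  st <- tibble::tibble(track_id = 1:3,
                       net_direction_deg = c(90, 0, 60))  # n, e, boundary
  pf <- perpendicular_fraction(st, edge)
  expect_equal(pf$flags$alpha_deg, c(90, 0, 60))
  expect_equal(pf$flags$perpendicular, c(TRUE, FALSE, TRUE))
  expect_equal(pf$fraction, 2 / 3)
})

test_that("leading-edge filter keeps tracks starting within the band", {
  edge <- wound_edge(c(100, 0), normal_deg = 0)
  tr <- tibble::tibble(track_id = rep(1:3, each = 2), frame = rep(1:2, 3),
                       x_um = c(90, 95, 40, 45, 110, 115), y_um = 0)
  kept <- leading_edge_filter(tr, edge, band_um = 30)
  expect_equal(unique(kept$track_id), 1L)  # 2 too deep, 3 on wound side
})

test_that("simulate-render-detect-link-measure recovers per-track persistence", {
  # well-separated cells on a coarse grid, noise-free frames
  cfg <- track_sim_config(n_cells = 9, n_frames = 12, speed_mean_um = 2,
                          speed_sd_um = 0.3, persistence_kappa = 3,
                          bias_weight = 1, wound_normal_deg = 90, seed = 21,
                          start_box = c(0, 0, 0, 0))
  tracks <- simulate_tracks(cfg)
  grid <- expand.grid(x = c(60, 130, 200), y = c(60, 130, 200))
  tracks <- tracks |>
    dplyr::group_by(track_id) |>
    dplyr::mutate(x_um = x_um + grid$x[dplyr::cur_group_id()],
                  y_um = y_um + grid$y[dplyr::cur_group_id()]) |>
    dplyr::ungroup()
  frames <- render_track_movie(tracks, field_um = c(280, 280),
                               psf_sigma_px = 2)
  det <- purrr::map_dfr(seq_along(frames), function(f) {
    dplyr::mutate(detect_nuclei(frames[[f]], min_sep_px = 8), frame = f)
  })
  linked <- link_tracks(det, max_disp_um = 6)
  st <- track_statistics(linked)
  expect_equal(nrow(st), 9)
  truth <- track_statistics(tracks)
  # match recovered tracks to ground truth by start position
  starts <- linked |> dplyr::group_by(track_id) |>
    dplyr::slice_min(frame, n = 1) |> dplyr::ungroup()
  true_starts <- tracks |> dplyr::group_by(track_id) |>
    dplyr::slice_min(frame, n = 1) |> dplyr::ungroup()
  match <- vapply(seq_len(nrow(starts)), function(i) {
    true_starts$track_id[which.min((true_starts$x_um - starts$x_um[i])^2 +
                                   (true_starts$y_um - starts$y_um[i])^2)]
  }, integer(1))
  got <- st$persistence[order(starts$track_id)]
  want <- truth$persistence[match[order(starts$track_id)]]
  expect_lt(max(abs(got - want)), 0.02)
})
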