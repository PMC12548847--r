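make_translating_movie <- function(step = 2, nf = 10, ny = 40, nx = 60,
                                   noise = 1, seed = 2) {
  withr::with_seed(seed, {
    frames <- array(0, dim = c(nf, ny, nx))
    xs <- matrix(rep(1:nx, each = ny), ny, nx)
    ysm <- matrix(rep(1:ny, nx), ny, nx)
    for (t in 1:nf) {
      cx <- 10 + step * (t - 1)
      frames[t, , ] <- 100 * exp(-(((xs - cx)^2) / 18 + ((ysm - 20)^2) / 50)) +
        abs(rnorm(ny * nx, 0, noise))
    }
    ca_movie(frames, 1, 1)
  })
}

signal_flow_mean <- function(fl, min_frames) {
  m <- dplyr::filter(fl$mean_flow, .data$n_frames >= min_frames)
  c(dx = mean(m$mean_dx), dy = mean(m$mean_dy))
}

test_that("binarization threshold is mean + 0.5 SD", {
  vals <- array(rep(c(0, 100), each = 50), dim = c(4, 5, 5))
  mv <- ca_movie(vals, 1, 1)
  mask <- binarize_signal(mv)
  expect_equal(attr(mask, "threshold"), mean(vals) + 0.5 * sd(vals))
  expect_equal(attr(mask, "threshold"), 75, tolerance = 0.5)
  expect_true(all(mask[vals == 100]))
  expect_false(any(mask[vals == 0]))
  expect_warning(m0 <- binarize_signal(ca_movie(array(5, dim = c(2, 3, 3)), 1, 1)),
                 "Constant")
  expect_false(any(m0))
})

test_that("orientation puts the long axis vertical with ExE on top", {
  lay <- simulate_layout(seed = 3)
  tr <- orient_vertical(lay[, c("x_um", "y_um", "tissue")])
  rc <- tr$centroids
  pc <- prcomp(cbind(rc$x_um, rc$y_um))
  expect_lt(abs(abs(pc$rotation[2, 1]) - 1), 1e-6)
  expect_gt(mean(rc$y_um[rc$tissue == "ExE"]),
            mean(rc$y_um[rc$tissue != "ExE"]))
  # near-vertical input with ExE up: close-to-identity rotation
  vert <- tibble::tibble(x_um = rnorm(20, 0, 0.5), y_um = seq(0, 100, length.out = 20),
                         tissue = rep(c("epiblast", "ExE"), each = 10))
  t2 <- orient_vertical(vert)
  expect_lt(abs(t2$angle_rad), 0.05)
  # horizontal line with ExE at negative x rotates ExE upwards
  horiz <- tibble::tibble(x_um = seq(-50, 50, length.out = 20),
                          y_um = rnorm(20, 0, 0.2),
                          tissue = rep(c("ExE", "emVE"), each = 10))
  t3 <- orient_vertical(horiz)
  expect_gt(mean(t3$centroids$y_um[horiz$tissue == "ExE"]), 0)
  # isotropic cloud is ambiguous
  iso <- withr::with_seed(4, tibble::tibble(
    x_um = rnorm(200), y_um = rnorm(200),
    tissue = rep(c("ExE", "emVE"), 100)))
  expect_error(orient_vertical(iso), class = "embryocal_orientation_error")
})

test_that("re-orienting an oriented embryo is a no-op", {
  lay <- simulate_layout(seed = 7)
  once <- orient_vertical(lay[, c("x_um", "y_um", "tissue")])$centroids
  twice <- orient_vertical(once)$centroids
  expect_equal(twice$x_um, once$x_um - mean(once$x_um), tolerance = 1e-6)
  expect_equal(twice$y_um, once$y_um - mean(once$y_um), tolerance = 1e-6)
})

test_that("superpixel tracking recovers a translating front", {
  mv <- make_translating_movie(step = 2)
  fl <- track_flow(mv, n_superpixels = 60)
  v <- signal_flow_mean(fl, 5)
  expect_lt(abs(v["dx"] - 2), 0.25)
  expect_lt(abs(v["dy"]), 0.25)
})

test_that("blinking without motion produces no flow", {
  fr <- array(10, dim = c(6, 20, 20))
  for (t in 1:6) fr[t, 8:12, 8:12] <- if (t %% 2) 30 else 120
  fr <- fr + withr::with_seed(5, array(abs(rnorm(length(fr), 0, 0.5)), dim = dim(fr)))
  fl <- track_flow(ca_movie(fr, 1, 1), n_superpixels = 16)
  mag <- sqrt(fl$mean_flow$mean_dx^2 + fl$mean_flow$mean_dy^2)
  expect_lt(mean(mag), 0.1)
})

test_that("flow respects mirror and time-reversal symmetry", {
  mv <- make_translating_movie(step = 2)
  v <- signal_flow_mean(track_flow(mv, n_superpixels = 60), 5)
  mvm <- ca_movie(mv$frames[, , dim(mv$frames)[3]:1], 1, 1)
  vm <- signal_flow_mean(track_flow(mvm, n_superpixels = 60), 5)
  expect_lt(abs(v["dx"] + vm["dx"]), 0.3)
  mvr <- ca_movie(mv$frames[dim(mv$frames)[1]:1, , ], 1, 1)
  vr <- signal_flow_mean(track_flow(mvr, n_superpixels = 60), 5)
  expect_lt(abs(v["dx"] + vr["dx"]), 0.4)
})

test_that("the Lucas-Kanade backend tracks sub-pixel motion", {
  fr <- array(0, dim = c(8, 30, 30))
  xs <- matrix(rep(1:30, each = 30), 30, 30)
  ysm <- matrix(rep(1:30, 30), 30, 30)
  for (t in 1:8) {
    fr[t, , ] <- 100 * exp(-(((xs - (8 + 0.8 * (t - 1)))^2 + (ysm - 15)^2) / 40))
  }
  fl <- track_flow(ca_movie(fr, 1, 1), n_superpixels = 25, method = "lk")
  v <- signal_flow_mean(fl, 4)
  expect_lt(abs(v["dx"] - 0.8), 0.15)
  expect_warning(track_flow(ca_movie(array(c(1, 2), dim = c(2, 4, 4)), 1, 1),
                            mask = array(FALSE, dim = c(2, 4, 4)),
                            n_superpixels = 4),
                 "Empty")
})

test_that("wave estimation is exact on clean front positions", {
  front <- tibble::tibble(time_s = 0:2, position_um = c(0, 10, 20))
  est <- estimate_wave(front)
  expect_equal(est$speed_um_s, 10)
  expect_equal(est$direction, "apical_basal")
  rev_est <- estimate_wave(dplyr::mutate(front, position_um = rev(position_um)))
  expect_equal(rev_est$speed_um_s, 10)
  expect_equal(rev_est$direction, "basal_apical")
  expect_error(estimate_wave(front[1:2, ]), class = "embryocal_estimation_error")
})

test_that("the binarize-localize-regress pipeline recovers generator speeds", {
  for (sp in c(2, 8, 15.41, 20)) {
    w <- simulate_wave_movie(sp, frame_interval_s = 0.5, pixel_size_um = 0.5,
                             cell_depth_um = 40, noise_sd = 3, seed = 7)
    est <- wave_speed_from_movie(w$movie)
    expect_lt(abs(est$speed_um_s - sp) / sp, 0.15)
  }
})
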