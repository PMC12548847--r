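test_that("kernel calibration hits the requested width", {
  for (w in c(10, 20, 40)) {
    k <- calibrate_kernel(w, rise_s = 2)
    expect_lt(abs(k$fwhm_s - w), 0.01)
    # numerically re-measure the width on a fine grid
    tt <- seq(0, 10 * w, by = 0.05)
    y <- eval_kernel(tt, k, 1)
    above <- range(tt[y >= 0.5])
    expect_lt(abs(diff(above) - w), 0.1)
    expect_equal(eval_kernel(k$t_peak, k, 1), 1, tolerance = 1e-9)
    expect_lte(max(y), 1)
  }
  expect_error(calibrate_kernel(-1), class = "embryocal_config_error")
})

test_that("trace length and degenerate configurations behave as specified", {
  lay <- simulate_layout(seed = 1)
  ds <- simulate_embryo_dataset(sim_config(seed = 1), lay)
  expect_equal(unique(table(ds$traces$cell_id)), 121L)

  quiet <- sim_config(tissue_rates = c(epiblast = 0, ExE = 0, emVE = 0, exVE = 0),
                      noise_sd = 0, drift_amplitude = 0, seed = 1)
  ds0 <- simulate_embryo_dataset(quiet, lay)
  expect_true(all(ds0$traces$intensity == quiet$baseline_level))
  expect_equal(nrow(ds0$truth$events), 0L)

  expect_error(sim_config(duration_s = -5), class = "embryocal_config_error")
  expect_error(sim_config(frame_interval_s = 0), class = "embryocal_config_error")
  expect_error(sim_config(duration_s = 601), class = "embryocal_config_error")
  bad_lay <- tibble::tibble(cell_id = 1:3, tissue = c("emVE", "emVE", "notatissue"))
  expect_error(simulate_embryo_dataset(sim_config(), bad_lay),
               class = "embryocal_layout_error")
})

test_that("event counts follow the homogeneous Poisson law", {
  lay <- tibble::tibble(cell_id = seq_len(500), tissue = "epiblast")
  cfg_base <- sim_config(tissue_rates = c(epiblast = 0.15), noise_sd = 0,
                         drift_amplitude = 0)
  counts <- vapply(1:20, function(s) {
    cfg <- sim_config(tissue_rates = c(epiblast = 0.15), noise_sd = 0,
                      drift_amplitude = 0, seed = 1000 + s)
    nrow(simulate_embryo_dataset(cfg, lay)$truth$events)
  }, 1)
  n_cells <- 500 * 20
  mean_rate <- sum(counts) / n_cells
  se <- sqrt(0.15 / n_cells)
  expect_lt(abs(mean_rate - 0.15), 3 * se)
})

test_that("generation is bit-reproducible under a fixed seed", {
  lay <- simulate_layout(seed = 5)
  a <- simulate_embryo_dataset(sim_config(seed = 42), lay)
  b <- simulate_embryo_dataset(sim_config(seed = 42), lay)
  expect_identical(a$traces, b$traces)
  expect_identical(a$truth$events, b$truth$events)
  w1 <- simulate_wave_movie(10, noise_sd = 2, seed = 3)
  w2 <- simulate_wave_movie(10, noise_sd = 2, seed = 3)
  expect_identical(w1$movie$frames, w2$movie$frames)
})

test_that("isolated true events lie under local maxima of the noiseless trace", {
  lay <- tibble::tibble(cell_id = 1:80, tissue = "exVE")
  cfg <- sim_config(tissue_rates = c(exVE = 0.82), noise_sd = 0,
                    drift_amplitude = 0, seed = 9)
  ds <- simulate_embryo_dataset(cfg, lay)
  checked <- 0L
  for (cid in unique(ds$truth$events$cell_id)) {
    y <- ds$traces$intensity[ds$traces$cell_id == cid]
    locmax <- which(diff(sign(diff(y))) < 0) + 1L
    pt <- sort(ds$truth$events$peak_time_s[ds$truth$events$cell_id == cid])
    for (k in seq_along(pt)) {
      # a transient overlapping a larger neighbour, or truncated at the
      # trace end, need not have its own maximum; check isolated events
      gap_ok <- all(abs(pt[-k] - pt[k]) > 40)
      interior <- pt[k] > 10 && pt[k] < cfg$duration_s - 10
      if (!gap_ok || !interior) next
      expect_lte(min(abs(locmax - (round(pt[k] / 5) + 1))), 1)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 20)
})

test_that("wave movies advance the front at the configured speed", {
  # 1 px per frame: 1 um/s at 0.5 um pixels and 0.5 s frames
  w <- simulate_wave_movie(1, frame_interval_s = 0.5, pixel_size_um = 0.5,
                           cell_depth_um = 20, noise_sd = 0)
  fp <- front_positions(w$movie, axis = "y")
  steps <- diff(fp$position_um[!is.na(fp$position_um)])
  expect_true(all(abs(steps - 0.5) < 0.02))  # 1 px = 0.5 um per frame

  # intracellular transit time: ceil(40 / 15.41 / 0.5) frames
  w2 <- simulate_wave_movie(15.41, frame_interval_s = 0.5, pixel_size_um = 0.5,
                            cell_depth_um = 40, noise_sd = 0, edge_width_um = 0.1)
  done <- which(apply(w2$movie$frames, 1, min) >
                  w2$movie$frames[1, 1, 1] + 50)[1] - 1L
  expect_equal(done, ceiling(40 / 15.41 / 0.5))

  expect_error(simulate_wave_movie(0), class = "embryocal_config_error")
  expect_warning(simulate_wave_movie(0.1, frame_interval_s = 0.5,
                                     pixel_size_um = 0.5, cell_depth_um = 10),
                 "interpolate")
})

test_that("intercellular waves activate cells in distance order", {
  lay <- simulate_layout(seed = 2)
  origin <- lay$cell_id[which.max(lay$y_um)]
  w <- simulate_wave_movie(20, frame_interval_s = 0.5, pixel_size_um = 1,
                           mode = "intercellular", layout = lay, origin = origin)
  act <- w$truth$activation_s
  expect_equal(act$t_activate_s[act$cell_id == origin], 0)
  d <- sqrt((lay$x_um - lay$x_um[lay$cell_id == origin])^2 +
              (lay$y_um - lay$y_um[lay$cell_id == origin])^2)
  expect_equal(act$t_activate_s, d / 20, tolerance = 1e-8)
  expect_error(simulate_wave_movie(5, mode = "intercellular", layout = lay,
                                   origin = 99999),
               class = "embryocal_layout_error")
})

test_that("inhibitor experiments draw Poisson counts with the right means", {
  r1 <- simulate_inhibitor_experiment(400, 18, effect_multiplier = 1, seed = 3)
  m <- tapply(r1$total_transients, r1$timepoint, mean)
  expect_lt(abs(m[["baseline"]] - m[["treated_30min"]]), 4 * sqrt(2 * 18 / 400))

  r0 <- simulate_inhibitor_experiment(50, 18, effect_multiplier = 0, seed = 3)
  expect_true(all(r0$total_transients[r0$timepoint == "treated_30min"] == 0))

  r <- simulate_inhibitor_experiment(500, 18, effect_multiplier = 1.3 / 18, seed = 4)
  treated <- r$total_transients[r$timepoint == "treated_30min"]
  expect_lt(abs(mean(treated) - 1.3), 3 * sqrt(1.3 / 500))

  expect_error(simulate_inhibitor_experiment(5, 18, 1, timepoints = character(0)),
               class = "embryocal_config_error")
})
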