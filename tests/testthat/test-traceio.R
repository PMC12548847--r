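test_that("trace extraction is the per-label pixel mean", {
  frames <- array(0, dim = c(3, 4, 4))
  frames[, 1:2, 1:2] <- 7
  labels <- matrix(0L, 4, 4)
  labels[1:2, 1:2] <- 1L
  labels[3:4, 3:4] <- 2L
  frames[1, 3, 3] <- 3; frames[1, 3, 4] <- 5
  mv <- ca_movie(frames, 5, 1)
  lm <- roi_label_map(labels, tibble::tibble(cell_id = 1:2,
                                             tissue = c("emVE", "ExE")))
  tr <- extract_traces(mv, lm)
  expect_true(all(tr$intensity[tr$cell_id == 1] == 7))
  expect_equal(tr$intensity[tr$cell_id == 2 & tr$frame == 0], (3 + 5) / 4)
  expect_equal(tr$tissue[tr$cell_id == 2][1], "ExE")
})

test_that("extraction matches a per-pixel brute-force mean and is linear", {
  set.seed(11)
  frames <- array(runif(20 * 20 * 10, 0, 100), dim = c(10, 20, 20))
  labels <- matrix(sample(0:3, 400, replace = TRUE), 20, 20)
  mv <- ca_movie(frames, 5, 1)
  lm <- roi_label_map(labels, tibble::tibble(cell_id = 1:3,
                                             tissue = c("emVE", "ExE", "exVE")),
                      check_connected = FALSE)
  tr <- extract_traces(mv, lm)
  for (lab in 1:3) {
    for (t in 1:10) {
      acc <- 0; n <- 0
      for (i in 1:20) for (j in 1:20) {
        if (labels[i, j] == lab) { acc <- acc + frames[t, i, j]; n <- n + 1 }
      }
      expect_equal(tr$intensity[tr$cell_id == lab & tr$frame == t - 1],
                   acc / n, tolerance = 1e-12)
    }
  }
  mv2 <- ca_movie(frames * 2 + 1, 5, 1)
  mv_sum <- ca_movie(frames + frames * 2 + 1, 5, 1)
  expect_equal(extract_traces(mv_sum, lm)$intensity,
               extract_traces(mv, lm)$intensity + extract_traces(mv2, lm)$intensity,
               tolerance = 1e-9)
})

test_that("label map validation catches bad inputs", {
  labels <- matrix(c(0, 1, 1, 2), 2, 2)
  expect_error(roi_label_map(labels, tibble::tibble(cell_id = 1, tissue = "emVE")),
               class = "embryocal_label_error")
  expect_error(roi_label_map(labels, tibble::tibble(cell_id = 1:2,
                                                    tissue = c("emVE", "brain"))),
               class = "embryocal_label_error")
  split_lab <- matrix(0L, 5, 5); split_lab[1, 1] <- 1L; split_lab[5, 5] <- 1L
  expect_warning(roi_label_map(split_lab, tibble::tibble(cell_id = 1, tissue = "ExE")),
                 "connected")
  mv <- ca_movie(array(1, dim = c(2, 3, 3)), 5, 1)
  lm <- roi_label_map(matrix(1L, 2, 2), tibble::tibble(cell_id = 1, tissue = "ExE"))
  expect_error(extract_traces(mv, lm), class = "embryocal_format_error")
})

test_that("movies round-trip through 16-bit TIFF with sidecar metadata", {
  set.seed(3)
  frames <- array(sample(0:65535, 2 * 8 * 9, replace = TRUE), dim = c(2, 8, 9))
  mv <- ca_movie(frames, frame_interval_s = 2, pixel_size_um = 0.5)
  path <- withr::local_tempfile(fileext = ".tif")
  write_movie(mv, path)
  back <- read_movie(path)
  expect_identical(back$frames, frames + 0)  # numeric comparison, exact
  expect_equal(back$frame_interval_s, 2)
  expect_equal(back$pixel_size_um, 0.5)

  file.remove(paste0(path, ".json"))
  expect_warning(back2 <- read_movie(path), "sidecar")
  expect_equal(back2$frame_interval_s, 5)

  rgb <- array(runif(4 * 4 * 3), dim = c(4, 4, 3))
  rgb_path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(rgb, rgb_path)
  expect_error(read_movie(rgb_path), class = "embryocal_format_error")
})

test_that("label images round-trip", {
  labels <- matrix(0L, 6, 6); labels[2:3, 2:3] <- 1L; labels[5, 5:6] <- 7L
  lm <- roi_label_map(labels, tibble::tibble(cell_id = c(1L, 7L),
                                             tissue = c("emVE", "ExE")))
  path <- withr::local_tempfile(fileext = ".tif")
  write_labels(lm, path)
  back <- read_labels(path)
  expect_identical(back$labels + 0L, labels)
  expect_equal(back$tissues$tissue, c("emVE", "ExE"))
})

test_that("trace tables round-trip as CSV and enforce their contract", {
  lay <- simulate_layout(seed = 8)
  ds <- simulate_embryo_dataset(sim_config(seed = 8, duration_s = 100), lay)
  path <- withr::local_tempfile(fileext = ".csv")
  write_traces(ds$traces, path)
  back <- read_traces(path)
  expect_equal(back$intensity, ds$traces$intensity, tolerance = 1e-6)
  expect_identical(back$cell_id, ds$traces$cell_id)

  broken <- ds$traces[-1, ]  # one cell now has 20 frames instead of 21
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(broken, path2)
  expect_error(read_traces(path2), class = "embryocal_format_error")

  path3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(ds$traces, -"tissue"), path3)
  suppressWarnings(
    expect_error(read_traces(path3), class = "embryocal_format_error"))
})

test_that("a full-scale cohort table conserves per-tissue tallies", {
  # same shape as the quantified E5.5 dataset: 1,126 cells split
  # 323/430/205/168 across tissues, 14 embryos
  split <- c(epiblast = 323, ExE = 430, emVE = 205, exVE = 168)
  cells <- tibble::tibble(
    cell_id = seq_len(sum(split)),
    tissue = rep(names(split), split),
    embryo_id = sprintf("emb%02d", rep_len(1:14, sum(split))))
  traces <- tidyr::expand_grid(cells, frame = 0:2) |>
    dplyr::mutate(time_s = frame * 5, intensity = 100)
  path <- withr::local_tempfile(fileext = ".csv")
  write_traces(traces, path)
  back <- read_traces(path)
  tal <- dplyr::count(dplyr::distinct(back, .data$cell_id, .data$tissue), .data$tissue)
  expect_equal(sum(tal$n), 1126L)
  expect_equal(tal$n[match(names(split), tal$tissue)], unname(split), ignore_attr = TRUE)
})
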