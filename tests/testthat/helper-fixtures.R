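# Shared fixtures, built in code and cached for the session.

# SNR-5 regime used across detection benchmarks: 5-s frames, 10-min
# traces, 20-s FWHM kernels of amplitude 100 on noise SD 20.
snr5_config <- function(seed, noise_sd = 20) {
  sim_config(noise_sd = noise_sd, seed = seed)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Detector benchmark data: training and held-out test sets with two
# isolated transients per trace.
detector_train_set <- function() {
  cached("det_train", {
    d <- simulate_transient_traces(60, snr5_config(21), events_per_trace = 2,
                                   min_gap_s = 80)
    d$detrended <- detrend_traces(d$traces)
    d
  })
}

detector_test_set <- function() {
  cached("det_test", {
    d <- simulate_transient_traces(150, snr5_config(99), events_per_trace = 2,
                                   min_gap_s = 80)
    d$detrended <- detrend_traces(d$traces)
    d
  })
}

# CNN trained once per session on ground-truth labels of the training set.
truth_trained_detector <- function() {
  cached("det_model", {
    tr <- detector_train_set()
    labs <- dplyr::transmute(tr$truth$events, embryo_id, cell_id,
                             frame = as.integer(round(peak_time_s / 5)))
    train_detector(tr$detrended, labs, seed = 7)
  })
}

# Noiseless trace with transient apexes landing exactly on given frames.
kernel_trace <- function(peak_frames, n_frames = 121, interval = 5,
                         amplitude = 100, fwhm = 20) {
  kern <- calibrate_kernel(fwhm)
  tt <- (seq_len(n_frames) - 1) * interval
  y <- rep(0, n_frames)
  for (f in peak_frames) {
    y <- y + eval_kernel(tt - (f * interval - kern$t_peak), kern, amplitude)
  }
  y
}

# Wrap a single intensity vector as a one-cell trace table.
as_trace_tbl <- function(y, interval = 5, embryo = "e1", cell = 1L,
                         tissue = "emVE") {
  tibble::tibble(embryo_id = embryo, cell_id = cell, tissue = tissue,
                 frame = seq_along(y) - 1L,
                 time_s = (seq_along(y) - 1L) * interval, intensity = y)
}

# Dense reference solver for the ALS inner problem (test oracle).
dense_als_reference <- function(y, lambda = 1e3, p = 0.01, max_iter = 10) {
  m <- length(y)
  D <- matrix(0, m - 2, m)
  for (i in seq_len(m - 2)) D[i, i:(i + 2)] <- c(1, -2, 1)
  P <- lambda * crossprod(D)
  w <- rep(1, m)
  z <- y
  for (it in seq_len(max_iter)) {
    z <- solve(P + diag(w), w * y)
    w_new <- ifelse(y > z, p, 1 - p)
    if (all(w_new == w)) break
    w <- w_new
  }
  as.numeric(z)
}
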