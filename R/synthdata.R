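#' Simulation configuration for synthetic embryo timelapses
#'
#' Bundles the acquisition and signal parameters of the synthetic
#' generator. Defaults emulate the quantified imaging regime: a single
#' mid-sagittal optical section at 5-s intervals for 10 min, GCaMP-like
#' transients of ~20 s full width at half maximum riding on a slow
#' baseline drift with shot-like Gaussian noise. The default per-tissue
#' transient rates (expected transients per cell per 10 min) are a
#' calibration chosen so the expected active-cell fractions
#' \eqn{1 - e^{-rate}} match the observed per-tissue percentages; they are
#' not measured rates.
#'
#' @param frame_interval_s Acquisition interval, seconds.
#' @param duration_s Total imaged duration, seconds; must be a positive
#'   multiple of `frame_interval_s`. A frame at t = 0 is always included,
#'   so traces have `duration_s / frame_interval_s + 1` frames.
#' @param tissue_rates Named numeric vector, expected transients per cell
#'   per 10 min, one entry per tissue.
#' @param kernel_amplitude Transient peak height, arbitrary units.
#' @param kernel_fwhm_s Transient full width at half maximum, seconds.
#' @param kernel_rise_s Transient rise time constant, seconds.
#' @param baseline_level Constant fluorescence baseline, AU.
#' @param drift_amplitude Amplitude of the slow sinusoidal drift, AU.
#' @param noise_sd SD of i.i.d. Gaussian noise added per frame, AU.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(frame_interval_s = 5,
                       duration_s = 600,
                       tissue_rates = c(epiblast = 0.11, ExE = 0.48,
                                        emVE = 0.51, exVE = 0.82),
                       kernel_amplitude = 100,
                       kernel_fwhm_s = 20,
                       kernel_rise_s = 2,
                       baseline_level = 100,
                       drift_amplitude = 20,
                       noise_sd = 20,
                       seed = 1L) {
  if (frame_interval_s <= 0) abort_config("`frame_interval_s` must be positive.")
  if (duration_s <= 0) abort_config("`duration_s` must be positive.")
  if (abs(duration_s / frame_interval_s - round(duration_s / frame_interval_s)) > 1e-9) {
    abort_config("`duration_s` must be a multiple of `frame_interval_s`.")
  }
  if (any(tissue_rates < 0)) abort_config("Tissue rates must be >= 0.")
  if (kernel_fwhm_s <= frame_interval_s / 2) {
    abort_config("`kernel_fwhm_s` must exceed half the frame interval.")
  }
  if (noise_sd < 0) abort_config("`noise_sd` must be >= 0.")
  structure(list(frame_interval_s = frame_interval_s, duration_s = duration_s,
                 tissue_rates = tissue_rates,
                 kernel_amplitude = kernel_amplitude,
                 kernel_fwhm_s = kernel_fwhm_s, kernel_rise_s = kernel_rise_s,
                 baseline_level = baseline_level,
                 drift_amplitude = drift_amplitude, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Synthetic egg-cylinder cell layout
#'
#' Places cell centroids in a stylised mid-sagittal egg-cylinder section:
#' the extraembryonic ectoderm (ExE) occupies the proximal (top) interior,
#' the epiblast the distal (bottom) interior, and the visceral endoderm
#' monolayer wraps the outside (emVE over the epiblast, exVE over the
#' ExE). Adjacency is mutual nearest-neighbour and symmetric.
#'
#' @param n_per_tissue Named integer vector of cell counts per tissue.
#' @param pixel_size_um Physical pixel size, micrometres.
#' @param seed Integer seed.
#' @return A tibble of class `embryo_layout` with columns `cell_id`,
#'   `tissue`, `x_um`, `y_um`, and attributes `adjacency` (list of integer
#'   vectors keyed by cell id) and `pixel_size_um`.
#' @export
simulate_layout <- function(n_per_tissue = c(epiblast = 23, ExE = 31,
                                             emVE = 15, exVE = 12),
                            pixel_size_um = 1,
                            seed = 1L) {
  if (pixel_size_um <= 0) abort_config("`pixel_size_um` must be positive.")
  unknown <- setdiff(names(n_per_tissue), ca_tissues())
  if (length(unknown) > 0) {
    abort(paste0("Unknown tissue in layout: ", paste(unknown, collapse = ", ")),
          class = "embryocal_layout_error")
  }
  withr::with_seed(as.integer(seed), {
    # Egg cylinder: ellipse with semi-axes 40 (x) and 80 (y), centred at (50, 90).
    place <- function(n, tissue) {
      if (n == 0) return(NULL)
      u <- runif(n)
      th <- runif(n, 0, 2 * pi)
      pts <- switch(tissue,
        ExE = cbind(50 + 28 * sqrt(u) * cos(th), 90 + 55 * (0.1 + 0.85 * runif(n))),
        epiblast = cbind(50 + 28 * sqrt(u) * cos(th), 90 - 55 * (0.1 + 0.85 * runif(n))),
        emVE = {
          a <- runif(n, pi, 2 * pi)  # distal half of the outline
          cbind(50 + 36 * cos(a), 90 + 72 * sin(a))
        },
        exVE = {
          a <- runif(n, 0, pi)       # proximal half of the outline
          cbind(50 + 36 * cos(a), 90 + 72 * sin(a))
        })
      tibble(tissue = tissue, x_um = pts[, 1], y_um = pts[, 2])
    }
    cells <- dplyr::bind_rows(purrr::imap(as.list(n_per_tissue),
                                          function(n, tis) place(n, tis)))
    cells <- dplyr::mutate(cells, cell_id = seq_len(nrow(cells)), .before = 1)
    d <- as.matrix(stats::dist(cells[, c("x_um", "y_um")]))
    diag(d) <- Inf
    k <- min(4, nrow(cells) - 1)
    adj <- lapply(seq_len(nrow(cells)), function(i) {
      order(d[i, ])[seq_len(k)]
    })
    # symmetrize
    for (i in seq_along(adj)) for (j in adj[[i]]) {
      adj[[j]] <- sort(unique(c(adj[[j]], i)))
    }
    structure(cells, adjacency = adj, pixel_size_um = pixel_size_um,
              class = c("embryo_layout", class(cells)))
  })
}

#' Simulate a synthetic embryo trace dataset with ground truth
#'
#' Draws, for every cell of the layout, a homogeneous Poisson number of
#' transient events at the cell's tissue rate (scaled to the configured
#' duration), places the events uniformly in time, and synthesises the
#' fluorescence trace as baseline + slow sinusoidal drift + transient
#' kernels + Gaussian noise.
#'
#' @param config A [sim_config()].
#' @param layout An [simulate_layout()] layout (or any tibble with
#'   `cell_id` and `tissue` columns).
#' @param embryo_id Identifier stamped on the traces.
#' @return A list with `traces` (long tibble: embryo_id, cell_id, tissue,
#'   frame, time_s, intensity) and `truth` (list with `events`, a tibble
#'   of true event times, and `config`).
#' @export
simulate_embryo_dataset <- function(config, layout, embryo_id = "sim1") {
  stopifnot(inherits(config, "sim_config"))
  if (!all(c("cell_id", "tissue") %in% names(layout))) {
    abort("Layout must have `cell_id` and `tissue` columns.",
          class = "embryocal_layout_error")
  }
  unknown <- setdiff(unique(layout$tissue), names(config$tissue_rates))
  if (length(unknown) > 0) {
    abort(paste0("Layout tissue(s) missing from `tissue_rates`: ",
                 paste(unknown, collapse = ", ")),
          class = "embryocal_layout_error")
  }
  n_frames <- as.integer(round(config$duration_s / config$frame_interval_s)) + 1L
  times <- (seq_len(n_frames) - 1L) * config$frame_interval_s
  kern <- calibrate_kernel(config$kernel_fwhm_s, config$kernel_rise_s)

  withr::with_seed(config$seed, {
    out <- purrr::map2(layout$cell_id, layout$tissue, function(cid, tis) {
      rate <- config$tissue_rates[[tis]] * config$duration_s / 600
      n_ev <- rpois(1, rate)
      ev <- sort(runif(n_ev, 0, config$duration_s))
      clean <- rep(config$baseline_level, n_frames)
      if (config$drift_amplitude > 0) {
        phase <- runif(1, 0, 2 * pi)
        clean <- clean + config$drift_amplitude *
          sin(2 * pi * times / (2 * config$duration_s) + phase)
      }
      for (te in ev) {
        clean <- clean + eval_kernel(times - te, kern, config$kernel_amplitude)
      }
      y <- clean + rnorm(n_frames, 0, config$noise_sd)
      list(trace = y, events = ev)
    })
    traces <- tibble(
      embryo_id = embryo_id,
      cell_id = rep(layout$cell_id, each = n_frames),
      tissue = rep(layout$tissue, each = n_frames),
      frame = rep.int(seq_len(n_frames) - 1L, nrow(layout)),
      time_s = rep.int(times, nrow(layout)),
      intensity = unlist(lapply(out, `[[`, "trace"), use.names = FALSE)
    )
    events <- tibble(
      embryo_id = embryo_id,
      cell_id = rep(layout$cell_id, times = vapply(out, function(o) length(o$events), 1L)),
      event_time_s = unlist(lapply(out, `[[`, "events"), use.names = FALSE)
    )
    events$peak_time_s <- events$event_time_s + kern$t_peak
    list(traces = traces, truth = list(events = events, config = config))
  })
}

#' Simulate traces carrying a fixed number of isolated transients
#'
#' Benchmark generator for duration/intensity recovery: each trace holds
#' exactly `events_per_trace` transients placed uniformly at least
#' `margin_s` from the trace ends and at least `min_gap_s` apart, plus
#' drift and noise as configured.
#'
#' @param n_traces Number of traces to generate.
#' @param config A [sim_config()]; tissue rates are ignored.
#' @param events_per_trace Events injected per trace.
#' @param margin_s Keep events this far from both trace ends, seconds.
#' @param min_gap_s Minimum spacing between events in a trace, seconds.
#' @return As [simulate_embryo_dataset()].
#' @export
simulate_transient_traces <- function(n_traces, config, events_per_trace = 1,
                                      margin_s = 40, min_gap_s = 60) {
  stopifnot(inherits(config, "sim_config"))
  n_frames <- as.integer(round(config$duration_s / config$frame_interval_s)) + 1L
  times <- (seq_len(n_frames) - 1L) * config$frame_interval_s
  kern <- calibrate_kernel(config$kernel_fwhm_s, config$kernel_rise_s)
  withr::with_seed(config$seed, {
    out <- purrr::map(seq_len(n_traces), function(cid) {
      repeat {
        ev <- sort(runif(events_per_trace, margin_s, config$duration_s - margin_s))
        if (events_per_trace < 2 || min(diff(ev)) >= min_gap_s) break
      }
      clean <- rep(config$baseline_level, n_frames)
      if (config$drift_amplitude > 0) {
        phase <- runif(1, 0, 2 * pi)
        clean <- clean + config$drift_amplitude *
          sin(2 * pi * times / (2 * config$duration_s) + phase)
      }
      for (te in ev) clean <- clean + eval_kernel(times - te, kern, config$kernel_amplitude)
      list(trace = clean + rnorm(n_frames, 0, config$noise_sd), events = ev)
    })
    traces <- tibble(
      embryo_id = "bench",
      cell_id = rep(seq_len(n_traces), each = n_frames),
      tissue = "emVE",
      frame = rep.int(seq_len(n_frames) - 1L, n_traces),
      time_s = rep.int(times, n_traces),
      intensity = unlist(lapply(out, `[[`, "trace"), use.names = FALSE)
    )
    events <- tibble(
      embryo_id = "bench",
      cell_id = rep(seq_len(n_traces), each = events_per_trace),
      event_time_s = unlist(lapply(out, `[[`, "events"), use.names = FALSE)
    )
    events$peak_time_s <- events$event_time_s + kern$t_peak
    list(traces = traces, truth = list(events = events, config = config))
  })
}

#' Simulate a propagating calcium wave movie
#'
#' Builds a pixel movie in which fluorescence rises as a planar front,
#' travelling at constant speed from an origin, passes each pixel.
#' `mode = "intracellular"` models a single apical-to-basal transit of one
#' columnar cell (front moves down the cell's long axis from the apical
#' face at the top); `mode = "intercellular"` activates the cells of a
#' layout in order of centroid distance from an origin cell.
#'
#' @param speed_um_s Front speed, micrometres per second (> 0).
#' @param frame_interval_s Frame interval, seconds.
#' @param pixel_size_um Pixel size, micrometres.
#' @param mode `"intracellular"` or `"intercellular"`.
#' @param layout Required for intercellular mode.
#' @param origin Origin `cell_id` (intercellular mode).
#' @param cell_depth_um,cell_width_um Cell geometry for intracellular mode.
#' @param participating Optional cell ids taking part in the wave
#'   (intercellular mode); defaults to all.
#' @param edge_width_um Width of the smooth (logistic) front edge.
#' @param baseline,amplitude Intensity floor and front step height, AU.
#' @param noise_sd Gaussian pixel noise SD, AU.
#' @param duration_s Movie length; defaults to 1.3x the front transit time.
#' @param seed Integer seed for the noise.
#' @return A list with `movie` (class `ca_movie`: `frames` array
#'   \[t, y, x\], `frame_interval_s`, `pixel_size_um`) and `truth`
#'   (speed, mode, activation times for intercellular mode).
#' @export
simulate_wave_movie <- function(speed_um_s,
                                frame_interval_s = 0.5,
                                pixel_size_um = 0.5,
                                mode = c("intracellular", "intercellular"),
                                layout = NULL, origin = NULL,
                                cell_depth_um = 40, cell_width_um = 10,
                                participating = NULL,
                                edge_width_um = 1,
                                baseline = 10, amplitude = 100,
                                noise_sd = 0, duration_s = NULL,
                                seed = 1L) {
  mode <- match.arg(mode)
  if (speed_um_s <= 0) abort_config("`speed_um_s` must be positive.")
  if (speed_um_s * frame_interval_s < pixel_size_um) {
    warn("Front moves less than one pixel per frame; estimation will interpolate.")
  }
  if (mode == "intracellular") {
    transit <- cell_depth_um / speed_um_s
    duration_s <- duration_s %||% (1.3 * transit)
    n_frames <- max(4L, as.integer(floor(duration_s / frame_interval_s)) + 1L)
    ny <- as.integer(round(cell_depth_um / pixel_size_um))
    nx <- as.integer(round(cell_width_um / pixel_size_um))
    y_um <- (seq_len(ny) - 0.5) * pixel_size_um  # depth below the apical face
    frames <- array(0, dim = c(n_frames, ny, nx))
    for (t in seq_len(n_frames)) {
      d <- speed_um_s * (t - 1L) * frame_interval_s
      col <- baseline + amplitude * stats::plogis((d - y_um) / edge_width_um)
      frames[t, , ] <- matrix(col, ny, nx)
    }
    truth <- list(speed_um_s = speed_um_s, mode = mode, axis = "apical_basal",
                  depth_um = cell_depth_um)
  } else {
    if (is.null(layout) || is.null(origin)) {
      abort_config("Intercellular mode needs `layout` and `origin`.")
    }
    if (!origin %in% layout$cell_id) {
      abort("`origin` is not a cell of the layout.", class = "embryocal_layout_error")
    }
    participating <- participating %||% layout$cell_id
    o <- layout[layout$cell_id == origin, ]
    dist_um <- sqrt((layout$x_um - o$x_um)^2 + (layout$y_um - o$y_um)^2)
    t_act <- dist_um / speed_um_s
    duration_s <- duration_s %||% (1.3 * max(t_act[layout$cell_id %in% participating]))
    n_frames <- max(4L, as.integer(floor(duration_s / frame_interval_s)) + 1L)
    nx <- as.integer(ceiling(max(layout$x_um) / pixel_size_um)) + 12L
    ny <- as.integer(ceiling(max(layout$y_um) / pixel_size_um)) + 12L
    r_px <- max(2, round(3 / pixel_size_um))
    frames <- array(baseline, dim = c(n_frames, ny, nx))
    cx <- round(layout$x_um / pixel_size_um) + 6L
    cy <- round(layout$y_um / pixel_size_um) + 6L
    for (t in seq_len(n_frames)) {
      tt <- (t - 1L) * frame_interval_s
      for (i in seq_len(nrow(layout))) {
        if (!layout$cell_id[i] %in% participating) next
        level <- amplitude * stats::plogis((tt - t_act[i]) /
                                             (edge_width_um / speed_um_s + 1e-9))
        if (level < 1e-3) next
        ys <- pmax(1L, cy[i] - r_px):pmin(ny, cy[i] + r_px)
        xs <- pmax(1L, cx[i] - r_px):pmin(nx, cx[i] + r_px)
        frames[t, ys, xs] <- baseline + level
      }
    }
    truth <- list(speed_um_s = speed_um_s, mode = mode, origin = origin,
                  activation_s = tibble(cell_id = layout$cell_id,
                                        t_activate_s = t_act))
  }
  if (noise_sd > 0) {
    withr::with_seed(as.integer(seed), {
      frames <- frames + array(rnorm(length(frames), 0, noise_sd), dim = dim(frames))
    })
  }
  movie <- structure(list(frames = frames, frame_interval_s = frame_interval_s,
                          pixel_size_um = pixel_size_um), class = "ca_movie")
  list(movie = movie, truth = truth)
}

#' Simulate a pharmacological inhibitor experiment
#'
#' Draws per-embryo whole-embryo transient counts at each timepoint from a
#' Poisson distribution: mean `baseline_rate` at baseline and
#' `baseline_rate * effect_multiplier` after treatment (an optional
#' recovery timepoint uses `recovery_multiplier`).
#'
#' @param n_embryos Number of embryos (>= 1).
#' @param baseline_rate Expected transients per embryo per timelapse at
#'   baseline.
#' @param effect_multiplier Multiplicative effect of treatment (>= 0).
#' @param timepoints Character vector of timepoints; must include
#'   `"baseline"`.
#' @param recovery_multiplier Multiplier for a `"recovery_30min"`
#'   timepoint, if present.
#' @param condition Condition label stamped on the records.
#' @param seed Integer seed.
#' @return A tibble: embryo_id, condition, timepoint, total_transients.
#' @export
simulate_inhibitor_experiment <- function(n_embryos, baseline_rate,
                                          effect_multiplier,
                                          timepoints = c("baseline", "treated_30min"),
                                          recovery_multiplier = NULL,
                                          condition = "treated",
                                          seed = 1L) {
  if (length(timepoints) == 0) abort_config("`timepoints` must be non-empty.")
  if (n_embryos < 1) abort_config("`n_embryos` must be >= 1.")
  if (effect_multiplier < 0) abort_config("`effect_multiplier` must be >= 0.")
  mult <- vapply(timepoints, function(tp) {
    switch(tp,
           baseline = 1,
           recovery_30min = recovery_multiplier %||% 1,
           effect_multiplier)
  }, 1)
  withr::with_seed(as.integer(seed), {
    tidyr::expand_grid(embryo_id = sprintf("emb%03d", seq_len(n_embryos)),
                       timepoint = timepoints) |>
      dplyr::mutate(condition = condition,
                    total_transients = rpois(dplyr::n(),
                                             baseline_rate * mult[.data$timepoint]),
                    .after = "embryo_id")
  })
}

#' Simulate the clustering benchmark dataset
#'
#' A multi-embryo dataset mixing quiescent (noise-only) cells with three
#' oscillatory archetypes of distinct periods and amplitudes, mirroring
#' the structure used for global trace clustering: cells of one archetype
#' share a period (with per-event jitter) but have random phases, so
#' shift-tolerant similarity groups them while quiescent cells stay
#' diffuse.
#'
#' @param n_embryos Number of embryos.
#' @param cells_per_embryo Cells per embryo.
#' @param quiescent_fraction Fraction of cells with no events.
#' @param periods_s Oscillation periods of the three archetypes, seconds.
#' @param amplitudes Kernel amplitudes per archetype, AU.
#' @param config Base [sim_config()] (interval, duration, kernel, noise).
#' @param seed Integer seed.
#' @return A list with `traces` and `truth` (per-cell archetype labels:
#'   "quiescent" or "periodic_<period>").
#' @export
simulate_cluster_benchmark <- function(n_embryos = 14, cells_per_embryo = 60,
                                       quiescent_fraction = 0.5,
                                       periods_s = c(60, 180, 300),
                                       amplitudes = c(150, 100, 60),
                                       config = sim_config(noise_sd = 12),
                                       seed = 1L) {
  stopifnot(length(periods_s) == 3, length(amplitudes) == 3)
  n_frames <- as.integer(round(config$duration_s / config$frame_interval_s)) + 1L
  times <- (seq_len(n_frames) - 1L) * config$frame_interval_s
  kern <- calibrate_kernel(config$kernel_fwhm_s, config$kernel_rise_s)
  n_q <- round(cells_per_embryo * quiescent_fraction)
  n_a <- cells_per_embryo - n_q
  arche_of <- function(i) 1 + (i - 1) %% 3
  withr::with_seed(as.integer(seed), {
    res <- purrr::map(seq_len(n_embryos), function(e) {
      eid <- sprintf("emb%02d", e)
      labels <- c(rep("quiescent", n_q),
                  paste0("periodic_", periods_s[arche_of(seq_len(n_a))]))
      mats <- purrr::map(seq_len(cells_per_embryo), function(ci) {
        clean <- rep(config$baseline_level, n_frames)
        if (labels[ci] != "quiescent") {
          a_idx <- arche_of(ci - n_q)
          period <- periods_s[a_idx]
          phase <- runif(1, 0, period)
          ev <- seq(phase, config$duration_s, by = period)
          ev <- ev + rnorm(length(ev), 0, config$frame_interval_s / 2)
          ev <- ev[ev >= 0 & ev <= config$duration_s]
          for (te in ev) {
            clean <- clean + eval_kernel(times - te, kern, amplitudes[a_idx])
          }
        }
        clean + rnorm(n_frames, 0, config$noise_sd)
      })
      list(
        traces = tibble(
          embryo_id = eid,
          cell_id = rep(seq_len(cells_per_embryo), each = n_frames),
          tissue = "emVE",
          frame = rep.int(seq_len(n_frames) - 1L, cells_per_embryo),
          time_s = rep.int(times, cells_per_embryo),
          intensity = unlist(mats, use.names = FALSE)
        ),
        labels = tibble(embryo_id = eid, cell_id = seq_len(cells_per_embryo),
                        archetype = labels)
      )
    })
    list(traces = purrr::list_rbind(purrr::map(res, "traces")),
         truth = list(labels = purrr::list_rbind(purrr::map(res, "labels")),
                      config = config))
  })
}
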