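#' Movie and label-map containers
#'
#' `ca_movie()` wraps a 3D intensity array (time, y, x) with its frame
#' interval and pixel size. `roi_label_map()` wraps an integer label image
#' (0 = background, one positive integer per manually segmented cell)
#' together with the cell-to-tissue table.
#'
#' @param frames Numeric array \[t, y, x\], non-negative, >= 2 frames.
#' @param frame_interval_s Frame interval, seconds.
#' @param pixel_size_um Pixel size, micrometres.
#' @return An object of class `ca_movie`.
#' @export
ca_movie <- function(frames, frame_interval_s = 5, pixel_size_um = 1) {
  if (length(dim(frames)) != 3) abort_format("`frames` must be a 3D array [t, y, x].")
  if (dim(frames)[1] < 2) abort_format("A movie needs at least 2 frames.")
  if (any(frames < 0)) abort_format("Movie intensities must be non-negative.")
  if (frame_interval_s <= 0 || pixel_size_um <= 0) {
    abort_config("Frame interval and pixel size must be positive.")
  }
  structure(list(frames = frames, frame_interval_s = frame_interval_s,
                 pixel_size_um = pixel_size_um), class = "ca_movie")
}

#' @rdname ca_movie
#' @param labels Integer matrix (y, x); 0 is reserved for background.
#' @param tissues Tibble/data frame with columns `cell_id`, `tissue`.
#' @param check_connected Warn when a label's pixels are not 4-connected.
#' @export
roi_label_map <- function(labels, tissues, check_connected = TRUE) {
  labels <- as.matrix(labels)
  if (any(labels < 0) || any(labels != round(labels))) {
    abort_format("Labels must be non-negative integers (0 = background).")
  }
  present <- sort(setdiff(unique(as.vector(labels)), 0))
  missing <- setdiff(present, tissues$cell_id)
  if (length(missing) > 0) {
    abort(paste0("Label(s) absent from the tissue table: ",
                 paste(missing, collapse = ", ")),
          class = "embryocal_label_error")
  }
  unknown <- setdiff(unique(tissues$tissue), ca_tissues())
  if (length(unknown) > 0) {
    abort(paste0("Unknown tissue(s): ", paste(unknown, collapse = ", ")),
          class = "embryocal_label_error")
  }
  if (check_connected) {
    for (lab in present) {
      if (!is_connected(labels == lab)) {
        warn(sprintf("Label %d does not form a 4-connected region.", lab))
      }
    }
  }
  structure(list(labels = labels, tissues = as_tibble(tissues)),
            class = "ca_labels")
}

# Breadth-first 4-connectivity check on a logical mask.
is_connected <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) <= 1) return(TRUE)
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  queue <- idx[1, , drop = FALSE]
  seen[queue] <- TRUE
  found <- 1L
  while (nrow(queue) > 0) {
    nxt <- rbind(queue + rep(c(1L, 0L), each = nrow(queue)),
                 queue + rep(c(-1L, 0L), each = nrow(queue)),
                 queue + rep(c(0L, 1L), each = nrow(queue)),
                 queue + rep(c(0L, -1L), each = nrow(queue)))
    ok <- nxt[, 1] >= 1 & nxt[, 1] <= nrow(mask) &
      nxt[, 2] >= 1 & nxt[, 2] <= ncol(mask)
    nxt <- nxt[ok, , drop = FALSE]
    ok <- mask[nxt] & !seen[nxt]
    nxt <- unique(nxt[ok, , drop = FALSE])
    seen[nxt] <- TRUE
    found <- found + nrow(nxt)
    queue <- nxt
  }
  found == nrow(idx)
}

#' Extract per-cell mean-intensity traces from a labelled movie
#'
#' For every nonzero label, the trace value at each time point is the
#' arithmetic mean of the movie pixels inside that label's region —
#' the standard average-ROI-intensity readout.
#'
#' @param movie A [ca_movie()].
#' @param labels A [roi_label_map()] whose image matches the movie frames.
#' @param embryo_id Identifier stamped on the traces.
#' @param statistic Pixel statistic, `"mean"` (default, the tested path)
#'   or `"median"`.
#' @return A long trace tibble (embryo_id, cell_id, tissue, frame, time_s,
#'   intensity).
#' @export
extract_traces <- function(movie, labels, embryo_id = "embryo1",
                           statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(movie, "ca_movie"), inherits(labels, "ca_labels"))
  dm <- dim(movie$frames)
  if (!all(dim(labels$labels) == dm[2:3])) {
    abort_format("Label image shape does not match the movie frames.")
  }
  n_frames <- dm[1]
  flat <- matrix(movie$frames, nrow = n_frames)  # columns = pixels (y fastest)
  lab_vec <- as.vector(labels$labels)
  ids <- sort(setdiff(unique(lab_vec), 0))
  stat_fun <- if (statistic == "mean") rowMeans else function(m) apply(m, 1, median)
  rows <- purrr::map(ids, function(lab) {
    pix <- which(lab_vec == lab)
    if (length(pix) == 0) {
      warn(sprintf("Label %d has an empty region; skipped.", lab))
      return(NULL)
    }
    vals <- if (length(pix) == 1) flat[, pix] else stat_fun(flat[, pix, drop = FALSE])
    tibble(embryo_id = embryo_id, cell_id = as.integer(lab),
           tissue = labels$tissues$tissue[match(lab, labels$tissues$cell_id)],
           frame = seq_len(n_frames) - 1L,
           time_s = (seq_len(n_frames) - 1L) * movie$frame_interval_s,
           intensity = vals)
  })
  purrr::list_rbind(rows)
}

#' Read and write movies as multi-page TIFF with a JSON sidecar
#'
#' Pixel data travel as 16-bit multi-page TIFF; frame interval and pixel
#' size live in a `<path>.json` sidecar because plain TIFF has no slot
#' for them. Round-trips are exact for 16-bit integer data.
#'
#' @param movie A [ca_movie()]; intensities must fit in \[0, 65535\].
#' @param path TIFF file path.
#' @return `read_movie()` returns a [ca_movie()]; `write_movie()` returns
#'   `path` invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "ca_movie"))
  fr <- round(movie$frames)
  if (any(fr < 0) || any(fr > 65535)) {
    abort_format("Intensities must fit in 16-bit [0, 65535] for TIFF export.")
  }
  pages <- lapply(seq_len(dim(fr)[1]), function(t) fr[t, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  jsonlite::write_json(list(frame_interval_s = movie$frame_interval_s,
                            pixel_size_um = movie$pixel_size_um),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @param path TIFF file path (with optional `<path>.json` sidecar).
#' @export
read_movie <- function(path) {
  if (!file.exists(path)) abort_input(paste0("No such file: ", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2, TRUE))) {
    abort_format("Movie must be monochrome; multi-channel TIFF given.")
  }
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort_format("Ragged TIFF stack: pages differ in shape.")
  }
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  } else {
    warn("No metadata sidecar; assuming frame_interval_s = 5, pixel_size_um = 1.")
    meta <- list(frame_interval_s = 5, pixel_size_um = 1)
  }
  frames <- array(0, dim = c(length(pages), dims[1, 1], dims[2, 1]))
  for (t in seq_along(pages)) frames[t, , ] <- pages[[t]]
  ca_movie(frames, meta$frame_interval_s, meta$pixel_size_um)
}

#' Read and write label images as integer TIFF
#'
#' @param labels A [roi_label_map()].
#' @param path TIFF path for the label image; the tissue table is written
#'   next to it as `<path>.tissues.csv`.
#' @return `read_labels()` returns a [roi_label_map()].
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "ca_labels"))
  tiff::writeTIFF(labels$labels / 65535, path, bits.per.sample = 16)
  readr::write_csv(labels$tissues, paste0(path, ".tissues.csv"))
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  tissues <- readr::read_csv(paste0(path, ".tissues.csv"),
                             show_col_types = FALSE)
  roi_label_map(img, tissues, check_connected = FALSE)
}

#' Read and write long trace tables as CSV
#'
#' The on-disk format is the long table used throughout: one row per
#' (embryo, cell, frame), columns `embryo_id, cell_id, tissue, frame,
#' time_s, intensity`. Rows come back grouped by embryo and cell and
#' sorted by frame; every cell must have the same number of frames.
#'
#' @param traces A trace tibble.
#' @param path CSV file path.
#' @return `read_traces()` returns the trace tibble.
#' @export
write_traces <- function(traces, path) {
  check_trace_tbl(traces)
  readr::write_csv(dplyr::arrange(traces, .data$embryo_id, .data$cell_id,
                                  .data$frame), path)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) abort_input(paste0("No such file: ", path))
  traces <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = readr::cols(
                              embryo_id = readr::col_character(),
                              cell_id = readr::col_integer(),
                              tissue = readr::col_character(),
                              frame = readr::col_integer()))
  check_trace_tbl(traces)
  traces <- dplyr::arrange(traces, .data$embryo_id, .data$cell_id, .data$frame)
  counts <- dplyr::count(traces, .data$embryo_id, .data$cell_id)
  if (length(unique(counts$n)) > 1) {
    abort_format("Non-uniform frame count across cells in the trace table.")
  }
  traces
}
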