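#' Per-peak transient events from a de-trended trace
#'
#' For each detected peak the transient's extent is measured at half peak
#' height: the start is the time of the last frame before the rising
#' trace reaches half the peak height, the end is the time of the first
#' frame after the falling trace drops below it, and the duration is
#' their difference. Half-crossings are searched only within the
#' inter-peak interval (between flanking peaks or trace ends); a peak at
#' a trace boundary, or one whose half-crossing cannot be resolved before
#' the next peak, is flagged `truncated` and reports no duration.
#'
#' The reference level for "half peak intensity" is configurable and
#' recorded in the output: `"zero"` (default — de-trended traces are
#' zero-baselined, so height is the de-trended peak value),
#' `"interpeak_min"` or `"interpeak_median"` (height above the minimum or
#' median of the inter-peak interval).
#'
#' @param y De-trended intensity series.
#' @param peak_frames 0-based frames of detected peaks (local maxima).
#' @param frame_interval_s Frame interval, seconds.
#' @param baseline_ref Reference level convention (see Details).
#' @return Tibble: peak_frame, peak_time_s, start_time_s, end_time_s,
#'   duration_s, peak_intensity, truncated.
#' @examples
#' peak_events(c(0, 2, 6, 10, 7, 4, 1), peak_frames = 3, frame_interval_s = 5)
#' @export
peak_events <- function(y, peak_frames, frame_interval_s = 5,
                        baseline_ref = c("zero", "interpeak_min", "interpeak_median")) {
  baseline_ref <- match.arg(baseline_ref)
  n <- length(y)
  pk <- sort(as.integer(peak_frames)) + 1L  # 1-based
  if (length(pk) > 0 && (min(pk) < 1 || max(pk) > n)) {
    abort_input("Peak frame outside the trace.")
  }
  # measurements assume each peak frame is a local maximum of the trace;
  # snap detector calls to the apex within one frame so the half-height
  # reference is the actual apex value
  pk <- vapply(pk, function(i) {
    idx <- max(1, i - 1):min(n, i + 1)
    idx[which.max(y[idx])]
  }, 1L)
  pk <- sort(unique(pk))
  rows <- purrr::map(seq_along(pk), function(k) {
    i <- pk[k]
    lo <- if (k > 1) pk[k - 1] + 1L else 1L
    hi <- if (k < length(pk)) pk[k + 1] - 1L else n
    base <- switch(baseline_ref,
                   zero = 0,
                   interpeak_min = min(y[lo:hi]),
                   interpeak_median = median(y[lo:hi]))
    h <- y[i] - base
    half <- base + h / 2
    start_f <- NA_integer_
    if (i > lo) {
      below <- which(y[lo:(i - 1)] < half)
      if (length(below) > 0) start_f <- lo + max(below) - 1L
    }
    end_f <- NA_integer_
    if (i < hi) {
      below <- which(y[(i + 1):hi] < half)
      if (length(below) > 0) end_f <- i + min(below)
    }
    truncated <- is.na(start_f) || is.na(end_f) || i == 1L || i == n
    tibble(peak_frame = i - 1L,
           peak_time_s = (i - 1L) * frame_interval_s,
           start_time_s = if (is.na(start_f)) NA_real_ else (start_f - 1L) * frame_interval_s,
           end_time_s = if (is.na(end_f)) NA_real_ else (end_f - 1L) * frame_interval_s,
           duration_s = if (truncated) NA_real_ else (end_f - start_f) * frame_interval_s,
           peak_intensity = y[i] - base,
           truncated = truncated)
  })
  out <- purrr::list_rbind(rows)
  if (nrow(out) == 0) {
    out <- tibble(peak_frame = integer(0), peak_time_s = numeric(0),
                  start_time_s = numeric(0), end_time_s = numeric(0),
                  duration_s = numeric(0), peak_intensity = numeric(0),
                  truncated = logical(0))
  }
  out
}

#' Transient events for every cell of a trace table
#'
#' Applies [peak_events()] per cell, pairing each cell's de-trended trace
#' with its peak calls.
#'
#' @param traces De-trended long trace tibble.
#' @param peaks Peak-call tibble (embryo_id, cell_id, frame).
#' @param baseline_ref See [peak_events()].
#' @return Event tibble with identity columns plus the [peak_events()]
#'   measures.
#' @export
transient_events <- function(traces, peaks,
                             baseline_ref = c("zero", "interpeak_min",
                                              "interpeak_median")) {
  baseline_ref <- match.arg(baseline_ref)
  check_trace_tbl(traces, require_tissue = FALSE)
  value <- pick_value_col(traces)
  interval <- infer_interval(traces)
  vecs <- trace_vectors(dplyr::mutate(traces, intensity = .data[[value]]))
  meta <- trace_meta(traces)
  keys <- paste(meta$embryo_id, meta$cell_id, sep = "/")
  pk_key <- paste(peaks$embryo_id, peaks$cell_id, sep = "/")
  rows <- purrr::map(seq_along(vecs), function(k) {
    pf <- peaks$frame[pk_key == keys[k]]
    if (length(pf) == 0) return(NULL)
    ev <- peak_events(vecs[[k]], pf, frame_interval_s = interval,
                      baseline_ref = baseline_ref)
    dplyr::bind_cols(meta[rep(k, nrow(ev)), ], ev)
  })
  purrr::list_rbind(rows)
}

#' Per-cell transient summary
#'
#' Summarises each cell's transient events: number of peaks, mean peak
#' intensity, mean duration (over non-truncated events), and the
#' oscillation period as the mean peak-to-peak distance — defined only
#' for cells with at least two peaks, otherwise reported as `NA`.
#'
#' @param events Event tibble from [transient_events()].
#' @param cells Optional tibble of all cells (embryo_id, cell_id, tissue)
#'   so quiescent cells appear with `n_peaks = 0`; defaults to the cells
#'   present in `events`.
#' @return Tibble: embryo_id, cell_id, tissue, n_peaks,
#'   mean_peak_intensity, mean_period_s, mean_duration_s.
#' @export
summarize_cells <- function(events, cells = NULL) {
  per_cell <- events |>
    dplyr::group_by(.data$embryo_id, .data$cell_id) |>
    dplyr::arrange(.data$peak_time_s, .by_group = TRUE) |>
    dplyr::summarise(
      n_peaks = dplyr::n(),
      mean_peak_intensity = mean(.data$peak_intensity),
      mean_period_s = if (dplyr::n() >= 2) mean(diff(.data$peak_time_s)) else NA_real_,
      mean_duration_s = if (all(is.na(.data$duration_s))) NA_real_
                        else mean(.data$duration_s, na.rm = TRUE),
      .groups = "drop")
  cells <- cells %||% dplyr::distinct(events[, intersect(c("embryo_id", "cell_id", "tissue"),
                                                         names(events))])
  out <- dplyr::left_join(cells, per_cell, by = c("embryo_id", "cell_id"))
  out$n_peaks[is.na(out$n_peaks)] <- 0L
  out
}

#' Per-tissue transient summary
#'
#' Aggregates cell summaries by tissue: cell counts, the number and
#' percentage of active cells (>= 1 transient), and means of the per-cell
#' measures. The emVE is not subdivided into DVE and non-DVE.
#'
#' @param cell_summaries Tibble from [summarize_cells()]; must carry a
#'   `tissue` column with known tissue labels.
#' @return Tibble: tissue, n_cells, n_active, percent_active,
#'   mean_n_peaks, mean_period_s, mean_duration_s, mean_peak_intensity.
#' @export
summarize_tissues <- function(cell_summaries) {
  if (!"tissue" %in% names(cell_summaries)) {
    abort_input("`cell_summaries` must carry a `tissue` column.")
  }
  unknown <- setdiff(unique(cell_summaries$tissue), ca_tissues())
  if (length(unknown) > 0) {
    abort_input(paste0("Unknown tissue label(s): ", paste(unknown, collapse = ", ")))
  }
  cell_summaries |>
    dplyr::group_by(.data$tissue) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_active = sum(.data$n_peaks >= 1),
      percent_active = percent(sum(.data$n_peaks >= 1), dplyr::n()),
      mean_n_peaks = mean(.data$n_peaks),
      mean_period_s = if (all(is.na(.data$mean_period_s))) NA_real_
                      else mean(.data$mean_period_s, na.rm = TRUE),
      mean_duration_s = if (all(is.na(.data$mean_duration_s))) NA_real_
                        else mean(.data$mean_duration_s, na.rm = TRUE),
      mean_peak_intensity = if (all(is.na(.data$mean_peak_intensity))) NA_real_
                            else mean(.data$mean_peak_intensity, na.rm = TRUE),
      .groups = "drop")
}
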