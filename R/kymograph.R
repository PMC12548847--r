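#' Kymograph row order
#'
#' Rows (cells) are ordered by an indirect stable sort with cluster
#' number first and the time of the cell's first peak second. Rows
#' without peaks sort after the peaked rows of their cluster, preserving
#' input order among themselves.
#'
#' @param clusters Cluster id per row (`NA` sorts last).
#' @param first_peak_times First-peak time per row (`NA` = no peaks).
#' @return Integer permutation of the rows.
#' @export
row_order <- function(clusters, first_peak_times) {
  if (length(clusters) != length(first_peak_times)) {
    abort_input("`clusters` and `first_peak_times` must have equal length.")
  }
  cl <- as.numeric(clusters)
  cl[is.na(cl)] <- Inf
  no_peak <- is.na(first_peak_times)
  fp <- first_peak_times
  fp[no_peak] <- 0
  order(cl, no_peak, fp, method = "radix")
}

#' Render a kymograph of trace activity
#'
#' Stacks traces as an image — one row per cell, one column per time
#' point — with the two normalization/colour conventions:
#' `per_embryo_minmax` (values in \[0, 1\] from embryo-wide min-max,
#' coloured over \[0, 1\]) and `global_zscore` (per-embryo z-scores,
#' coloured over the positive value range \[0, 2\]: negative z clips to
#' 0, values above 2 clip to 2). The numeric matrix is the normalized
#' traces row-permuted by [row_order()], without clipping; clipping
#' applies only to the colour mapping.
#'
#' @param traces Long trace tibble.
#' @param labels Optional cluster labels (tibble with embryo_id, cell_id,
#'   cluster), e.g. `tidy()` of a [cluster_traces()] fit; without them
#'   rows are ordered by tissue.
#' @param peaks Optional peak-call tibble supplying first-peak times.
#' @param mode `"per_embryo_minmax"` or `"global_zscore"`.
#' @param value Column passed to [normalize_traces()].
#' @return An object of class `ca_kymograph`: `matrix` (rows = cells in
#'   display order, columns = time points), `rows` (tibble describing
#'   each row), `mode`, `color_range`, `times_s`. Supports `autoplot()`
#'   and [write_kymograph_png()].
#' @export
render_kymograph <- function(traces, labels = NULL, peaks = NULL,
                             mode = c("per_embryo_minmax", "global_zscore"),
                             value = NULL) {
  mode <- match.arg(mode)
  norm_mode <- if (mode == "per_embryo_minmax") "minmax_embryo" else "zscore_embryo"
  nt <- normalize_traces(traces, mode = norm_mode, value = value)
  vecs <- trace_vectors(dplyr::mutate(nt, intensity = .data$normalized))
  meta <- trace_meta(nt)
  X <- do.call(rbind, vecs)
  rownames(X) <- NULL
  times <- sort(unique(nt$time_s))
  if (!is.null(labels)) {
    meta <- dplyr::left_join(meta, labels[, c("embryo_id", "cell_id", "cluster")],
                             by = c("embryo_id", "cell_id"))
  } else if ("tissue" %in% names(meta)) {
    inform("No cluster labels; ordering kymograph rows by tissue.")
    meta$cluster <- as.integer(factor(meta$tissue, levels = ca_tissues()))
  } else {
    meta$cluster <- 1L
  }
  if (!is.null(peaks)) {
    fp <- peaks |>
      dplyr::group_by(.data$embryo_id, .data$cell_id) |>
      dplyr::summarise(first_peak_s = min(.data$time_s), .groups = "drop")
    meta <- dplyr::left_join(meta, fp, by = c("embryo_id", "cell_id"))
  } else {
    meta$first_peak_s <- NA_real_
  }
  ord <- row_order(meta$cluster, meta$first_peak_s)
  structure(list(matrix = X[ord, , drop = FALSE],
                 rows = dplyr::mutate(meta[ord, ], row = dplyr::row_number()),
                 mode = mode,
                 color_range = if (mode == "per_embryo_minmax") c(0, 1) else c(0, 2),
                 times_s = times),
            class = "ca_kymograph")
}

#' Write a kymograph as a PNG image
#'
#' Maps the (clipped) matrix through the magma colour scheme — the
#' yellower the colour, the stronger the intensity — and writes one
#' image pixel per (cell, time point).
#'
#' @param kymo A [render_kymograph()] object.
#' @param path Output PNG path.
#' @param n_colors Colour resolution.
#' @return `path`, invisibly.
#' @export
write_kymograph_png <- function(kymo, path, n_colors = 256) {
  stopifnot(inherits(kymo, "ca_kymograph"))
  rng <- kymo$color_range
  Z <- pmin(pmax(kymo$matrix, rng[1]), rng[2])
  idx <- 1L + as.integer(round((Z - rng[1]) / (rng[2] - rng[1]) * (n_colors - 1)))
  pal <- grDevices::col2rgb(viridisLite::magma(n_colors)) / 255
  img <- array(0, dim = c(nrow(Z), ncol(Z), 3))
  for (ch in 1:3) img[, , ch] <- matrix(pal[ch, idx], nrow(Z), ncol(Z))
  png::writePNG(img, path)
  invisible(path)
}

#' @method autoplot ca_kymograph
#' @export
autoplot.ca_kymograph <- function(object, ...) {
  rng <- object$color_range
  df <- tidyr::expand_grid(row = seq_len(nrow(object$matrix)),
                           col = seq_len(ncol(object$matrix)))
  df$time_s <- object$times_s[df$col]
  df$value <- pmin(pmax(as.vector(t(object$matrix))[
    (df$row - 1) * ncol(object$matrix) + df$col], rng[1]), rng[2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "magma", limits = rng,
                                  name = "normalized\nintensity") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "time (s)", y = "cell (sorted by cluster, first peak)") +
    ggplot2::theme_minimal()
}

#' @export
print.ca_kymograph <- function(x, ...) {
  cat(sprintf("<ca_kymograph> %d cells x %d time points (%s, colour range [%g, %g])\n",
              nrow(x$matrix), ncol(x$matrix), x$mode,
              x$color_range[1], x$color_range[2]))
  invisible(x)
}
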