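#' Normalize traces per embryo
#'
#' Two embryo-wise schemes: `minmax_embryo` maps values through
#' `(x - min)/(max - min)` with the minimum and maximum taken across all
#' traces of the embryo jointly (so every embryo's brightest value maps
#' to 1 with no cross-embryo leakage); `zscore_embryo` centres and scales
#' by the mean and SD of all pooled trace values of the embryo (used for
#' global clustering, where embryos with different dynamic ranges are
#' pooled).
#'
#' @param traces Long trace tibble.
#' @param mode `"minmax_embryo"` or `"zscore_embryo"`.
#' @param value Column to normalize; defaults to `detrended` when present
#'   else `intensity`.
#' @return The tibble with a `normalized` column added; the per-embryo
#'   constants are attached as attribute `"norm_constants"` (a tibble)
#'   for inversion.
#' @export
normalize_traces <- function(traces, mode = c("minmax_embryo", "zscore_embryo"),
                             value = NULL) {
  mode <- match.arg(mode)
  check_trace_tbl(traces, require_tissue = FALSE)
  value <- pick_value_col(traces, value)
  consts <- traces |>
    dplyr::group_by(.data$embryo_id) |>
    dplyr::summarise(center = if (mode == "minmax_embryo") min(.data[[value]])
                     else mean(.data[[value]]),
                     scale = if (mode == "minmax_embryo") {
                       max(.data[[value]]) - min(.data[[value]])
                     } else {
                       sd(.data[[value]])
                     },
                     .groups = "drop")
  if (any(consts$scale == 0 | !is.finite(consts$scale))) {
    abort("Zero dynamic range within an embryo; cannot normalize.",
          class = "embryocal_normalization_error")
  }
  out <- traces |>
    dplyr::left_join(consts, by = "embryo_id") |>
    dplyr::mutate(normalized = (.data[[value]] - .data$center) / .data$scale) |>
    dplyr::select(-"center", -"scale")
  attr(out, "norm_constants") <- consts
  attr(out, "norm_mode") <- mode
  out
}

#' Shift-tolerant trace similarity
#'
#' Similarity between two equal-length traces is the largest positive
#' value of their signal cross-correlation over all integer lags, after
#' mean subtraction and L2 normalisation — tolerant to slight
#' misalignment in peak times. Constant traces have similarity 1 with
#' another constant trace and 0 with any non-constant trace.
#'
#' @param a,b Numeric traces of equal length >= 2.
#' @return Similarity in \[0, 1\].
#' @export
trace_similarity <- function(a, b) {
  if (length(a) != length(b)) abort_input("Traces must have equal length.")
  if (length(a) < 2) abort_input("Traces must have length >= 2.")
  na <- sqrt(sum((a - mean(a))^2))
  nb <- sqrt(sum((b - mean(b))^2))
  if (na == 0 || nb == 0) return(if (na == 0 && nb == 0) 1 else 0)
  x <- (a - mean(a)) / na
  y <- (b - mean(b)) / nb
  n <- length(x)
  best <- 0
  for (lag in -(n - 1):(n - 1)) {
    if (lag >= 0) {
      v <- sum(x[(1 + lag):n] * y[1:(n - lag)])
    } else {
      v <- sum(x[1:(n + lag)] * y[(1 - lag):n])
    }
    if (v > best) best <- v
  }
  min(best, 1)
}

#' Pairwise similarity matrix of a trace set
#'
#' Computes [trace_similarity()] for every cell pair via lag-shifted
#' matrix products. The result is symmetric, clipped at 0, with unit
#' diagonal for non-constant traces.
#'
#' @param traces Long trace tibble (typically normalized; the similarity
#'   itself is invariant to per-trace affine rescaling with positive
#'   gain).
#' @param value Column to use; defaults to `normalized`, `detrended` or
#'   `intensity`, in that order of preference.
#' @param max_lag Maximum lag tried (frames); default all lags.
#' @return A list of class `ca_similarity`: `s` (matrix), `cells`
#'   (tibble aligned with rows).
#' @export
similarity_matrix <- function(traces, value = NULL, max_lag = NULL) {
  check_trace_tbl(traces, require_tissue = FALSE)
  value <- value %||% intersect(c("normalized", "detrended", "intensity"),
                                names(traces))[1]
  vecs <- trace_vectors(dplyr::mutate(traces, intensity = .data[[value]]))
  meta <- trace_meta(traces)
  X <- do.call(rbind, vecs)
  n <- nrow(X)
  T_len <- ncol(X)
  X <- X - rowMeans(X)
  nrm <- sqrt(rowSums(X^2))
  const <- nrm < 1e-12
  nrm[const] <- 1
  X <- X / nrm
  max_lag <- min(max_lag %||% (T_len - 1), T_len - 1)
  S <- X %*% t(X)
  S <- pmax(S, t(S))
  if (max_lag > 0) {
    for (lag in seq_len(max_lag)) {
      P <- X[, (1 + lag):T_len, drop = FALSE] %*% t(X[, 1:(T_len - lag), drop = FALSE])
      S <- pmax(S, P, t(P))
    }
  }
  S <- pmax(S, 0)
  S <- pmin(S, 1)
  S[const, ] <- 0
  S[, const] <- 0
  S[const, const] <- 1
  diag(S) <- 1
  structure(list(s = S, cells = meta), class = "ca_similarity")
}

#' Unbiased clustering of trace dynamics
#'
#' Groups cells by the similarity of their calcium dynamics: traces are
#' normalized per embryo (z-score for global mode, min-max for
#' per-embryo mode), pairwise similarity is the largest positive
#' cross-correlation, and hierarchical density-based clustering is run
#' on the distance `1 - s`. In global mode all embryos are pooled and
#' the outlier class is kept as one additional cluster; per-embryo mode
#' clusters each embryo separately and keeps the native outlier flag.
#' Cluster ids are renumbered in ascending order of the cluster's mean
#' transient count, so the most quiescent group is cluster 0.
#'
#' @param traces Long trace tibble (de-trended column used if present).
#' @param peaks Peak-call tibble used for the transient counts that order
#'   the cluster labels.
#' @param mode `"global"` or `"per_embryo"`.
#' @param min_cluster_size,min_samples Density clustering parameters.
#' @param value Column passed to [normalize_traces()].
#' @param max_lag Maximum cross-correlation lag (frames); default all.
#' @return An object of class `ca_clustering` with `labels` (tibble:
#'   embryo_id, cell_id, cluster, is_outlier), `similarity`, `mode` and
#'   `params`. `tidy()` returns the labels, `glance()` a one-row summary.
#' @export
cluster_traces <- function(traces, peaks, mode = c("global", "per_embryo"),
                           min_cluster_size = 20, min_samples = 10,
                           value = NULL, max_lag = NULL) {
  mode <- match.arg(mode)
  check_trace_tbl(traces, require_tissue = FALSE)
  norm_mode <- if (mode == "global") "zscore_embryo" else "minmax_embryo"
  nt <- normalize_traces(traces, mode = norm_mode, value = value)
  counts <- peaks |>
    dplyr::count(.data$embryo_id, .data$cell_id, name = "n_peaks")
  run_one <- function(tr) {
    sim <- similarity_matrix(tr, value = "normalized", max_lag = max_lag)
    raw <- hdbscan_clusters(1 - sim$s, min_cluster_size = min_cluster_size,
                            min_samples = min_samples)
    list(sim = sim, raw = raw)
  }
  if (mode == "global") {
    res <- run_one(nt)
    lab <- dplyr::mutate(res$sim$cells, raw = res$raw,
                         is_outlier = res$raw == 0L)
    sims <- res$sim
  } else {
    parts <- nt |>
      dplyr::group_by(.data$embryo_id) |>
      dplyr::group_split()
    out <- purrr::map(parts, run_one)
    lab <- purrr::list_rbind(purrr::map(out, function(o) {
      dplyr::mutate(o$sim$cells, raw = o$raw, is_outlier = o$raw == 0L)
    }))
    sims <- purrr::map(out, "sim")
  }
  lab <- dplyr::left_join(lab, counts, by = c("embryo_id", "cell_id")) |>
    dplyr::mutate(n_peaks = dplyr::coalesce(.data$n_peaks, 0L))
  if (mode == "global") {
    # outliers form one additional cluster before activity-ordered relabeling
    key <- lab$raw
    grp_means <- tapply(lab$n_peaks, key, mean)
    ord <- names(sort(grp_means))
    relab <- setNames(seq_along(ord) - 1L, ord)
    lab$cluster <- unname(relab[as.character(key)])
  } else {
    lab$cluster <- NA_integer_
    for (e in unique(lab$embryo_id)) {
      i <- lab$embryo_id == e & !lab$is_outlier
      if (!any(i)) next
      grp_means <- tapply(lab$n_peaks[i], lab$raw[i], mean)
      ord <- names(sort(grp_means))
      relab <- setNames(seq_along(ord) - 1L, ord)
      lab$cluster[i] <- unname(relab[as.character(lab$raw[i])])
    }
  }
  labels <- dplyr::select(lab, dplyr::any_of(c("embryo_id", "cell_id", "tissue")),
                          "cluster", "is_outlier", "n_peaks")
  structure(list(labels = labels, similarity = sims, mode = mode,
                 params = list(min_cluster_size = min_cluster_size,
                               min_samples = min_samples,
                               normalization = norm_mode)),
            class = "ca_clustering")
}

#' @method tidy ca_clustering
#' @export
tidy.ca_clustering <- function(x, ...) x$labels

#' @method glance ca_clustering
#' @export
glance.ca_clustering <- function(x, ...) {
  tibble(mode = x$mode,
         n_cells = nrow(x$labels),
         n_clusters = length(unique(x$labels$cluster[!is.na(x$labels$cluster)])),
         n_outliers = sum(x$labels$is_outlier),
         min_cluster_size = x$params$min_cluster_size,
         min_samples = x$params$min_samples,
         normalization = x$params$normalization)
}

#' @export
print.ca_clustering <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<ca_clustering> %s mode: %d cells in %d group(s), %d outlier(s)\n",
              g$mode, g$n_cells, g$n_clusters, g$n_outliers))
  print(dplyr::count(x$labels, .data$cluster, .data$is_outlier))
  invisible(x)
}
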