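#' Total transient count per embryo timelapse
#'
#' Sums detected transient peaks over every cell of each embryo — the
#' whole-embryo readout used for short (2-min, 10-s interval) inhibitor
#' timelapses. Those 13-frame recordings are short relative to the
#' classifier's 35-frame window (edge padding would dominate), so the
#' deterministic reference detector is the default here; a trained
#' classifier can be supplied explicitly.
#'
#' @param traces De-trended long trace tibble (any number of embryos).
#' @param method `"oracle"` (default) or `"cnn"`.
#' @param model `ca_detector`, required for the cnn method. A model
#'   trained at a different frame interval than the traces triggers a
#'   warning and falls back to the oracle detector.
#' @param trained_interval_s Frame interval the model was trained at
#'   (used only for the mismatch check).
#' @param ... Passed to [detect_transients()].
#' @return Tibble: embryo_id, total_transients.
#' @export
count_transients <- function(traces, method = c("oracle", "cnn"), model = NULL,
                             trained_interval_s = NULL, ...) {
  method <- match.arg(method)
  check_trace_tbl(traces, require_tissue = FALSE)
  if (method == "cnn" && !is.null(trained_interval_s)) {
    interval <- infer_interval(traces)
    if (abs(interval - trained_interval_s) > 1e-9) {
      warn("Frame interval differs from the detector's training interval; using the oracle detector.")
      method <- "oracle"
    }
  }
  calls <- detect_transients(traces, method = method, model = model, ...)
  base <- dplyr::distinct(traces, .data$embryo_id)
  tallies <- if (nrow(calls) > 0) {
    dplyr::count(calls, .data$embryo_id, name = "total_transients")
  } else {
    tibble(embryo_id = character(0), total_transients = integer(0))
  }
  dplyr::left_join(base, tallies, by = "embryo_id") |>
    dplyr::mutate(total_transients = dplyr::coalesce(.data$total_transients, 0L))
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' The group-comparison procedure used for all multi-condition
#' summaries: a one-way ANOVA F-test across groups, followed by Tukey's
#' honestly-significant-difference test (studentized range distribution)
#' on every group pair.
#'
#' @param records Data frame with the response and a grouping column.
#' @param response,group Column names (strings).
#' @return An object of class `ca_comparison`: `anova` (F, df, p),
#'   `tukey` (pairwise differences with adjusted p-values),
#'   `group_means`. `tidy()` returns the pairwise table, `glance()` the
#'   ANOVA row.
#' @export
compare_groups <- function(records, response = "total_transients",
                           group = "condition") {
  if (!all(c(response, group) %in% names(records))) {
    abort_input("`records` must contain the response and group columns.")
  }
  records <- dplyr::rename(records, .y = dplyr::all_of(response),
                           .g = dplyr::all_of(group))
  records$.g <- factor(records$.g)
  sizes <- table(records$.g)
  if (length(sizes) < 2) abort_input("Need at least 2 groups.")
  if (any(sizes < 2)) abort_input("Every group needs at least 2 observations.")
  wvar <- tapply(records$.y, records$.g, stats::var)
  if (all(wvar == 0)) {
    abort("Zero within-group variance in every group; ANOVA is degenerate.",
          class = "embryocal_degenerate_error")
  }
  fit <- aov(.y ~ .g, data = records)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$`.g`
  pairs <- rownames(tk)
  means <- records |>
    dplyr::group_by(.data$.g) |>
    dplyr::summarise(mean = mean(.data$.y), n = dplyr::n(), .groups = "drop") |>
    dplyr::rename(!!group := ".g")
  structure(list(
    anova = tibble(statistic = an$`F value`[1], df_between = an$Df[1],
                   df_within = an$Df[2], p_value = an$`Pr(>F)`[1]),
    tukey = tibble(pair = pairs, diff = tk[, "diff"], lwr = tk[, "lwr"],
                   upr = tk[, "upr"], p_adj = tk[, "p adj"]),
    group_means = means,
    response = response, group = group),
    class = "ca_comparison")
}

#' @method tidy ca_comparison
#' @export
tidy.ca_comparison <- function(x, ...) x$tukey

#' @method glance ca_comparison
#' @export
glance.ca_comparison <- function(x, ...) x$anova

#' @export
print.ca_comparison <- function(x, ...) {
  cat(sprintf("<ca_comparison> one-way ANOVA on %s by %s: F(%d, %d) = %.3f, p = %.4g\n",
              x$response, x$group, x$anova$df_between, x$anova$df_within,
              x$anova$statistic, x$anova$p_value))
  print(x$tukey)
  invisible(x)
}

#' Score DVE migration from a centroid track
#'
#' Given the track of the DVE reporter-domain centroid in oriented
#' embryo coordinates (long axis vertical, ExE up, so the distal pole
#' points down from the embryo centre), the outcome is called migrated
#' when the final angular displacement of the centroid from the distal
#' pole reaches the threshold (>= convention at the boundary).
#'
#' @param track Tibble with `x_um`, `y_um` centroid positions over time
#'   (>= 2 points), relative to the embryo centre.
#' @param angle_threshold_deg Migration call threshold, degrees.
#' @return Tibble: migrated, angular_displacement_deg.
#' @export
score_migration <- function(track, angle_threshold_deg = 30) {
  if (nrow(track) < 2) abort("Track needs at least 2 points.",
                             class = "embryocal_scoring_error")
  last <- track[nrow(track), ]
  v <- c(last$x_um, last$y_um)
  if (sqrt(sum(v^2)) == 0) {
    return(tibble(migrated = FALSE, angular_displacement_deg = 0))
  }
  # distal pole direction is (0, -1) in oriented coordinates
  ang <- acos(pmin(pmax(sum(v * c(0, -1)) / sqrt(sum(v^2)), -1), 1)) * 180 / pi
  # >= at the boundary, robust to floating-point rounding of the angle
  tibble(migrated = ang - angle_threshold_deg >= -1e-9,
         angular_displacement_deg = ang)
}

#' Condition-level summaries of inhibitor experiments
#'
#' Summarises migration outcomes per condition (n, migrated count,
#' percentage) and/or transient-count records per condition and
#' timepoint (mean count, with per-embryo deltas from baseline for the
#' paired design).
#'
#' @param outcomes Optional tibble: embryo_id, condition, migrated.
#' @param records Optional tibble: embryo_id, condition, timepoint,
#'   total_transients (timepoints include `"baseline"`).
#' @return A list with `migration` and/or `counts` tibbles (only the
#'   ones requested).
#' @export
summarize_rates <- function(outcomes = NULL, records = NULL) {
  out <- list()
  if (!is.null(outcomes)) {
    if (nrow(outcomes) == 0) {
      warn("No outcomes; migration summary omitted.")
    } else {
      out$migration <- outcomes |>
        dplyr::group_by(.data$condition) |>
        dplyr::summarise(n = dplyr::n(), k = sum(.data$migrated),
                         percent_migrated = percent(sum(.data$migrated), dplyr::n()),
                         .groups = "drop")
    }
  }
  if (!is.null(records)) {
    empty <- records |>
      dplyr::count(.data$condition) |>
      dplyr::filter(.data$n == 0)
    if (nrow(empty) > 0) warn("Empty condition(s) omitted from the summary.")
    out$counts <- records |>
      dplyr::group_by(.data$condition, .data$timepoint) |>
      dplyr::summarise(n = dplyr::n(), mean_count = mean(.data$total_transients),
                       .groups = "drop")
    base <- records |>
      dplyr::filter(.data$timepoint == "baseline") |>
      dplyr::select("embryo_id", "condition", baseline = "total_transients")
    out$deltas <- records |>
      dplyr::filter(.data$timepoint != "baseline") |>
      dplyr::inner_join(base, by = c("embryo_id", "condition")) |>
      dplyr::mutate(delta = .data$total_transients - .data$baseline)
  }
  out
}
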