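#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Quick line plot of a handful of traces
#'
#' @param traces Long trace tibble.
#' @param n Maximum number of cells to show.
#' @param value Column to plot (defaults to `detrended` when present).
#' @return A ggplot object, one facet per cell.
#' @export
plot_traces <- function(traces, n = 12, value = NULL) {
  check_trace_tbl(traces, require_tissue = FALSE)
  value <- pick_value_col(traces, value)
  keep <- utils::head(dplyr::distinct(traces, .data$embryo_id, .data$cell_id), n)
  df <- dplyr::semi_join(traces, keep, by = c("embryo_id", "cell_id"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data[[value]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~ paste(embryo_id, cell_id, sep = "/"), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = value) +
    ggplot2::theme_minimal()
}
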