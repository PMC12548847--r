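#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   across left_join bind_rows n distinct pull rename count
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map2 pmap map_dbl map_int map_lgl imap list_rbind
#' @importFrom stats rpois runif rnorm median mad sd aov TukeyHSD ptukey
#'   prcomp quantile coef lm fft setNames na.omit
#' @importFrom utils head modifyList packageVersion type.convert
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes
NULL

# Tissue vocabulary of the egg-cylinder stage: pluripotent epiblast,
# extraembryonic ectoderm (ExE), and the visceral endoderm split into the
# part overlying the epiblast (emVE) and the part overlying the ExE (exVE).
ca_tissues <- function() c("epiblast", "ExE", "emVE", "exVE")

abort_config <- function(msg) abort(msg, class = "embryocal_config_error")
abort_input  <- function(msg) abort(msg, class = "embryocal_input_error")
abort_format <- function(msg) abort(msg, class = "embryocal_format_error")

#' Percentage of a count, at one-decimal precision
#'
#' Computes `100 * k / n` rounded to one decimal place, the convention used
#' for all reported rates (active-cell fractions, migration rates).
#'
#' @param k Number of events (0 <= k <= n).
#' @param n Total count (> 0).
#' @return Percentage on the 0--100 scale, rounded to one decimal.
#' @examples
#' percent(32, 323)
#' @export
percent <- function(k, n) {
  if (any(n <= 0)) abort_input("`n` must be positive; percentage undefined for n = 0.")
  if (any(k < 0) || any(k > n)) abort_input("`k` must satisfy 0 <= k <= n.")
  round(100 * k / n, 1)
}

# Validate the long trace-table contract shared by every stage.
check_trace_tbl <- function(traces, require_tissue = TRUE) {
  needed <- c("embryo_id", "cell_id", "frame", "time_s", "intensity")
  if (require_tissue) needed <- c(needed[1:2], "tissue", needed[-(1:2)])
  missing <- setdiff(needed, names(traces))
  if (length(missing) > 0) {
    abort_format(paste0("Trace table is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  invisible(traces)
}

# Split a long trace table into a named list of intensity vectors keyed by
# "embryo_id/cell_id", each sorted by frame. Used by per-trace kernels.
trace_vectors <- function(traces) {
  check_trace_tbl(traces, require_tissue = FALSE)
  traces <- dplyr::arrange(traces, .data$embryo_id, .data$cell_id, .data$frame)
  key <- paste(traces$embryo_id, traces$cell_id, sep = "/")
  split(traces$intensity, factor(key, levels = unique(key)))
}

# Per-trace metadata (one row per cell) aligned with trace_vectors() order.
trace_meta <- function(traces) {
  cols <- intersect(c("embryo_id", "cell_id", "tissue"), names(traces))
  dplyr::distinct(traces[, cols, drop = FALSE])
}

# Derive a stream-specific 32-bit seed from a master seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}
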