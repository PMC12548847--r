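#' Asymmetric least squares (ALS) baseline of a trace
#'
#' Fits a smooth baseline z to an intensity series y by iteratively
#' reweighted penalised least squares: minimise
#' \deqn{\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z_i)^2}
#' with asymmetric weights \eqn{w_i = p} where \eqn{y_i > z_i} and
#' \eqn{1 - p} otherwise, so transient peaks are largely ignored while
#' slow trends (drift, bleaching) are followed. The penalised system is
#' solved with a sparse banded Cholesky factorisation.
#'
#' Defaults (`lambda = 1e3`, `p = 0.01`) are tuned so that a transient of
#' ~20 s width sampled at 5 s survives de-trending while drifts with
#' periods of five minutes or more are removed.
#'
#' @param y Numeric intensity series, length >= 5, finite.
#' @param lambda Smoothness penalty (> 0).
#' @param p Asymmetry parameter in (0, 1).
#' @param max_iter Maximum reweighting iterations.
#' @param tol Convergence tolerance on the weight vector.
#' @return Numeric baseline, same length as `y`.
#' @export
als_baseline <- function(y, lambda = 1e3, p = 0.01, max_iter = 10, tol = 0) {
  if (length(y) < 5) abort_input("Trace must have at least 5 samples.")
  if (any(!is.finite(y))) abort_input("Trace contains NaN/Inf values.")
  if (lambda <= 0 || p <= 0 || p >= 1 || max_iter < 1) {
    abort_config("Need lambda > 0, 0 < p < 1, max_iter >= 1.")
  }
  m <- length(y)
  D <- Matrix::bandSparse(m - 2, m, k = 0:2,
                          diagonals = list(rep(1, m - 2), rep(-2, m - 2),
                                           rep(1, m - 2)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- y
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    A <- DtD + Matrix::Diagonal(m, w)
    z <- as.numeric(Matrix::solve(A, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (max(abs(w_new - w)) <= tol) {
      converged <- TRUE
      w <- w_new
      break
    }
    w <- w_new
  }
  if (!converged && max_iter > 1) {
    warn("ALS weights did not stabilise within `max_iter`; returning last iterate.")
  }
  z
}

#' De-trend an intensity series
#'
#' Subtracts the [als_baseline()] from the trace (the default) or divides
#' by it (a dF/F-style option); the subtractive residual is the tested
#' path since downstream intensity comparisons are in arbitrary units.
#'
#' @inheritParams als_baseline
#' @param method `"subtract"` (residual, default) or `"divide"`
#'   ((y - z)/z).
#' @return Numeric residual series.
#' @export
detrend_trace <- function(y, lambda = 1e3, p = 0.01, max_iter = 10,
                          method = c("subtract", "divide")) {
  method <- match.arg(method)
  z <- als_baseline(y, lambda = lambda, p = p, max_iter = max_iter)
  if (method == "subtract") y - z else (y - z) / z
}

#' De-trend every trace of a long trace table
#'
#' Applies [detrend_trace()] cell by cell and returns the table with two
#' added columns: `baseline` (the fitted ALS baseline) and `detrended`
#' (the residual). Downstream stages use `detrended` when present.
#'
#' @param traces A long trace tibble.
#' @inheritParams detrend_trace
#' @return The input tibble plus `baseline` and `detrended` columns.
#' @export
detrend_traces <- function(traces, lambda = 1e3, p = 0.01, max_iter = 10,
                           method = c("subtract", "divide")) {
  method <- match.arg(method)
  check_trace_tbl(traces, require_tissue = FALSE)
  traces |>
    dplyr::arrange(.data$embryo_id, .data$cell_id, .data$frame) |>
    dplyr::group_by(.data$embryo_id, .data$cell_id) |>
    dplyr::mutate(baseline = als_baseline(.data$intensity, lambda = lambda,
                                          p = p, max_iter = max_iter),
                  detrended = if (method == "subtract") {
                    .data$intensity - .data$baseline
                  } else {
                    (.data$intensity - .data$baseline) / .data$baseline
                  }) |>
    dplyr::ungroup()
}

# Column downstream stages should read: `detrended` when present,
# otherwise raw `intensity`.
pick_value_col <- function(traces, value = NULL) {
  value %||% if ("detrended" %in% names(traces)) "detrended" else "intensity"
}
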