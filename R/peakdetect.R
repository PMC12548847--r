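#' Idealized probability trace
#'
#' The training target for the peak classifier: a binary vector the same
#' length as the trace that is nonzero only at transient peak frames.
#'
#' @param peak_frames 0-based peak frame indices, unique, within range.
#' @param n_frames Trace length.
#' @return Integer vector of 0/1, length `n_frames`.
#' @export
make_idealized_trace <- function(peak_frames, n_frames) {
  if (anyDuplicated(peak_frames)) abort_input("Duplicated peak frame.")
  if (length(peak_frames) > 0 &&
      (any(peak_frames < 0) || any(peak_frames >= n_frames))) {
    abort_input("Peak frame outside the trace.")
  }
  out <- integer(n_frames)
  out[peak_frames + 1L] <- 1L
  out
}

# Local maxima (strict on the left, non-strict on the right so plateaus
# yield their first frame). Returns 1-based indices.
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

# Topographic prominence of a peak at index i (1-based).
peak_prominence <- function(y, i) {
  left <- y[seq_len(i - 1)]
  right <- y[seq(i + 1, length(y))]
  higher_l <- which(left > y[i])
  higher_r <- which(right > y[i])
  lmin <- if (length(higher_l) > 0) min(y[(max(higher_l) + 1):i]) else min(c(left, y[i]))
  rmin <- if (length(higher_r) > 0) min(y[i:(i + min(higher_r) - 1)]) else min(c(right, y[i]))
  y[i] - max(lmin, rmin)
}

# Greedy min-separation suppression: keep the higher call when two are
# closer than `min_separation` frames.
enforce_separation <- function(idx, height, min_separation) {
  if (length(idx) <= 1) return(idx)
  ord <- order(height, decreasing = TRUE)
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(idx[i] - kept) >= min_separation)) kept <- c(kept, idx[i])
  }
  sort(kept)
}

#' Deterministic reference peak detector
#'
#' Finds local maxima of a de-trended trace whose robust z-score
#' (median/MAD scaling) exceeds `z_thresh` and whose topographic
#' prominence exceeds `min_prominence`, then greedily keeps the higher
#' peak whenever two calls fall closer than `min_separation` frames.
#' Because a genuine GCaMP transient (~20 s wide) spans several frames
#' at 5-s sampling, a candidate must by default also have at least one
#' adjacent frame above half the z threshold (`min_support = 1`), which
#' rejects single-frame shot-noise spikes. Serves as the reference
#' standard that the trained classifier is benchmarked against, and as
#' the label source for synthetic training.
#'
#' @param y De-trended intensity series.
#' @param frame_interval_s Frame interval, seconds.
#' @param z_thresh Robust z-score threshold, SD units.
#' @param min_prominence Minimum topographic prominence, AU. The default
#'   (`NULL`) requires `z_thresh` robust SDs of prominence, which
#'   suppresses noise bumps riding on the decay tail of a real
#'   transient; pass 0 to disable.
#' @param min_separation Minimum distance between calls, frames.
#' @param min_support Number of adjacent frames required above
#'   `z_thresh / 2` (0 disables the support check).
#' @return Tibble with `frame` (0-based), `time_s`, `score` (robust z).
#' @export
oracle_detect <- function(y, frame_interval_s = 5, z_thresh = 3,
                          min_prominence = NULL, min_separation = 3,
                          min_support = 1) {
  med <- median(y)
  # noise scale floored at 1% of the dynamic range: in a noise-free
  # trace the robust scale collapses and numerical de-trending ripple
  # would otherwise be called as peaks
  s <- max(robust_scale(y), 0.01 * diff(range(y)))
  if (!is.finite(s) || s == 0) {
    return(tibble(frame = integer(0), time_s = numeric(0), score = numeric(0)))
  }
  min_prominence <- min_prominence %||% (z_thresh * s)
  z <- (y - med) / s
  n <- length(y)
  cand <- local_maxima(y)
  cand <- cand[z[cand] > z_thresh]
  if (min_support > 0 && length(cand) > 0) {
    ok <- vapply(cand, function(i) {
      nb <- c(if (i > 1) z[i - 1] else -Inf, if (i < n) z[i + 1] else -Inf)
      sum(nb > z_thresh / 2) >= min_support
    }, TRUE)
    cand <- cand[ok]
  }
  if (min_prominence > 0 && length(cand) > 0) {
    prom <- vapply(cand, function(i) peak_prominence(y, i), 1)
    cand <- cand[prom > min_prominence]
  }
  keep <- enforce_separation(cand, y[cand], min_separation)
  if (length(keep) > 0) {
    # apex refinement: noise shifts the raw argmax by a frame; the
    # maximum of a 3-point moving average within +-1 frame is a more
    # stable apex estimate and keeps calls on the frame grid
    yp <- c(y[1], y, y[n])
    ys <- (yp[1:n] + yp[2:(n + 1)] + yp[3:(n + 2)]) / 3
    keep <- vapply(keep, function(i) {
      idx <- max(1, i - 1):min(n, i + 1)
      idx[which.max(ys[idx])]
    }, 1L)
    keep <- sort(unique(keep))
    keep <- enforce_separation(keep, y[keep], min_separation)
  }
  tibble(frame = keep - 1L, time_s = (keep - 1L) * frame_interval_s,
         score = z[keep])
}

# Robust per-trace noise scale: MAD of first differences / sqrt(2).
# Estimating the noise from frame-to-frame differences is insensitive to
# the fraction of the trace occupied by transients (which inflates a
# plain trace MAD); falls back to trace MAD/SD for degenerate input.
robust_scale <- function(y) {
  s <- mad(diff(y)) / sqrt(2)
  if (s == 0 || !is.finite(s)) s <- mad(y)
  if (s == 0 || !is.finite(s)) s <- sd(y)
  if (s == 0 || !is.finite(s)) s <- 1
  s
}

# Edge-reflected sliding windows centred on every frame: n x window.
trace_windows <- function(y, window) {
  h <- (window - 1) %/% 2
  n <- length(y)
  left <- if (h > 0) y[pmin(n, (h + 1):2)] else numeric(0)
  right <- if (h > 0) y[pmax(1, (n - 1):(n - h))] else numeric(0)
  yp <- c(left, y, right)
  idx <- outer(seq_len(n), 0:(window - 1), `+`)
  matrix(yp[idx], n, window)
}

#' Train the transient peak classifier
#'
#' Trains a small 1D convolutional network to score, for a symmetrical
#' temporal window of `window` frames, the probability that a transient
#' peak sits at the window centre. Positive examples are windows centred
#' within +/-1 frame of a labelled peak; negatives are sampled from the
#' remaining frames at `negative_ratio` per positive. Traces are scaled
#' to robust noise units (see the noise-scale note in [oracle_detect()])
#' before windowing. Training is deterministic under a fixed seed.
#'
#' @param traces De-trended long trace tibble (needs >= 3 labelled traces).
#' @param labels Peak-frame table: `embryo_id`, `cell_id`, `frame`
#'   (0-based peak frames, as in [make_idealized_trace()]).
#' @param window Window length N, odd; default 35 frames.
#' @param seed Integer seed.
#' @param epochs,batch_size,lr Optimiser settings (Adam, binary
#'   cross-entropy).
#' @param negative_ratio Negatives sampled per positive (default 6:
#'   background windows vastly outnumber peak windows at detection
#'   time, so a moderate excess of negatives keeps the false-call rate
#'   down without hurting sensitivity).
#' @return An object of class `ca_detector`.
#' @export
train_detector <- function(traces, labels, window = 35, seed = 1L,
                           epochs = 40, batch_size = 256, lr = 1e-2,
                           negative_ratio = 6) {
  if (window %% 2 != 1) abort_config("`window` must be odd.")
  check_trace_tbl(traces, require_tissue = FALSE)
  value <- pick_value_col(traces)
  vecs <- trace_vectors(dplyr::mutate(traces, intensity = .data[[value]]))
  meta <- trace_meta(traces)
  if (length(vecs) < 3) abort_input("Need at least 3 labelled traces to train.")
  lab_key <- paste(labels$embryo_id, labels$cell_id, sep = "/")
  if (nrow(labels) == 0) abort("No positive labels supplied.",
                               class = "embryocal_training_error")
  withr::with_seed(as.integer(seed), {
    Xs <- list(); ys <- list()
    keys <- paste(meta$embryo_id, meta$cell_id, sep = "/")
    for (k in seq_along(vecs)) {
      y <- vecs[[k]] / robust_scale(vecs[[k]])
      W <- trace_windows(y, window)
      pk <- labels$frame[lab_key == keys[k]] + 1L
      lab <- rep(0L, length(y))
      for (p in pk) {
        lab[max(1, p - 1):min(length(y), p + 1)] <- 1L
      }
      pos <- which(lab == 1L)
      neg <- which(lab == 0L)
      Xs[[k]] <- W[c(pos, neg), , drop = FALSE]
      ys[[k]] <- c(rep(1L, length(pos)), rep(0L, length(neg)))
    }
    X <- do.call(rbind, Xs)
    yy <- unlist(ys)
    pos_i <- which(yy == 1L)
    neg_i <- which(yy == 0L)
    if (length(pos_i) == 0) abort("Labels contain no positive windows.",
                                  class = "embryocal_training_error")
    n_neg <- min(length(neg_i), ceiling(negative_ratio * length(pos_i)))
    neg_i <- sample(neg_i, n_neg)
    sel <- c(pos_i, neg_i)
    X <- X[sel, , drop = FALSE]
    yy <- yy[sel]
    net <- cnn_init(window)
    fit <- cnn_train(net, X, yy, epochs = epochs, batch_size = batch_size, lr = lr)
    structure(list(window = window, net = fit$net,
                   training = list(seed = as.integer(seed), epochs = epochs,
                                   lr = lr, batch_size = batch_size,
                                   final_loss = fit$final_loss,
                                   n_pos = length(pos_i), n_neg = n_neg,
                                   n_traces = length(vecs))),
              class = "ca_detector")
  })
}

#' Per-frame peak probability of a trace
#'
#' Applies the trained classifier to edge-reflected sliding windows,
#' giving one probability per frame.
#'
#' @param model A [train_detector()] model.
#' @param y De-trended intensity series.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict_peak_prob <- function(model, y) {
  stopifnot(inherits(model, "ca_detector"))
  W <- trace_windows(y / robust_scale(y), model$window)
  cnn_forward(model$net, W)$prob
}

#' Detect transient peaks with the trained classifier
#'
#' Computes the per-frame probability trace for every cell, then calls
#' local maxima of the probability above `prob_thresh`, enforcing
#' `min_separation` greedily by probability.
#'
#' @param model A [train_detector()] model.
#' @param traces De-trended long trace tibble.
#' @param prob_thresh Probability threshold for a call.
#' @param min_separation Minimum distance between calls, frames.
#' @return Peak-call tibble: embryo_id, cell_id, frame, time_s, score.
#' @export
detect_peaks <- function(model, traces, prob_thresh = 0.5, min_separation = 3) {
  stopifnot(inherits(model, "ca_detector"))
  check_trace_tbl(traces, require_tissue = FALSE)
  value <- pick_value_col(traces)
  dt <- dplyr::arrange(traces, .data$embryo_id, .data$cell_id, .data$frame)
  interval <- infer_interval(dt)
  vecs <- trace_vectors(dplyr::mutate(dt, intensity = .data[[value]]))
  meta <- trace_meta(dt)
  calls <- purrr::imap(vecs, function(y, key) {
    prob <- predict_peak_prob(model, y)
    n <- length(y)
    cand <- local_maxima(prob)
    cand <- cand[prob[cand] >= prob_thresh]
    keep <- enforce_separation(cand, prob[cand], min_separation)
    if (length(keep) > 0) {
      # the probability trace plateaus around an event; place the call
      # on the trace apex with the same 3-point refinement the
      # reference detector uses, so both paths share one convention
      yp <- c(y[1], y, y[n])
      ys <- (yp[1:n] + yp[2:(n + 1)] + yp[3:(n + 2)]) / 3
      keep <- vapply(keep, function(i) {
        idx <- max(1, i - 1):min(n, i + 1)
        idx[which.max(ys[idx])]
      }, 1L)
      keep <- sort(unique(keep))
      keep <- enforce_separation(keep, y[keep], min_separation)
    }
    tibble(frame = keep - 1L, time_s = (keep - 1L) * interval,
           score = prob[keep])
  })
  attach_meta(calls, meta)
}

#' Detect transients across a trace table (oracle or classifier path)
#'
#' One front door for both detectors, so every downstream stage can take
#' either interchangeably.
#'
#' @param traces De-trended long trace tibble.
#' @param method `"oracle"` (deterministic reference) or `"cnn"`.
#' @param model Required when `method = "cnn"`.
#' @param ... Passed to [oracle_detect()] or [detect_peaks()].
#' @return Peak-call tibble: embryo_id, cell_id, frame, time_s, score.
#' @export
detect_transients <- function(traces, method = c("oracle", "cnn"),
                              model = NULL, ...) {
  method <- match.arg(method)
  if (method == "cnn") {
    if (is.null(model)) abort_input("`model` is required for the cnn method.")
    return(detect_peaks(model, traces, ...))
  }
  check_trace_tbl(traces, require_tissue = FALSE)
  value <- pick_value_col(traces)
  dt <- dplyr::arrange(traces, .data$embryo_id, .data$cell_id, .data$frame)
  interval <- infer_interval(dt)
  vecs <- trace_vectors(dplyr::mutate(dt, intensity = .data[[value]]))
  meta <- trace_meta(dt)
  calls <- purrr::map(vecs, function(y) {
    oracle_detect(y, frame_interval_s = interval, ...)
  })
  attach_meta(calls, meta)
}

# Frame interval from the time stamps of a long trace table.
infer_interval <- function(traces) {
  tt <- sort(unique(traces$time_s))
  if (length(tt) < 2) return(5)
  diff(tt)[1]
}

attach_meta <- function(call_list, meta) {
  out <- purrr::imap(call_list, function(df, key) {
    parts <- strsplit(key, "/", fixed = TRUE)[[1]]
    dplyr::mutate(df, embryo_id = parts[1],
                  cell_id = utils::type.convert(parts[2], as.is = TRUE),
                  .before = 1)
  })
  res <- purrr::list_rbind(out)
  if (nrow(res) > 0 && "tissue" %in% names(meta)) {
    res <- dplyr::left_join(res, meta, by = c("embryo_id", "cell_id")) |>
      dplyr::relocate("tissue", .after = "cell_id")
  }
  res
}

#' Event-level detection accuracy against ground truth
#'
#' Matches each call to at most one truth event within a frame tolerance
#' (greedy, nearest first); unmatched calls are false positives and
#' unmatched events false negatives.
#'
#' @param calls Peak-call tibble (embryo_id, cell_id, frame).
#' @param truth Truth tibble (embryo_id, cell_id, and `frame`,
#'   `peak_time_s` or `event_time_s` — in that order of preference; the
#'   generators record `peak_time_s`, the time the transient kernel
#'   actually peaks).
#' @param frame_interval_s Used to convert truth times to frames.
#' @param tol_frames Matching tolerance, frames.
#' @return One-row tibble: n_true, n_called, tp, fp, fn, precision,
#'   recall, f1.
#' @export
event_match_stats <- function(calls, truth, frame_interval_s = 5, tol_frames = 1) {
  if (!"frame" %in% names(truth)) {
    tcol <- if ("peak_time_s" %in% names(truth)) "peak_time_s" else "event_time_s"
    truth <- dplyr::mutate(truth,
                           frame = as.integer(round(.data[[tcol]] / frame_interval_s)))
  }
  key <- function(d) paste(d$embryo_id, d$cell_id, sep = "/")
  tp <- 0L
  truth_split <- split(truth$frame, key(truth))
  calls_split <- split(calls$frame, key(calls))
  for (k in names(truth_split)) {
    tf <- truth_split[[k]]
    cf <- calls_split[[k]] %||% integer(0)
    used <- rep(FALSE, length(tf))
    for (f in sort(cf)) {
      d <- abs(tf - f)
      d[used] <- Inf
      j <- which.min(d)
      if (length(j) == 1 && is.finite(d[j]) && d[j] <= tol_frames) {
        used[j] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  n_true <- nrow(truth)
  n_called <- nrow(calls)
  fp <- n_called - tp
  fn <- n_true - tp
  precision <- if (n_called > 0) tp / n_called else NA_real_
  recall <- if (n_true > 0) tp / n_true else NA_real_
  f1 <- if (isTRUE(precision + recall > 0)) 2 * precision * recall / (precision + recall) else 0
  tibble(n_true = n_true, n_called = n_called, tp = tp, fp = fp, fn = fn,
         precision = precision, recall = recall, f1 = f1)
}

#' @method tidy ca_detector
#' @export
tidy.ca_detector <- function(x, ...) {
  tibble(layer = c("conv1", "conv2", "dense"),
         kernel = c(x$net$k1, x$net$k2, NA_integer_),
         channels_out = c(x$net$c1, x$net$c2, 1L),
         n_parameters = c(length(x$net$W1) + length(x$net$b1),
                          length(x$net$W2) + length(x$net$b2),
                          length(x$net$W3) + 1L))
}

#' @method glance ca_detector
#' @export
glance.ca_detector <- function(x, ...) {
  tibble(window = x$window, n_traces = x$training$n_traces,
         n_pos = x$training$n_pos, n_neg = x$training$n_neg,
         epochs = x$training$epochs, final_loss = x$training$final_loss,
         seed = x$training$seed)
}

#' @export
print.ca_detector <- function(x, ...) {
  cat("<ca_detector> 1D CNN transient peak classifier\n")
  cat(sprintf("  window: %d frames | trained on %d traces (%d pos / %d neg windows)\n",
              x$window, x$training$n_traces, x$training$n_pos, x$training$n_neg))
  cat(sprintf("  final training loss: %.4f (seed %d, %d epochs)\n",
              x$training$final_loss, x$training$seed, x$training$epochs))
  invisible(x)
}
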