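#' Binarize a calcium-signal movie
#'
#' Thresholds the movie at mean + 0.5 SD, both computed over all pixels
#' and frames of the signal channel, to keep only clear calcium signal
#' before motion tracking.
#'
#' @param movie A [ca_movie()].
#' @return Logical array the shape of `movie$frames`; attribute
#'   `"threshold"` records the cut.
#' @export
binarize_signal <- function(movie) {
  stopifnot(inherits(movie, "ca_movie"))
  s <- sd(movie$frames)
  thr <- mean(movie$frames) + 0.5 * s
  if (s == 0) warn("Constant movie; binarization yields an empty mask.")
  mask <- movie$frames > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Orientation transform from cell centroids
#'
#' Rotates an embryo so its long axis (first principal component of the
#' cell centroids) is vertical, choosing between the two vertical
#' alternatives so that the ExE centroid mean lies above (larger y than)
#' the non-ExE mean — the "long axis vertical, ExE top" convention that
#' makes embryos comparable.
#'
#' @param centroids Tibble with `x_um`, `y_um`, `tissue` (>= 3
#'   non-collinear points, >= 1 ExE cell).
#' @return An object of class `ca_orientation`: `angle_rad`, rotation
#'   matrix `R`, and the rotated centroids. Apply to new points with
#'   [orient_points()].
#' @export
orient_vertical <- function(centroids) {
  if (nrow(centroids) < 3) abort_input("Need at least 3 centroids.")
  if (!any(centroids$tissue == "ExE")) abort_input("Need at least one ExE centroid.")
  xy <- as.matrix(centroids[, c("x_um", "y_um")])
  pc <- prcomp(xy, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (ev[2] == 0 || ev[1] / ev[2] < 1.05) {
    abort("Centroid cloud is isotropic; orientation is ambiguous.",
          class = "embryocal_orientation_error")
  }
  v <- pc$rotation[, 1]               # first principal axis
  theta <- atan2(v[1], v[2])          # rotate v onto +y
  rot <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  ctr <- colMeans(xy)
  for (a in c(theta, theta + pi)) {
    R <- rot(a)
    rxy <- sweep(xy, 2, ctr) %*% t(R)
    is_exe <- centroids$tissue == "ExE"
    if (mean(rxy[is_exe, 2]) > mean(rxy[!is_exe, 2])) {
      out <- centroids
      out$x_um <- rxy[, 1]
      out$y_um <- rxy[, 2]
      return(structure(list(angle_rad = atan2(sin(a), cos(a)), R = R,
                            center = ctr, centroids = out),
                       class = "ca_orientation"))
    }
  }
  abort("Could not orient: ExE and non-ExE centroids coincide.",
        class = "embryocal_orientation_error")
}

#' @rdname orient_vertical
#' @param transform A `ca_orientation`.
#' @param xy Two-column matrix of points (same units as the centroids).
#' @export
orient_points <- function(transform, xy) {
  stopifnot(inherits(transform, "ca_orientation"))
  sweep(as.matrix(xy), 2, transform$center) %*% t(transform$R)
}

# Block-matching displacement of one patch between two frames, by
# zero-normalized cross-correlation (invariant to the gain/offset
# changes a blinking reporter produces). Returns c(dx, dy) in pixels
# (x = column axis, y = row axis) with sub-pixel parabolic refinement.
# Matches below `min_ncc` are rejected as structureless (flat or pure
# noise patches correlate weakly everywhere), so intensity changes
# without coherent motion yield no flow vector.
block_match <- function(f0, f1, cy, cx, patch = 4, radius = 5,
                        min_ncc = 0.5) {
  ny <- nrow(f0); nx <- ncol(f0)
  ys <- max(1, cy - patch):min(ny, cy + patch)
  xs <- max(1, cx - patch):min(nx, cx + patch)
  tmpl <- f0[ys, xs, drop = FALSE]
  tmpl <- tmpl - mean(tmpl)
  tn <- sqrt(sum(tmpl^2))
  if (tn < 1e-12) return(c(NA_real_, NA_real_))
  tmpl <- tmpl / tn
  dys <- -radius:radius
  dxs <- -radius:radius
  ncc <- matrix(-Inf, length(dys), length(dxs))
  for (iy in seq_along(dys)) for (ix in seq_along(dxs)) {
    y2 <- ys + dys[iy]; x2 <- xs + dxs[ix]
    if (min(y2) < 1 || max(y2) > ny || min(x2) < 1 || max(x2) > nx) next
    p <- f1[y2, x2, drop = FALSE]
    p <- p - mean(p)
    pn <- sqrt(sum(p^2))
    if (pn < 1e-12) next
    ncc[iy, ix] <- sum(tmpl * p) / pn
  }
  if (!any(is.finite(ncc))) return(c(NA_real_, NA_real_))
  best <- max(ncc)
  if (best < min_ncc) return(c(NA_real_, NA_real_))
  cand <- which(ncc >= best - 1e-12, arr.ind = TRUE)
  mag <- dys[cand[, 1]]^2 + dxs[cand[, 2]]^2
  pick <- cand[which.min(mag), ]
  dy <- dys[pick[1]]; dx <- dxs[pick[2]]
  # parabolic sub-pixel refinement along each axis (maximising NCC)
  refine <- function(vm, v0, vp) {
    den <- 2 * v0 - vm - vp
    if (!is.finite(vm) || !is.finite(vp) || den <= 0) return(0)
    max(-0.5, min(0.5, 0.5 * (vp - vm) / den))
  }
  sub_y <- if (pick[1] > 1 && pick[1] < length(dys)) {
    refine(ncc[pick[1] - 1, pick[2]], ncc[pick[1], pick[2]], ncc[pick[1] + 1, pick[2]])
  } else 0
  sub_x <- if (pick[2] > 1 && pick[2] < length(dxs)) {
    refine(ncc[pick[1], pick[2] - 1], ncc[pick[1], pick[2]], ncc[pick[1], pick[2] + 1])
  } else 0
  c(dx + sub_x, dy + sub_y)
}

# One Lucas-Kanade step (single window, no pyramid): solves the 2x2
# normal equations of the brightness-constancy constraint on a patch.
lk_match <- function(f0, f1, cy, cx, patch = 4, iters = 3) {
  ny <- nrow(f0); nx <- ncol(f0)
  ys <- max(2, cy - patch):min(ny - 1, cy + patch)
  xs <- max(2, cx - patch):min(nx - 1, cx + patch)
  Iy <- (f0[ys + 1, xs, drop = FALSE] - f0[ys - 1, xs, drop = FALSE]) / 2
  Ix <- (f0[ys, xs + 1, drop = FALSE] - f0[ys, xs - 1, drop = FALSE]) / 2
  A <- cbind(as.vector(Ix), as.vector(Iy))
  AtA <- crossprod(A)
  if (abs(det(AtA)) < 1e-8) return(c(NA_real_, NA_real_))
  d <- c(0, 0)
  for (it in seq_len(iters)) {
    w <- round(d)  # integer warp actually applied
    y2 <- ys + w[2]; x2 <- xs + w[1]
    if (min(y2) < 1 || max(y2) > ny || min(x2) < 1 || max(x2) > nx) break
    It <- as.vector(f1[y2, x2, drop = FALSE] - f0[ys, xs, drop = FALSE])
    step <- as.numeric(solve(AtA, -crossprod(A, It)))
    d_new <- w + step  # step is the residual relative to the warp
    if (sum((d_new - d)^2) < 1e-6) { d <- d_new; break }
    d <- d_new
  }
  d
}

#' Superpixel signal-flow tracking
#'
#' Motion-sensing superpixel tracking of the calcium signal: regular
#' grid seeds are advected frame to frame by a local displacement
#' estimate (dense block matching by default, or an iterative
#' Lucas-Kanade solve for the second backend), restricted to regions
#' where the binarized signal is present. The mean temporal flow map is
#' the per-seed average displacement over the movie.
#'
#' @param movie A [ca_movie()].
#' @param mask Logical mask from [binarize_signal()]; computed from the
#'   movie when `NULL`.
#' @param n_superpixels Approximate number of grid seeds (>= 4).
#' @param method `"block"` (robust to large displacements, default) or
#'   `"lk"` (gradient-based Lucas-Kanade).
#' @param patch Half-width of the matching patch, pixels.
#' @param radius Search radius for block matching, pixels/frame.
#' @return An object of class `ca_flow`: `tracks` (tibble: seed, frame,
#'   x, y, dx, dy, valid), `mean_flow` (per-seed mean displacement,
#'   pixels/frame), and parameters.
#' @export
track_flow <- function(movie, mask = NULL, n_superpixels = 200,
                       method = c("block", "lk"), patch = 4, radius = 5) {
  method <- match.arg(method)
  stopifnot(inherits(movie, "ca_movie"))
  if (n_superpixels < 4) abort_config("`n_superpixels` must be >= 4.")
  mask <- mask %||% binarize_signal(movie)
  dm <- dim(movie$frames)
  n_frames <- dm[1]; ny <- dm[2]; nx <- dm[3]
  if (!any(mask)) {
    warn("Empty signal mask; flow field is empty.")
    return(structure(list(tracks = tibble(), mean_flow = tibble(),
                          params = list(method = method)), class = "ca_flow"))
  }
  aspect <- ny / nx
  rows <- max(2L, round(sqrt(n_superpixels * aspect)))
  cols <- max(2L, round(n_superpixels / rows))
  seed_y <- (seq_len(rows) - 0.5) / rows * ny
  seed_x <- (seq_len(cols) - 0.5) / cols * nx
  seeds <- tidyr::expand_grid(y0 = seed_y, x0 = seed_x)
  pos_x <- seeds$x0; pos_y <- seeds$y0
  match_fun <- if (method == "block") {
    function(f0, f1, cy, cx) block_match(f0, f1, cy, cx, patch, radius)
  } else {
    function(f0, f1, cy, cx) lk_match(f0, f1, cy, cx, patch)
  }
  recs <- vector("list", n_frames - 1)
  for (t in seq_len(n_frames - 1)) {
    f0 <- movie$frames[t, , ]
    f1 <- movie$frames[t + 1, , ]
    m0 <- mask[t, , ]
    dx <- dy <- rep(NA_real_, nrow(seeds))
    for (s in seq_len(nrow(seeds))) {
      cy <- as.integer(round(pos_y[s])); cx <- as.integer(round(pos_x[s]))
      if (cy < 1 || cy > ny || cx < 1 || cx > nx) next
      ys <- max(1, cy - patch):min(ny, cy + patch)
      xs <- max(1, cx - patch):min(nx, cx + patch)
      if (!any(m0[ys, xs])) next
      d <- match_fun(f0, f1, cy, cx)
      if (any(is.na(d))) next
      dx[s] <- d[1]; dy[s] <- d[2]
    }
    recs[[t]] <- tibble(seed = seq_len(nrow(seeds)), frame = t - 1L,
                        x = pos_x, y = pos_y, dx = dx, dy = dy,
                        valid = !is.na(dx))
    adv <- !is.na(dx)
    pos_x[adv] <- pmin(pmax(pos_x[adv] + dx[adv], 1), nx)
    pos_y[adv] <- pmin(pmax(pos_y[adv] + dy[adv], 1), ny)
  }
  tracks <- purrr::list_rbind(recs)
  mean_flow <- tracks |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$seed) |>
    dplyr::summarise(x0 = dplyr::first(.data$x), y0 = dplyr::first(.data$y),
                     mean_dx = mean(.data$dx), mean_dy = mean(.data$dy),
                     n_frames = dplyr::n(), .groups = "drop")
  structure(list(tracks = tracks, mean_flow = mean_flow,
                 params = list(method = method, patch = patch, radius = radius,
                               n_superpixels = n_superpixels)),
            class = "ca_flow")
}

#' @method autoplot ca_flow
#' @export
autoplot.ca_flow <- function(object, scale = 3, ...) {
  ggplot2::ggplot(object$mean_flow,
                  ggplot2::aes(x = .data$x0, y = .data$y0)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$x0 + scale * .data$mean_dx,
                                       yend = .data$y0 + scale * .data$mean_dy),
                          arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm"))) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = "Mean temporal signal flow") +
    ggplot2::theme_minimal()
}

#' Sub-pixel front positions of an advancing signal
#'
#' For each frame, averages intensity across the axis perpendicular to
#' the wave, then localizes the half-max crossing of the advancing edge
#' by linear interpolation — the position (in micrometres from the
#' leading image edge) where the profile falls through half of the
#' movie-wide intensity range.
#'
#' @param movie A [ca_movie()].
#' @param axis `"y"` (front advances down rows, e.g. apical to basal) or
#'   `"x"`.
#' @param level Crossing level; default midway between the movie's
#'   minimum and maximum.
#' @return Tibble: frame, time_s, position_um (NA when no crossing).
#' @export
front_positions <- function(movie, axis = c("y", "x"), level = NULL) {
  axis <- match.arg(axis)
  stopifnot(inherits(movie, "ca_movie"))
  level <- level %||% ((max(movie$frames) + min(movie$frames)) / 2)
  n_frames <- dim(movie$frames)[1]
  out <- purrr::map(seq_len(n_frames), function(t) {
    fr <- movie$frames[t, , ]
    p <- if (axis == "y") rowMeans(fr) else colMeans(fr)
    above <- p >= level
    pos <- NA_real_
    if (any(above) && !all(above)) {
      i <- max(which(above))
      if (i < length(p)) {
        frac <- (p[i] - level) / (p[i] - p[i + 1])
        pos <- (i - 0.5 + frac) * movie$pixel_size_um
      }
    }
    tibble(frame = t - 1L, time_s = (t - 1L) * movie$frame_interval_s,
           position_um = pos)
  })
  purrr::list_rbind(out)
}

#' Estimate wave speed and direction from front positions
#'
#' Least-squares regression of front position (micrometres) on time
#' (seconds); the speed is the absolute slope and the direction label
#' follows the slope sign along the chosen anatomical axis. Duration is
#' the time between the first and last localized front.
#'
#' @param front Tibble with `time_s` and `position_um` (NAs dropped);
#'   needs >= 3 localized points.
#' @param axis `"apical_basal"` (positions increase from the apical
#'   face) or `"proximal_distal"` (positions increase distally).
#' @return An object of class `ca_wave` (also a tibble row):
#'   speed_um_s, direction, duration_s, n_points, r_squared.
#' @export
estimate_wave <- function(front, axis = c("apical_basal", "proximal_distal")) {
  axis <- match.arg(axis)
  front <- dplyr::filter(front, !is.na(.data$position_um))
  if (nrow(front) < 3) {
    abort("Need at least 3 localized front positions.",
          class = "embryocal_estimation_error")
  }
  fit <- lm(position_um ~ time_s, data = front)
  slope <- coef(fit)[["time_s"]]
  ss_tot <- sum((front$position_um - mean(front$position_um))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  labels <- if (axis == "apical_basal") {
    c(forward = "apical_basal", backward = "basal_apical")
  } else {
    c(forward = "distal", backward = "proximal")
  }
  direction <- if (slope > 0) labels[["forward"]]
               else if (slope < 0) labels[["backward"]] else "mixed"
  out <- tibble(speed_um_s = abs(slope), direction = direction,
                duration_s = diff(range(front$time_s)),
                n_points = nrow(front),
                r_squared = r2)
  class(out) <- c("ca_wave", class(out))
  out
}

#' Wave speed straight from a movie
#'
#' Convenience pipeline: binarize the movie, localize the half-max front
#' per frame along the axis, and regress position on time.
#'
#' @inheritParams front_positions
#' @inheritParams estimate_wave
#' @return A [estimate_wave()] result.
#' @export
wave_speed_from_movie <- function(movie, axis = c("y", "x"),
                                  direction_axis = c("apical_basal",
                                                     "proximal_distal")) {
  axis <- match.arg(axis)
  direction_axis <- match.arg(direction_axis)
  mask <- binarize_signal(movie)
  front <- front_positions(movie, axis = axis,
                           level = attr(mask, "threshold"))
  estimate_wave(front, axis = direction_axis)
}
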