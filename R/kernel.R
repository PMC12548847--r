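#' Calcium transient kernel
#'
#' The fluorescence signature of a single cytosolic calcium transient is
#' modelled as a product of an exponential rise and an exponential decay,
#' \deqn{f(t) = A \, (1 - e^{-t/\tau_r}) \, e^{-t/\tau_d}, \quad t \ge 0,}
#' rescaled so that its maximum equals the requested amplitude. The
#' user-facing width parameter is the full width at half maximum (FWHM);
#' the decay constant \eqn{\tau_d} is solved numerically (bisection,
#' tolerance 1e-3 s) so the kernel's FWHM matches it.
#'
#' @param fwhm_s Full width at half maximum of the kernel, seconds.
#' @param rise_s Rise time constant \eqn{\tau_r}, seconds.
#' @return A list with `tau_r`, `tau_d`, `t_peak` (time of maximum, s) and
#'   `fwhm_s` (the achieved width).
#' @export
calibrate_kernel <- function(fwhm_s, rise_s = 2) {
  if (fwhm_s <= 0 || rise_s <= 0) abort_config("Kernel widths must be positive.")
  f <- function(tau_d) kernel_fwhm(rise_s, tau_d) - fwhm_s
  lo <- fwhm_s / 50
  hi <- fwhm_s * 5
  while (f(lo) > 0 && lo > 1e-6) lo <- lo / 2
  while (f(hi) < 0 && hi < 1e6) hi <- hi * 2
  while (hi - lo > 1e-3) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  tau_d <- (lo + hi) / 2
  list(tau_r = rise_s, tau_d = tau_d,
       t_peak = kernel_tpeak(rise_s, tau_d),
       fwhm_s = kernel_fwhm(rise_s, tau_d))
}

# Unnormalized kernel shape.
kernel_shape <- function(t, tau_r, tau_d) {
  ifelse(t < 0, 0, (1 - exp(-t / tau_r)) * exp(-t / tau_d))
}

# Closed-form location of the maximum: f'(t)=0 at
# t* = tau_r * log(1 + tau_d/tau_r).
kernel_tpeak <- function(tau_r, tau_d) tau_r * log(1 + tau_d / tau_r)

kernel_fwhm <- function(tau_r, tau_d) {
  tp <- kernel_tpeak(tau_r, tau_d)
  pk <- kernel_shape(tp, tau_r, tau_d)
  g <- function(t) kernel_shape(t, tau_r, tau_d) - pk / 2
  t_up <- stats::uniroot(g, c(0, tp), tol = 1e-7)$root
  hi <- tp + tau_d
  while (g(hi) > 0) hi <- hi + tau_d
  t_dn <- stats::uniroot(g, c(tp, hi), tol = 1e-7)$root
  t_dn - t_up
}

#' Evaluate a calibrated transient kernel
#'
#' @param t Times (s) relative to event onset; values before onset give 0.
#' @param kernel A list from [calibrate_kernel()].
#' @param amplitude Peak height, arbitrary units.
#' @return Numeric vector of kernel values.
#' @export
eval_kernel <- function(t, kernel, amplitude = 1) {
  pk <- kernel_shape(kernel$t_peak, kernel$tau_r, kernel$tau_d)
  amplitude * kernel_shape(t, kernel$tau_r, kernel$tau_d) / pk
}
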