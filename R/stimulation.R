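## TENS pulse synthesis and network response.
##
## A periodic trapezoidal pulse (square wave with linear ramps) is expanded
## into its Fourier series, the network is evaluated at every harmonic
## frequency, the response is formed per harmonic in the frequency domain
## (Ohm's law / impedance dividers) and the per-layer time-domain traces are
## reconstructed over one period by inverse FFT.

#' Stimulation pulse specification
#'
#' Periodic square pulse with linear edge ramps (trapezoid): the pulse rises
#' over `ramp_us`, holds the intensity until `width_ms`, and falls over
#' `ramp_us` (so the 50\%-amplitude width equals `width_ms`).
#'
#' @param mode `"voltage"` (intensity in V) or `"current"` (intensity in A).
#' @param intensity pulse amplitude, nonzero (1 V or 1e-3 A are typical
#'   stimulation defaults).
#' @param width_ms pulse width W, ms; duty cycle `W*F` must be < 1.
#' @param freq_hz repetition (stimulation) frequency F, Hz.
#' @param ramp_us edge ramp time, microseconds; must be < W.
#' @return object of class `pulse_spec`.
#' @export
pulse_spec <- function(mode = c("voltage", "current"), intensity = 1,
                       width_ms = 3, freq_hz = 10, ramp_us = 1) {
  mode <- match.arg(mode)
  if (intensity == 0) stop("intensity must be nonzero", call. = FALSE)
  .tpb_stopifnot_scalar(width_ms, "width_ms")
  .tpb_stopifnot_scalar(freq_hz, "freq_hz")
  .tpb_stopifnot_scalar(ramp_us, "ramp_us")
  if (width_ms * 1e-3 * freq_hz >= 1)
    stop(sprintf("duty cycle W*F = %.3g must be < 1", width_ms * 1e-3 * freq_hz),
         call. = FALSE)
  if (ramp_us * 1e-6 >= width_ms * 1e-3)
    stop("ramp time must be shorter than the pulse width", call. = FALSE)
  structure(list(mode = mode, intensity = intensity, width_ms = width_ms,
                 freq_hz = freq_hz, ramp_us = ramp_us, shape = "square"),
            class = "pulse_spec")
}

#' @export
print.pulse_spec <- function(x, ...) {
  cat(sprintf("<pulse_spec> %s %g %s / width %g ms / %g Hz / ramp %g us\n",
              x$shape, x$intensity, if (x$mode == "voltage") "V" else "A",
              x$width_ms, x$freq_hz, x$ramp_us))
  invisible(x)
}

#' Ideal time-domain pulse waveform
#'
#' Samples the periodic trapezoid directly (independent of the Fourier
#' synthesis; used as a reconstruction oracle and for plotting).
#'
#' @param spec a [pulse_spec()].
#' @param t time points, s.
#' @return numeric vector.
#' @export
pulse_waveform <- function(spec, t) {
  T <- 1 / spec$freq_hz
  W <- spec$width_ms * 1e-3
  tr <- spec$ramp_us * 1e-6
  tt <- t %% T
  a <- numeric(length(tt))
  a[tt < tr] <- tt[tt < tr] / tr
  a[tt >= tr & tt < W] <- 1
  i <- tt >= W & tt < W + tr
  a[i] <- 1 - (tt[i] - W) / tr
  spec$intensity * a
}

#' Fourier-series harmonics of the pulse
#'
#' Closed-form complex Fourier coefficients \eqn{c_k} of the periodic
#' trapezoid (rect of width W convolved with a normalized rect of width
#' `ramp_us`):
#' \deqn{c_0 = A\,W F, \qquad
#'   c_k = \frac{A}{T}\,
#'   \frac{(1 - e^{-j\omega_k W})(1 - e^{-j\omega_k t_r})}{(j\omega_k)^2 t_r}}
#' with \eqn{\omega_k = 2\pi k F}.  The k = 0 term is the waveform's time
#' average and amplitudes decay as \eqn{O(1/k)} (then \eqn{O(1/k^2)} beyond
#' the ramp corner).
#'
#' @param spec a [pulse_spec()].
#' @param n_harmonics number of harmonics K (\eqn{\ge 1}).
#' @return object of class `harmonic_spectrum`: integer `k` (0..K),
#'   `frequency` (Hz) and complex `coef`.
#' @export
pulse_harmonics <- function(spec, n_harmonics = 4096) {
  stopifnot(inherits(spec, "pulse_spec"))
  if (n_harmonics < 1) stop("n_harmonics must be >= 1", call. = FALSE)
  K <- as.integer(n_harmonics)
  A <- spec$intensity
  F <- spec$freq_hz
  W <- spec$width_ms * 1e-3
  tr <- spec$ramp_us * 1e-6
  k <- 0:K
  w <- 2 * pi * k * F
  jw <- complex(real = 0, imaginary = 1) * w
  ck <- complex(length.out = K + 1L)
  ck[1] <- A * W * F
  ck[-1] <- A * F * (1 - exp(-jw[-1] * W)) * (1 - exp(-jw[-1] * tr)) /
    (jw[-1]^2 * tr)
  structure(list(k = k, frequency = k * F, coef = ck, spec = spec),
            class = "harmonic_spectrum")
}

## inverse real FFT of harmonics c_0..c_K onto N = 2K uniform samples of one
## period; x[n] = sum_k c_k e^{j 2 pi k n / N} + c.c. (Nyquist bin real)
.harmonics_to_time <- function(coef) {
  K <- length(coef) - 1L
  N <- 2L * K
  z <- complex(length.out = N)
  z[1] <- coef[1]
  if (K > 1L) {
    z[2:K] <- coef[2:K]
    z[N:(N - K + 2L)] <- Conj(coef[2:K])
  }
  z[K + 1L] <- complex(real = Re(coef[K + 1L]))
  Re(stats::fft(z, inverse = TRUE))
}

#' Time-domain response of a layered body to a stimulation pulse
#'
#' Per harmonic k the network impedance is evaluated at \eqn{kF} (the DC bin
#' through the resistive limit).  In voltage mode the current harmonic is
#' \eqn{I_k = V_k/Z_{tot}} and each layer's voltage drop is
#' \eqn{V_k Z_{layer}/Z_{tot}}; in current mode \eqn{V_k = I_k Z_{tot}}.
#' One period of time-domain traces is reconstructed by inverse FFT on
#' \eqn{2K} uniform samples.
#'
#' The per-layer voltage decomposition assumes a series (all-SPC) topology;
#' if any interface classifies PPC a warning is raised and the per-layer
#' columns describe the parallel partial elements instead.
#'
#' @param body a [layered_body()].
#' @param spec a [pulse_spec()].
#' @param n_harmonics harmonic count K; truncated (with a warning) to keep
#'   all harmonic frequencies within the validity range of tabulated
#'   materials.
#' @param coeffs IF coefficient list.
#' @param scale IF unit-calibration scale; defaults to the body's.
#' @return object of class `response_traces`: `time` (s, one period),
#'   `source` (reconstructed stimulus), `current` (total current, A),
#'   `v_layers` (matrix of per-layer voltages, V), `v_gel` (gel drop, V),
#'   `v_total` (voltage across body + gel), plus `mode`, `spec`,
#'   `n_harmonics`.
#' @export
respond <- function(body, spec, n_harmonics = 4096,
                    coeffs = default_if_coefficients(), scale = NULL) {
  stopifnot(inherits(body, "layered_body"), inherits(spec, "pulse_spec"))
  fmax <- min(vapply(body$layers,
                     function(l) material_frequency_range(l$material)[2],
                     numeric(1)))
  K <- as.integer(n_harmonics)
  if (is.finite(fmax) && K * spec$freq_hz > fmax) {
    K <- max(1L, as.integer(floor(fmax / spec$freq_hz)))
    warning(sprintf("harmonics truncated to K = %d to stay within the material validity range (%.3g Hz)",
                    K, fmax), call. = FALSE)
  }
  hs <- pulse_harmonics(spec, K)
  sp <- build_network(body, hs$frequency, coeffs, scale)
  zt <- sp$z_total
  zl <- sp$z_layers
  if (any(sp$classes == "PPC", na.rm = TRUE))
    warning("PPC interface present: per-layer columns are parallel partial elements, not series voltage drops",
            call. = FALSE)
  c0_bad <- !is.finite(Mod(zt[1]))
  if (spec$mode == "current" && c0_bad)
    stop("singular DC response in current mode: no conductive path through the stack",
         call. = FALSE)
  n_layers <- ncol(zl)
  if (spec$mode == "voltage") {
    ik <- hs$coef / zt
    ratio <- zl / zt                      # layer divider per harmonic
    gel_ratio <- sp$gel_ohms / zt
    if (c0_bad) {                         # DC blocked: no current, divider
      ik[1] <- 0                          # taken at the fundamental
      ratio[1, ] <- ratio[2, ]
      gel_ratio[1] <- gel_ratio[2]
    }
    vk <- sweep(ratio, 1, hs$coef, `*`)
    vgel <- hs$coef * gel_ratio
    source <- .harmonics_to_time(hs$coef)
    current <- .harmonics_to_time(ik)
    v_total <- source
  } else {
    vk <- sweep(zl, 1, hs$coef, `*`)
    vgel <- hs$coef * sp$gel_ohms
    source <- .harmonics_to_time(hs$coef)
    current <- source
    v_total <- .harmonics_to_time(hs$coef * zt)
  }
  v_layers <- vapply(seq_len(n_layers), function(i) .harmonics_to_time(vk[, i]),
                     numeric(2L * K))
  colnames(v_layers) <- colnames(zl)
  N <- 2L * K
  structure(list(time = (0:(N - 1L)) / (N * spec$freq_hz),
                 source = source, current = current,
                 v_layers = v_layers, v_gel = .harmonics_to_time(vgel),
                 v_total = if (spec$mode == "voltage") v_total
                           else .harmonics_to_time(hs$coef * zt),
                 mode = spec$mode, spec = spec, n_harmonics = K,
                 harmonics = hs),
            class = "response_traces")
}

#' @export
print.response_traces <- function(x, ...) {
  cat(sprintf("<response_traces> %s-driven, %d harmonics, %d time samples over %g s\n",
              x$mode, x$n_harmonics, length(x$time), 1 / x$spec$freq_hz))
  cat(sprintf("  peak |current| = %.4g A; peak |v_total| = %.4g V\n",
              max(abs(x$current)), max(abs(x$v_total))))
  invisible(x)
}

#' @export
plot.response_traces <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  graphics::plot(x$time * 1e3, x$current * 1e6, type = "l",
                 xlab = "time [ms]", ylab = "current [uA]", ...)
  graphics::matplot(x$time * 1e3, x$v_layers, type = "l",
                    xlab = "time [ms]", ylab = "layer voltage [V]", ...)
  graphics::legend("topright", legend = colnames(x$v_layers),
                   col = seq_len(ncol(x$v_layers)), lty = seq_len(ncol(x$v_layers)),
                   bty = "n")
  invisible(x)
}

#' Pulse-parameter dose map
#'
#' Runs [respond()] over a grid of pulse widths and stimulation frequencies
#' and reports one amplitude number per cell: for a voltage-driven template
#' the total-current amplitude, for a current-driven template the
#' source-voltage (compliance) amplitude.  The default metric
#' `"mean_pulse"` averages the trace over the pulse's on-interval (a
#' charge-per-width measure): through an RC-type load it decreases as the
#' pulse widens, which is the behaviour pulse-width dose sweeps describe.
#' `"peak"` (peak absolute value within the period) is the alternative; for
#' pulses longer than the network time constant it saturates at the inrush
#' amplitude set by the high-frequency impedance, nearly width-independent.
#'
#' @param body a [layered_body()].
#' @param spec_template a [pulse_spec()] providing mode, intensity and ramp.
#' @param widths_ms pulse-width values, ms (stimulation sweeps typically
#'   span 0.05 to 5 ms).
#' @param freqs_hz stimulation-frequency values, Hz (typically 1 to 300 Hz).
#' @param metric `"mean_pulse"` (default) or `"peak"`.
#' @param n_harmonics harmonics per cell.
#' @param ... passed to [respond()].
#' @return data.frame of class `dose_map` with columns `width_ms`,
#'   `freq_hz`, `value` (A or V).  Grid cells violating duty < 1 are skipped
#'   with a warning and reported as `NA`.
#' @export
dose_map <- function(body, spec_template = pulse_spec(),
                     widths_ms = exp(seq(log(0.05), log(5), length.out = 7)),
                     freqs_hz = exp(seq(log(1), log(300), length.out = 7)),
                     metric = c("mean_pulse", "peak"), n_harmonics = 4096, ...) {
  metric <- match.arg(metric)
  if (length(widths_ms) == 0L || length(freqs_hz) == 0L)
    stop("empty dose grid", call. = FALSE)
  g <- expand.grid(width_ms = widths_ms, freq_hz = freqs_hz)
  vals <- rep(NA_real_, nrow(g))
  skipped <- 0L
  for (i in seq_len(nrow(g))) {
    if (g$width_ms[i] * 1e-3 * g$freq_hz[i] >= 1) { skipped <- skipped + 1L; next }
    sp <- spec_template
    sp$width_ms <- g$width_ms[i]
    sp$freq_hz <- g$freq_hz[i]
    tr <- respond(body, sp, n_harmonics = n_harmonics, ...)
    trace <- if (sp$mode == "voltage") tr$current else tr$v_total
    vals[i] <- if (metric == "peak") max(abs(trace)) else
      mean(trace[tr$time < sp$width_ms * 1e-3])
  }
  if (skipped > 0L)
    warning(sprintf("%d grid cell(s) skipped: duty cycle >= 1", skipped), call. = FALSE)
  structure(data.frame(g, value = vals),
            metric = metric, mode = spec_template$mode,
            class = c("dose_map", "data.frame"))
}

#' @export
plot.dose_map <- function(x, ...) {
  w <- sort(unique(x$width_ms)); f <- sort(unique(x$freq_hz))
  m <- matrix(x$value[order(x$freq_hz, x$width_ms)], length(w), length(f))
  graphics::image(log10(w), log10(f), m,
                  xlab = "log10 width [ms]", ylab = "log10 frequency [Hz]",
                  main = sprintf("%s %s", attr(x, "metric"),
                                 if (attr(x, "mode") == "voltage") "current [A]" else "voltage [V]"),
                  ...)
  invisible(x)
}
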