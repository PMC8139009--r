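## Complex-permittivity algebra and the complex-capacitor <-> parallel-RC <->
## impedance correspondence, plus dispersive material models.
##
## Convention (declared once, used everywhere): e^{+j omega t} time dependence,
##   eps* = eps - j sigma/omega        [F/m, absolute]
## so Im(eps*) <= 0 for passive media.  The "complex conductivity"
##   kappa*(omega) = j omega eps* = sigma + j omega eps
## is the admittance-form twin of eps*; it stays finite at DC, which is why
## all network math is done in kappa rather than eps*.

#' Complex permittivity from real permittivity and conductivity
#'
#' Evaluates \eqn{\varepsilon^* = \varepsilon - j\sigma/\omega} at the given
#' frequency.  Inputs are vectorized and recycled.
#'
#' @param eps_rel real relative permittivity (dimensionless, \eqn{\ge 0}).
#' @param sigma conductivity in S/m (\eqn{\ge 0}).
#' @param frequency frequency in Hz, must be > 0 (the conduction term
#'   diverges at DC; use [complex_conductivity()] for DC-safe algebra).
#' @param relative if `TRUE` return the relative complex permittivity
#'   \eqn{\varepsilon^*/\varepsilon_0}; otherwise absolute F/m.
#' @return complex vector.
#' @export
#' @examples
#' complex_permittivity(50, 0.1, 100)
complex_permittivity <- function(eps_rel, sigma, frequency, relative = FALSE) {
  if (any(frequency <= 0)) stop("frequency must be > 0", call. = FALSE)
  if (any(sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  w <- 2 * pi * frequency
  out <- complex(real = EPS0 * eps_rel, imaginary = -sigma / w)
  if (relative) out / EPS0 else out
}

#' Convert between absolute and relative complex permittivity
#'
#' @param eps complex permittivity (absolute F/m for `rel_permittivity`,
#'   relative for `abs_permittivity`).
#' @return complex vector.
#' @export
rel_permittivity <- function(eps) eps / EPS0

#' @rdname rel_permittivity
#' @export
abs_permittivity <- function(eps) eps * EPS0

## ---------------------------------------------------------------------------
## Dispersive materials

new_material <- function(name, source, table = NULL, eps_inf = NULL,
                         terms = NULL, sigma_static = NULL, f_max_hz = Inf,
                         flags = character()) {
  structure(list(name = name, source = source, table = table,
                 eps_inf = eps_inf, terms = terms,
                 sigma_static = sigma_static, f_max_hz = f_max_hz,
                 flags = flags),
            class = "dispersive_material")
}

#' Tabulated dispersive material
#'
#' A material defined by a frequency grid with real relative permittivity and
#' conductivity at each point.  Evaluation between grid points is linear in
#' log-frequency; evaluation outside the grid is an error (no silent
#' extrapolation).
#'
#' @param name material name.
#' @param frequency_hz strictly increasing grid, all > 0.
#' @param eps_rel_real real relative permittivity at each grid point.
#' @param sigma_s_per_m conductivity (S/m) at each grid point.
#' @param check_physical enforce \eqn{\sigma \ge 0} and \eqn{\varepsilon_r \ge 1}
#'   at every grid point.  Materials recovered from measured impedance may
#'   legitimately violate these (see [permittivity_from_spectrum()]), in which
#'   case the violations are recorded in the material's `flags` instead.
#' @return object of class `dispersive_material`.
#' @export
tabulated_material <- function(name, frequency_hz, eps_rel_real, sigma_s_per_m,
                               check_physical = TRUE) {
  n <- length(frequency_hz)
  if (n < 2L) stop("tabulated material needs at least two grid points", call. = FALSE)
  if (length(eps_rel_real) != n || length(sigma_s_per_m) != n)
    stop("frequency grid and property columns must have equal length", call. = FALSE)
  if (any(frequency_hz <= 0)) stop("all grid frequencies must be > 0", call. = FALSE)
  if (any(diff(frequency_hz) <= 0))
    stop("frequency grid must be strictly increasing", call. = FALSE)
  flags <- character()
  if (any(sigma_s_per_m < 0)) {
    if (check_physical) stop("sigma must be >= 0 at every grid point", call. = FALSE)
    flags <- c(flags, "negative_sigma")
  }
  if (any(eps_rel_real < 1)) {
    if (check_physical) stop("eps_rel_real must be >= 1 at every grid point", call. = FALSE)
    flags <- c(flags, "eps_rel_below_one")
  }
  tab <- data.frame(frequency_hz = as.numeric(frequency_hz),
                    eps_rel_real = as.numeric(eps_rel_real),
                    sigma_s_per_m = as.numeric(sigma_s_per_m))
  new_material(name, "tabulated", table = tab, flags = flags)
}

#' Parametric (Cole-Cole style) dispersive material
#'
#' Relative complex permittivity
#' \deqn{\varepsilon_r^*(\omega) = \varepsilon_\infty +
#'   \sum_k \frac{\Delta\varepsilon_k}{1 + (j\omega\tau_k)^{1-\alpha_k}}
#'   - j\frac{\sigma_s}{\omega\varepsilon_0}}
#' with amplitude \eqn{\Delta\varepsilon_k}, relaxation time \eqn{\tau_k} (s)
#' and broadening exponent \eqn{\alpha_k \in [0,1)} per dispersion term, plus
#' a static conductivity.  Valid at any frequency > 0 (and at DC through
#' [complex_conductivity()]).
#'
#' @param name material name.
#' @param eps_inf high-frequency relative permittivity (\eqn{\ge 1}).
#' @param terms list of dispersion terms, each a list or named vector with
#'   `delta_eps`, `tau_s`, `alpha`.
#' @param sigma_static static conductivity, S/m (\eqn{\ge 0}).
#' @param f_max_hz optional upper validity bound, Hz; evaluation above it is
#'   an error, mirroring the no-extrapolation rule for tabulated grids.
#' @return object of class `dispersive_material`.
#' @export
parametric_material <- function(name, eps_inf, terms = list(), sigma_static = 0,
                                f_max_hz = Inf) {
  if (eps_inf < 1) stop("eps_inf must be >= 1", call. = FALSE)
  if (sigma_static < 0) stop("sigma_static must be >= 0", call. = FALSE)
  terms <- lapply(terms, function(tr) {
    tr <- as.list(tr)
    for (f in c("delta_eps", "tau_s", "alpha"))
      if (is.null(tr[[f]])) stop("dispersion term missing field '", f, "'", call. = FALSE)
    if (tr$delta_eps < 0 || tr$tau_s <= 0 || tr$alpha < 0 || tr$alpha >= 1)
      stop("dispersion term out of range: need delta_eps >= 0, tau_s > 0, 0 <= alpha < 1",
           call. = FALSE)
    tr[c("delta_eps", "tau_s", "alpha")]
  })
  new_material(name, "parametric", eps_inf = eps_inf, terms = terms,
               sigma_static = sigma_static, f_max_hz = f_max_hz)
}

#' @export
print.dispersive_material <- function(x, ...) {
  cat("<dispersive_material> ", x$name, " [", x$source, "]\n", sep = "")
  if (x$source == "tabulated") {
    rng <- range(x$table$frequency_hz)
    cat(sprintf("  grid: %d points, %.3g Hz to %.3g Hz\n", nrow(x$table), rng[1], rng[2]))
  } else {
    cat(sprintf("  eps_inf = %g, %d dispersion term(s), sigma_static = %g S/m\n",
                x$eps_inf, length(x$terms), x$sigma_static))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Validity range of a material
#'
#' @param material a `dispersive_material`.
#' @return numeric length-2 vector (Hz); parametric materials are valid on
#'   `c(0, Inf)`.
#' @export
material_frequency_range <- function(material) {
  stopifnot(inherits(material, "dispersive_material"))
  if (material$source == "tabulated") range(material$table$frequency_hz)
  else c(0, material$f_max_hz %||% Inf)
}

## interpolate eps_r and sigma on the tabulated grid (log-frequency, linear)
.tab_props <- function(material, frequency) {
  rng <- range(material$table$frequency_hz)
  bad <- frequency < rng[1] * (1 - 1e-12) | frequency > rng[2] * (1 + 1e-12)
  if (any(bad))
    stop(sprintf("frequency %g Hz outside validity range [%g, %g] Hz of material '%s'",
                 frequency[which(bad)[1]], rng[1], rng[2], material$name), call. = FALSE)
  lf <- log(pmin(pmax(frequency, rng[1]), rng[2]))
  lg <- log(material$table$frequency_hz)
  list(eps_rel = stats::approx(lg, material$table$eps_rel_real, xout = lf)$y,
       sigma   = stats::approx(lg, material$table$sigma_s_per_m, xout = lf)$y)
}

.parametric_eps_rel <- function(material, frequency) {
  w <- 2 * pi * frequency
  eps <- rep(as.complex(material$eps_inf), length(w))
  for (tr in material$terms) {
    jwt <- complex(real = 0, imaginary = 1) * w * tr$tau_s
    eps <- eps + tr$delta_eps / (1 + jwt^(1 - tr$alpha))
  }
  eps - complex(real = 0, imaginary = 1) * material$sigma_static / (w * EPS0)
}

#' Evaluate the complex permittivity of a material
#'
#' @param material a `dispersive_material`.
#' @param frequency frequency vector, Hz; must be > 0 and within the
#'   material's validity range.
#' @param relative return relative (dimensionless) instead of absolute F/m.
#' @return complex vector of \eqn{\varepsilon^*} values.
#' @export
#' @examples
#' m <- parametric_material("demo", eps_inf = 50, sigma_static = 0.1)
#' evaluate_permittivity(m, 100)
evaluate_permittivity <- function(material, frequency, relative = FALSE) {
  stopifnot(inherits(material, "dispersive_material"))
  if (any(frequency <= 0))
    stop(sprintf("frequency must be > 0 to evaluate permittivity of '%s'",
                 material$name), call. = FALSE)
  if (material$source == "tabulated") {
    pr <- .tab_props(material, frequency)
    out <- complex_permittivity(pr$eps_rel, pr$sigma, frequency, relative = TRUE)
  } else {
    fmax <- material$f_max_hz %||% Inf
    if (any(frequency > fmax))
      stop(sprintf("frequency %g Hz outside validity range [0, %g] Hz of material '%s'",
                   max(frequency), fmax, material$name), call. = FALSE)
    out <- .parametric_eps_rel(material, frequency)
  }
  if (relative) out else out * EPS0
}

#' Complex conductivity (admittance-form permittivity)
#'
#' \eqn{\kappa^*(\omega) = j\omega\varepsilon^* = \sigma + j\omega\varepsilon}
#' in S/m.  Unlike \eqn{\varepsilon^*} this is finite at DC, where it reduces
#' to the (static or lowest-grid) conductivity, so the whole network algebra
#' is carried out in \eqn{\kappa}.
#'
#' @inheritParams evaluate_permittivity
#' @return complex vector, S/m.
#' @export
complex_conductivity <- function(material, frequency) {
  stopifnot(inherits(material, "dispersive_material"))
  out <- complex(length.out = length(frequency))
  zero <- frequency == 0
  if (any(zero)) {
    ## resistive DC limit: static conductivity (parametric) or the
    ## conductivity at the lowest tabulated grid point
    sig0 <- if (material$source == "parametric") material$sigma_static
            else material$table$sigma_s_per_m[1]
    out[zero] <- complex(real = sig0)
  }
  if (any(!zero)) {
    f <- frequency[!zero]
    out[!zero] <- complex(real = 0, imaginary = 1) * 2 * pi * f *
      evaluate_permittivity(material, f)
  }
  out
}

## ---------------------------------------------------------------------------
## Complex capacitor <-> impedance

#' Complex capacitance of a layer
#'
#' \eqn{C^* = \varepsilon^* g} with geometric factor g in metres
#' (\eqn{g = C/\varepsilon}, e.g. A/d for a parallel plate).
#'
#' @param eps complex permittivity, absolute F/m.
#' @param gf geometric factor, m; must be > 0.
#' @return complex capacitance, F.
#' @export
complex_capacitance <- function(eps, gf) {
  .tpb_stopifnot_scalar(gf, "gf")
  eps * gf
}

#' Impedance of a complex capacitor
#'
#' \eqn{Z = 1/(j\omega C^*)}.  Computed in admittance form
#' \eqn{Y = j\omega C^*}; at DC the conduction part of \eqn{C^*} has already
#' diverged, so a finite DC impedance must be supplied through
#' `dc_conductance` (\eqn{\sigma g}, the resistive limit) -- otherwise
#' frequency 0 is a singular-impedance error.
#'
#' @param cap complex capacitance (F), evaluated at `frequency`.
#' @param frequency Hz.
#' @param dc_conductance optional \eqn{\sigma g} in S used when
#'   `frequency == 0`.
#' @return complex impedance, Ohm.
#' @export
capacitor_impedance <- function(cap, frequency, dc_conductance = NULL) {
  if (length(frequency) == 1L) frequency <- rep(frequency, length(cap))
  z <- complex(length.out = length(cap))
  zero <- frequency == 0
  if (any(zero)) {
    if (is.null(dc_conductance) || any(dc_conductance <= 0))
      stop("singular impedance: frequency = 0 with no conductive path (supply dc_conductance = sigma*gf > 0)",
           call. = FALSE)
    z[zero] <- 1 / dc_conductance
  }
  y <- complex(real = 0, imaginary = 1) * 2 * pi * frequency[!zero] * cap[!zero]
  if (any(Mod(y) == 0))
    stop("singular impedance: zero admittance at a positive frequency", call. = FALSE)
  z[!zero] <- 1 / y
  z
}

#' Impedance of a homogeneous material layer
#'
#' Convenience wrapper: \eqn{Z = 1/(\kappa^* g)} with
#' \eqn{\kappa^* = j\omega\varepsilon^*}.  Well-defined at DC for
#' parametric materials with \eqn{\sigma > 0}.
#'
#' @inheritParams complex_conductivity
#' @param gf geometric factor, m.
#' @return complex impedance vector, Ohm.
#' @export
layer_impedance <- function(material, gf, frequency) {
  .tpb_stopifnot_scalar(gf, "gf")
  1 / (complex_conductivity(material, frequency) * gf)
}

#' Recover a tabulated material from an impedance spectrum
#'
#' Inverts the complex-capacitor relation per frequency:
#' \eqn{\varepsilon^* = 1/(j\omega Z g)}, splitting the result into real
#' relative permittivity and conductivity (\eqn{\sigma = -\omega\,
#' \mathrm{Im}\,\varepsilon^*}).  This is the permittivity-from-measurement
#' step used on single-layer structures probed with surface electrodes.
#'
#' Negative recovered conductivity or sub-unity permittivity are not errors
#' (measurement noise and electrode effects can produce them) but are
#' recorded in the returned material's `flags` with a warning.
#'
#' @param impedance complex impedance vector, Ohm; all magnitudes > 0.
#' @param frequency_hz matching frequency grid, Hz, strictly increasing > 0.
#' @param gf geometric factor of the probed structure, m.
#' @param name name for the recovered material.
#' @return a tabulated `dispersive_material`.
#' @export
permittivity_from_spectrum <- function(impedance, frequency_hz, gf,
                                       name = "recovered") {
  .tpb_stopifnot_scalar(gf, "gf")
  if (length(impedance) != length(frequency_hz))
    stop("impedance and frequency_hz must have equal length", call. = FALSE)
  if (any(frequency_hz <= 0)) stop("frequencies must be > 0", call. = FALSE)
  if (any(Mod(impedance) == 0)) stop("zero impedance cannot be inverted", call. = FALSE)
  w <- 2 * pi * frequency_hz
  eps <- 1 / (complex(real = 0, imaginary = 1) * w * impedance * gf)
  eps_rel <- Re(eps) / EPS0
  sigma <- -w * Im(eps)
  m <- tabulated_material(name, frequency_hz, eps_rel, sigma, check_physical = FALSE)
  if ("negative_sigma" %in% m$flags)
    warning(sprintf("material '%s': negative conductivity recovered at %d grid point(s)",
                    name, sum(sigma < 0)), call. = FALSE)
  m
}

## ---------------------------------------------------------------------------
## Electrode geometry and the half-space geometric-factor estimate

#' Electrode geometry
#'
#' Two identical rectangular surface electrodes.  The derived area is
#' width x length; the derived source-return distance is the centre-to-centre
#' distance, separation + width.
#'
#' @param width_m,length_m electrode dimensions, m.
#' @param separation_m edge-to-edge separation, m.
#' @return object of class `electrode_geometry`.
#' @export
electrode_geometry <- function(width_m = 0.01, length_m = 0.01,
                               separation_m = 0.01) {
  for (v in c(width_m, length_m, separation_m))
    .tpb_stopifnot_scalar(v, "electrode dimension")
  structure(list(width_m = width_m, length_m = length_m,
                 separation_m = separation_m,
                 area_m2 = width_m * length_m,
                 distance_m = separation_m + width_m),
            class = "electrode_geometry")
}

#' @export
print.electrode_geometry <- function(x, ...) {
  cat(sprintf("<electrode_geometry> %g x %g m, separation %g m (A = %g m^2, d = %g m)\n",
              x$width_m, x$length_m, x$separation_m, x$area_m2, x$distance_m))
  invisible(x)
}

#' Half-space geometric factor of a coplanar electrode pair
#'
#' Conformal-mapping estimate of the geometric factor g = C/eps of an
#' effectively infinite half-space under two coplanar strip electrodes
#' (width w, gap s, length L):
#' \deqn{g = \frac{L}{2}\, \frac{K(k')}{K(k)}, \qquad k = \frac{s}{s + 2w}}
#' with K the complete elliptic integral of the first kind.  This provides
#' the bottom-layer GF when no externally computed value is supplied.
#'
#' @param geometry an [electrode_geometry()].
#' @return geometric factor, m.
#' @export
gf_halfspace <- function(geometry) {
  stopifnot(inherits(geometry, "electrode_geometry"))
  k <- geometry$separation_m / (geometry$separation_m + 2 * geometry$width_m)
  Kk <- pracma::ellipke(k^2)$k
  Kkp <- pracma::ellipke(1 - k^2)$k
  geometry$length_m / 2 * Kkp / Kk
}
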