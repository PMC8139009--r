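## Layered-body impedance network.
##
## Per frequency the stack is reduced by the PC recurrence: each interface is
## classified PPC/SPC, per-layer partial capacitors come from the (i, i+1)
## pair composition, the infinite bottom layer contributes eps*g2, and the
## gel contact resistance is appended in series.  An SPC interface makes the
## upper layer's capacitor a series element (its impedances add); a PPC
## interface puts it in parallel with the reduced structure below.

#' A tissue layer
#'
#' @param material a [dispersive_material][tabulated_material].
#' @param thickness_mm thickness in mm (> 0); ignored when `infinite`.
#' @param infinite marks the effectively infinite bottom layer.
#' @param name layer name; defaults to the material name.
#' @return object of class `tissue_layer`.
#' @export
tissue_layer <- function(material, thickness_mm = NULL, infinite = FALSE,
                         name = material$name) {
  stopifnot(inherits(material, "dispersive_material"))
  if (!infinite) .tpb_stopifnot_scalar(thickness_mm, "thickness_mm")
  structure(list(material = material, thickness_mm = thickness_mm,
                 infinite = infinite, name = name),
            class = "tissue_layer")
}

#' A layered body under surface electrodes
#'
#' Ordered top-to-bottom layers, exactly one of which -- the bottom one --
#' is marked effectively infinite.  An optional conductive-gel contact
#' resistance is connected in series with the whole stack.
#'
#' @param layers list of [tissue_layer()] objects, top to bottom.
#' @param geometry an [electrode_geometry()].
#' @param gel_ohms series gel resistance, Ohm (\eqn{\ge 0}).
#' @param g2 bottom-layer geometric factor in m, or `"estimate"` to use the
#'   coplanar conformal-mapping estimate [gf_halfspace()] (a directly
#'   supplied numeric value takes precedence).
#' @param if_scale IF unit-calibration scale factor carried by the body
#'   (default 1; see [calibrate_if_scale()]).
#' @param name body name.
#' @return object of class `layered_body`.
#' @export
layered_body <- function(layers, geometry = electrode_geometry(),
                         gel_ohms = 0, g2 = "estimate", if_scale = 1,
                         name = "body") {
  stopifnot(length(layers) >= 1L,
            all(vapply(layers, inherits, logical(1), "tissue_layer")))
  n <- length(layers)
  inf_flags <- vapply(layers, `[[`, logical(1), "infinite")
  if (sum(inf_flags) != 1L || !inf_flags[n])
    stop("exactly one layer must be infinite, and it must be the bottom one",
         call. = FALSE)
  if (gel_ohms < 0) stop("gel_ohms must be >= 0", call. = FALSE)
  if (identical(g2, "estimate")) g2 <- gf_halfspace(geometry)
  .tpb_stopifnot_scalar(g2, "g2")
  .tpb_stopifnot_scalar(if_scale, "if_scale")
  nm <- make.unique(vapply(layers, `[[`, character(1), "name"))
  for (i in seq_len(n)) layers[[i]]$name <- nm[i]
  structure(list(layers = layers, geometry = geometry, gel_ohms = gel_ohms,
                 g2 = g2, if_scale = if_scale, name = name),
            class = "layered_body")
}

#' @export
print.layered_body <- function(x, ...) {
  cat("<layered_body> ", x$name, "\n", sep = "")
  for (l in x$layers)
    cat(sprintf("  %-10s %s\n", l$name,
                if (l$infinite) "(infinite)" else sprintf("%g mm", l$thickness_mm)))
  cat(sprintf("  gel %g Ohm, g2 = %.4g m, IF scale = %g\n",
              x$gel_ohms, x$g2, x$if_scale))
  invisible(x)
}

layer_names <- function(body) vapply(body$layers, `[[`, character(1), "name")

#' Default analysis frequency grid
#'
#' 201 points, log-spaced from 0.1 Hz to 10 kHz (the impedance-analyzer
#' protocol the models are exercised on).
#'
#' @param n number of points.
#' @param fmin,fmax grid limits, Hz.
#' @return numeric vector.
#' @export
default_frequency_grid <- function(n = 201, fmin = 0.1, fmax = 1e4) {
  exp(seq(log(fmin), log(fmax), length.out = n))
}

## body -> [nf x n] matrices of generalized permittivities; DC rows use the
## conductivity limit (kappa(0) = sigma), in which both the element algebra
## and the IF arguments are carried by sigma
.body_reduce <- function(body, frequency, coeffs, scale) {
  n <- length(body$layers); nf <- length(frequency)
  h <- vapply(body$layers, function(l)
    if (l$infinite) Inf else l$thickness_mm, numeric(1))
  pos <- frequency > 0
  elems <- matrix(complex(real = NA_real_), nf, n)
  total_z <- complex(length.out = nf)
  classes <- matrix(NA_character_, nf, max(n - 1L, 0L))
  if (any(pos)) {
    f <- frequency[pos]
    eps <- matrix(vapply(body$layers,
                         function(l) evaluate_permittivity(l$material, f),
                         complex(length(f))), length(f), n)
    red <- pc_reduce(eps, eps / EPS0, h, body$g2, coeffs, scale)
    jw <- complex(real = 0, imaginary = 1) * 2 * pi * f
    elems[pos, ] <- 1 / (jw * red$elems)   # layer impedances (0 when merged)
    total_z[pos] <- 1 / (jw * red$total)
    if (n > 1L) classes[pos, ] <- red$classes
  }
  if (any(!pos)) {
    sig <- matrix(vapply(body$layers,
                         function(l) complex_conductivity(l$material, 0),
                         complex(1)), 1, n)
    cls0 <- if (n > 1L) classify_pair(sig[, -n, drop = TRUE], sig[, -1L, drop = TRUE])
            else character(0)
    if (any(cls0 == "PPC"))
      stop("DC response is undefined for a PPC interface (the PPC interdimensional factor diverges logarithmically at DC)",
           call. = FALSE)
    red0 <- pc_reduce(sig, sig, h, body$g2, coeffs, scale)
    elems[!pos, ] <- rep(1 / red0$elems, each = sum(!pos))
    total_z[!pos] <- 1 / red0$total
    if (n > 1L) classes[!pos, ] <- rep(red0$classes, each = sum(!pos))
  }
  list(z_layers = elems, z_total = total_z + body$gel_ohms, classes = classes)
}

#' Impedance spectrum of a layered body
#'
#' Evaluates all layer permittivities over the grid, classifies every
#' interface, composes per-layer partial capacitors through the recurrent PC
#' reduction, converts them to impedances (\eqn{Z = 1/(j\omega C^*)}) and
#' appends the gel resistance in series.  Frequency 0 is supported when all
#' interfaces are SPC/homogeneous at DC (the resistive limit, computed in
#' complex-conductivity form).
#'
#' @param body a [layered_body()].
#' @param frequencies frequency grid, Hz (strictly increasing,
#'   \eqn{\ge 0}); defaults to [default_frequency_grid()].
#' @param coeffs named list with `PPC` and `SPC` [if_coefficients()].
#' @param scale IF unit-calibration scale factor; defaults to the body's
#'   `if_scale`.
#' @return object of class `impedance_spectrum`: `frequency`, complex matrix
#'   `z_layers` (one column per layer), complex `z_total` (gel included),
#'   `classes` (interface topology tags per frequency), `gel_ohms`.
#' @export
build_network <- function(body, frequencies = default_frequency_grid(),
                          coeffs = default_if_coefficients(), scale = NULL) {
  stopifnot(inherits(body, "layered_body"))
  if (any(diff(frequencies) <= 0))
    stop("frequency grid must be strictly increasing", call. = FALSE)
  if (any(frequencies < 0)) stop("frequencies must be >= 0", call. = FALSE)
  scale <- scale %||% body$if_scale
  red <- .body_reduce(body, frequencies, coeffs, scale)
  .warn_crossover(red$classes, frequencies)
  colnames(red$z_layers) <- layer_names(body)
  structure(list(frequency = frequencies, z_layers = red$z_layers,
                 z_total = red$z_total, classes = red$classes,
                 gel_ohms = body$gel_ohms, body_name = body$name),
            class = "impedance_spectrum")
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  rng <- range(x$frequency)
  cat(sprintf("<impedance_spectrum> %s: %d frequencies, %.3g Hz to %.3g Hz\n",
              x$body_name, length(x$frequency), rng[1], rng[2]))
  cat(sprintf("  |Z_total|: %.4g Ohm (low end) to %.4g Ohm (high end)\n",
              Mod(x$z_total[1]), Mod(x$z_total[length(x$z_total)])))
  topo <- apply(x$classes, 2, function(cl) paste(unique(cl), collapse = "/"))
  if (length(topo))
    cat("  interfaces:", paste(topo, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.impedance_spectrum <- function(x, ...) {
  nm <- c(colnames(x$z_layers), "total")
  z <- cbind(x$z_layers, x$z_total)
  do.call(rbind, lapply(seq_along(nm), function(i)
    data.frame(frequency_hz = x$frequency, layer = nm[i],
               z_real = Re(z[, i]), z_imag = Im(z[, i]))))
}

#' @export
plot.impedance_spectrum <- function(x, ...) {
  pos <- x$frequency > 0
  n <- ncol(x$z_layers)
  graphics::matplot(x$frequency[pos],
                    cbind(Mod(x$z_layers[pos, , drop = FALSE]), Mod(x$z_total[pos])),
                    type = "l", log = "xy", lty = c(rep(2, n), 1),
                    col = c(seq_len(n) + 1, 1),
                    xlab = "frequency [Hz]", ylab = "|Z| [Ohm]", ...)
  graphics::legend("bottomleft", legend = c(colnames(x$z_layers), "total"),
                   lty = c(rep(2, n), 1), col = c(seq_len(n) + 1, 1), bty = "n")
  invisible(x)
}

.find_layer <- function(body, layer_name) {
  idx <- match(layer_name, layer_names(body))
  if (is.na(idx))
    stop(sprintf("no layer named '%s' (layers: %s)", layer_name,
                 paste(layer_names(body), collapse = ", ")), call. = FALSE)
  idx
}

#' Sweep one layer's thickness
#'
#' @param body a [layered_body()].
#' @param layer_name layer to vary; must not be the infinite bottom layer.
#' @param values_mm thickness values, mm.
#' @param frequencies frequency grid, Hz.
#' @param ... passed to [build_network()].
#' @return named list of `impedance_spectrum` objects, one per thickness;
#'   the input body is unmodified.
#' @export
thickness_sweep <- function(body, layer_name, values_mm,
                            frequencies = default_frequency_grid(), ...) {
  idx <- .find_layer(body, layer_name)
  if (body$layers[[idx]]$infinite)
    stop("cannot sweep the thickness of the infinite bottom layer", call. = FALSE)
  out <- lapply(values_mm, function(v) {
    b <- body
    b$layers[[idx]]$thickness_mm <- v
    build_network(b, frequencies, ...)
  })
  names(out) <- sprintf("%s_%g_mm", layer_name, values_mm)
  out
}

## uniformly scale a material's complex permittivity (both eps and sigma)
scale_material <- function(material, factor) {
  .tpb_stopifnot_scalar(factor, "factor")
  m <- material
  if (m$source == "tabulated") {
    m$table$eps_rel_real <- m$table$eps_rel_real * factor
    m$table$sigma_s_per_m <- m$table$sigma_s_per_m * factor
  } else {
    m$eps_inf <- m$eps_inf * factor
    m$terms <- lapply(m$terms, function(tr) { tr$delta_eps <- tr$delta_eps * factor; tr })
    m$sigma_static <- m$sigma_static * factor
  }
  m$name <- sprintf("%s_x%g", m$name, factor)
  ## bypass the eps_r >= 1 check: a scaled physical material is a what-if input
  m$flags <- unique(c(m$flags, if (factor != 1) "scaled"))
  m
}

#' Sweep one layer's permittivity
#'
#' Scales the named layer's complex permittivity \eqn{\varepsilon^*(\omega)}
#' (real and conduction part together) by each factor.
#'
#' @param body a [layered_body()].
#' @param layer_name layer to vary.
#' @param scale_factors multiplicative factors, all > 0; default
#'   \eqn{\pm 20\%} in 10\% steps.
#' @param frequencies frequency grid, Hz.
#' @param ... passed to [build_network()].
#' @return named list of `impedance_spectrum` objects.
#' @export
permittivity_sweep <- function(body, layer_name,
                               scale_factors = c(0.8, 0.9, 1.0, 1.1, 1.2),
                               frequencies = default_frequency_grid(), ...) {
  if (any(scale_factors <= 0)) stop("scale factors must be > 0", call. = FALSE)
  idx <- .find_layer(body, layer_name)
  out <- lapply(scale_factors, function(s) {
    b <- body
    b$layers[[idx]]$material <- scale_material(b$layers[[idx]]$material, s)
    build_network(b, frequencies, ...)
  })
  names(out) <- sprintf("%s_x%g", layer_name, scale_factors)
  out
}

#' Calibrate the IF unit scale against a reference total impedance
#'
#' The absolute unit of the shipped IF coefficients is an open
#' interpretation question, so the package exposes a single multiplicative
#' calibration factor on all interdimensional factors.  This helper solves
#' for the factor that makes \eqn{|Z_{total}|} at one reference frequency
#' equal a known value (for a body whose finite layers are all series/SPC
#' elements, where the dependence is monotone).
#'
#' @param body a [layered_body()].
#' @param target_ohms reference \eqn{|Z_{total}|}, Ohm.
#' @param frequency reference frequency, Hz.
#' @param coeffs IF coefficient list.
#' @return the calibrated scale factor (also set on the returned body's
#'   `if_scale` attribute via `attr(, "body")`).
#' @export
calibrate_if_scale <- function(body, target_ohms, frequency = 0.1,
                               coeffs = default_if_coefficients()) {
  .tpb_stopifnot_scalar(target_ohms, "target_ohms")
  f <- function(ls) {
    sp <- build_network(body, frequency, coeffs, scale = 10^ls)
    log(Mod(sp$z_total)) - log(target_ohms)
  }
  sol <- stats::uniroot(f, lower = -12, upper = 8, tol = 1e-12)
  s <- 10^sol$root
  b <- body; b$if_scale <- s
  structure(s, body = b)
}
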