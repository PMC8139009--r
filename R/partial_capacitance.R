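## Partial-capacitance (PC) composition of layered dielectrics.
##
## The PC method decomposes the total capacitance of a layered structure into
## per-layer capacitors.  Whether a layer's capacitor sits in parallel (PPC)
## or in series (SPC) with the structure below is decided by the permittivity
## ratio against the underlying layer:
##   PPC  (|eps1| > |eps2|):  C_tot = (eps1 - eps2) I + C_below
##   SPC  (|eps1| < |eps2|):  1/C_tot = (1/eps1 - 1/eps2)/I + 1/C_below
## where I is the interdimensional factor (IF), the regression-corrected
## geometric factor of the upper layer, and C_below is eps2*g2 for an
## effectively infinite bottom layer.  The same algebra applied to
## kappa = j w eps* yields admittances/conductances, which is how the network
## module reuses the core at DC.

#' Interdimensional-factor coefficients
#'
#' Holds the regression coefficients of the IF models:
#' \deqn{I_{PPC} = a_0 + a_1 \ln|\Delta\varepsilon_r| + a_2 \ln h_1}
#' \deqn{I_{SPC} = (b_0 + b_1 \ln(\varepsilon_{2r}/\varepsilon_{1r}))/h_1 + c_0}
#' with the declared unit interpretation: thickness \eqn{h_1} in millimetres
#' inside the log/inverse terms, permittivity arguments relative
#' (dimensionless), output in geometric-factor units.
#'
#' @param kind `"PPC"` or `"SPC"`.
#' @param values numeric length-3: `(a0, a1, a2)` for PPC,
#'   `(b0, b1, c0)` for SPC.
#' @param units_note free-text record of the unit interpretation.
#' @param provenance `"published-default"` for the shipped triples or an
#'   identifier of the fit that produced them.
#' @return object of class `if_coefficients`.
#' @export
if_coefficients <- function(kind = c("PPC", "SPC"), values,
                            units_note = "h1 in mm; permittivity arguments relative; IF in GF units",
                            provenance = "user") {
  kind <- match.arg(kind)
  if (length(values) != 3L || !is.numeric(values) || any(!is.finite(values)))
    stop("'values' must be three finite numbers", call. = FALSE)
  values <- as.numeric(values)
  names(values) <- if (kind == "PPC") c("a0", "a1", "a2") else c("b0", "b1", "c0")
  structure(list(kind = kind, values = values, units_note = units_note,
                 provenance = provenance),
            class = "if_coefficients")
}

#' @export
print.if_coefficients <- function(x, ...) {
  cat("<if_coefficients> ", x$kind, " [", x$provenance, "]\n  ", sep = "")
  cat(paste(sprintf("%s = %.6g", names(x$values), x$values), collapse = ", "), "\n")
  cat("  units:", x$units_note, "\n")
  invisible(x)
}

#' Shipped default IF coefficients
#'
#' The published regression triples:
#' PPC \eqn{(a_0,a_1,a_2) = 10^{-3}(4.69, 1.12, 4.40)} and
#' SPC \eqn{(b_0,b_1,c_0) = 10^{3}(2.83, 1.00, 1.30)}.
#'
#' @param kind `"PPC"`, `"SPC"`, or `NULL` for a named list of both.
#' @return an `if_coefficients` object, or a list of two.
#' @export
default_if_coefficients <- function(kind = NULL) {
  both <- list(
    PPC = if_coefficients("PPC", 1e-3 * c(4.69, 1.12, 4.40),
                          provenance = "published-default"),
    SPC = if_coefficients("SPC", 1e3 * c(2.83, 1.00, 1.30),
                          provenance = "published-default"))
  if (is.null(kind)) both else both[[match.arg(kind, c("PPC", "SPC"))]]
}

#' Classify a layer pair as PPC, SPC or homogeneous
#'
#' The comparison is on complex-permittivity magnitudes at one frequency:
#' PPC when the upper layer's magnitude exceeds the lower's, SPC when it is
#' smaller, homogeneous when equal within a relative tolerance.
#'
#' @param eps1,eps2 complex permittivities of the upper and lower layer
#'   (any common unit); vectorized.
#' @param tol relative tie tolerance on the magnitudes.
#' @return character vector of `"PPC"`, `"SPC"`, `"HOMOGENEOUS"`.
#' @export
classify_pair <- function(eps1, eps2, tol = 1e-9) {
  if (any(!is.finite(Mod(eps1))) || any(!is.finite(Mod(eps2))))
    stop("permittivities must be finite", call. = FALSE)
  m1 <- Mod(eps1); m2 <- Mod(eps2)
  out <- rep("HOMOGENEOUS", max(length(m1), length(m2)))
  d <- m1 - m2
  scale <- pmax(m1, m2)
  tie <- abs(d) <= tol * scale
  out[!tie & d > 0] <- "PPC"
  out[!tie & d < 0] <- "SPC"
  out
}

#' A two-layer composition problem
#'
#' Upper layer (permittivity `eps1`, thickness `h1_mm`) over an effectively
#' infinite lower layer (`eps2`, bottom geometric factor `g2`).
#' Permittivities are absolute (F/m) and may be vectors over a common
#' frequency grid.
#'
#' @param eps1,eps2 complex permittivities, F/m.
#' @param h1_mm upper-layer thickness in millimetres (> 0).
#' @param g2 bottom geometric factor in metres (> 0).
#' @return object of class `layer_pair`.
#' @export
layer_pair <- function(eps1, eps2, h1_mm, g2) {
  .tpb_stopifnot_scalar(h1_mm, "h1_mm")
  .tpb_stopifnot_scalar(g2, "g2")
  n <- max(length(eps1), length(eps2))
  structure(list(eps1 = rep_len(as.complex(eps1), n),
                 eps2 = rep_len(as.complex(eps2), n),
                 h1_mm = h1_mm, g2 = g2),
            class = "layer_pair")
}

## scalar/vector IF evaluators on already-extracted arguments
.if_ppc <- function(delta_rel, h1_mm, v) v[["a0"]] + v[["a1"]] * log(delta_rel) + v[["a2"]] * log(h1_mm)
.if_spc <- function(ratio_rel, h1_mm, v) (v[["b0"]] + v[["b1"]] * log(ratio_rel)) / h1_mm + v[["c0"]]

.check_if_positive <- function(I, kind) {
  if (any(I <= 0))
    warning(sprintf("%s interdimensional factor non-positive for %d input(s); the pair lies outside the regression's calibrated domain",
                    kind, sum(I <= 0)), call. = FALSE)
  I
}

#' Evaluate the PPC interdimensional factor
#'
#' \eqn{I = a_0 + a_1\ln|\Delta\varepsilon_r| + a_2\ln h_1} with
#' \eqn{\Delta\varepsilon_r} the magnitude of the relative-permittivity
#' difference of the pair and \eqn{h_1} in mm.  The magnitude (rather than a
#' complex principal log) keeps the IF real; the complex character of the
#' layers enters through the \eqn{(\varepsilon_1-\varepsilon_2)} term of the
#' composition itself.
#'
#' @param pair a [layer_pair()] satisfying the PPC condition.
#' @param coeffs PPC [if_coefficients()].
#' @return IF value(s), geometric-factor units.
#' @export
eval_ppc_if <- function(pair, coeffs = default_if_coefficients("PPC")) {
  stopifnot(inherits(pair, "layer_pair"), inherits(coeffs, "if_coefficients"))
  if (coeffs$kind != "PPC") stop("coefficients are not PPC", call. = FALSE)
  delta <- Mod(rel_permittivity(pair$eps1) - rel_permittivity(pair$eps2))
  if (any(delta == 0))
    stop("permittivity difference is zero: the pair is homogeneous; compose via the homogeneous path",
         call. = FALSE)
  .check_if_positive(.if_ppc(delta, pair$h1_mm, coeffs$values), "PPC")
}

#' Evaluate the SPC interdimensional factor
#'
#' \eqn{I = (b_0 + b_1\ln(\varepsilon_{2r}/\varepsilon_{1r}))/h_1 + c_0}
#' with the permittivity ratio taken as a magnitude (dimensionless) and
#' \eqn{h_1} in mm.
#'
#' @param pair a [layer_pair()] satisfying the SPC condition.
#' @param coeffs SPC [if_coefficients()].
#' @return IF value(s), geometric-factor units.
#' @export
eval_spc_if <- function(pair, coeffs = default_if_coefficients("SPC")) {
  stopifnot(inherits(pair, "layer_pair"), inherits(coeffs, "if_coefficients"))
  if (coeffs$kind != "SPC") stop("coefficients are not SPC", call. = FALSE)
  ratio <- Mod(pair$eps2) / Mod(pair$eps1)
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop("permittivity ratio must be finite and > 0", call. = FALSE)
  .check_if_positive(.if_spc(ratio, pair$h1_mm, coeffs$values), "SPC")
}

#' Compose a PPC pair into a total complex capacitance
#'
#' \eqn{C = (\varepsilon_1 - \varepsilon_2)\,I\,s + C_{below}} where
#' \eqn{C_{below}} defaults to \eqn{\varepsilon_2 g_2} (infinite bottom
#' layer) and `scale` s is the exposed unit-calibration factor on the IF.
#' A homogeneous pair short-circuits to \eqn{C_{below}} (the
#' \eqn{(\varepsilon_1-\varepsilon_2) I} term vanishes in the limit despite
#' the log divergence of I).
#'
#' @inheritParams eval_ppc_if
#' @param scale IF unit-calibration scale factor (default 1).
#' @param c_below capacitance of the already-reduced structure below the
#'   interface; defaults to `eps2 * g2`.
#' @return complex capacitance, F.
#' @export
compose_ppc <- function(pair, coeffs = default_if_coefficients("PPC"),
                        scale = 1, c_below = NULL) {
  cls <- classify_pair(pair$eps1, pair$eps2)
  below <- c_below %||% (pair$eps2 * pair$g2)
  out <- rep_len(below, length(pair$eps1))
  below <- out
  act <- cls != "HOMOGENEOUS"
  if (any(cls[act] == "SPC"))
    stop("pair violates the PPC condition (|eps1| < |eps2|)", call. = FALSE)
  if (any(act)) {
    if (coeffs$kind != "PPC") stop("coefficients are not PPC", call. = FALSE)
    delta <- Mod(rel_permittivity(pair$eps1[act]) - rel_permittivity(pair$eps2[act]))
    I <- .check_if_positive(.if_ppc(delta, pair$h1_mm, coeffs$values), "PPC")
    out[act] <- (pair$eps1[act] - pair$eps2[act]) * I * scale + below[act]
  }
  out
}

#' Compose an SPC pair into a total complex capacitance
#'
#' \eqn{1/C = (1/\varepsilon_1 - 1/\varepsilon_2)/(I\,s) + 1/C_{below}}.
#'
#' @inheritParams compose_ppc
#' @return complex capacitance, F.
#' @export
compose_spc <- function(pair, coeffs = default_if_coefficients("SPC"),
                        scale = 1, c_below = NULL) {
  cls <- classify_pair(pair$eps1, pair$eps2)
  below <- c_below %||% (pair$eps2 * pair$g2)
  if (any(Mod(below) == 0) || any(Mod(pair$eps1) == 0) || any(Mod(pair$eps2) == 0))
    stop("singularity: zero permittivity or zero bottom capacitance in a reciprocal term",
         call. = FALSE)
  out <- rep_len(below, length(pair$eps1))
  below <- out
  act <- cls != "HOMOGENEOUS"
  if (any(cls[act] == "PPC"))
    stop("pair violates the SPC condition (|eps1| > |eps2|)", call. = FALSE)
  if (any(act)) {
    if (coeffs$kind != "SPC") stop("coefficients are not SPC", call. = FALSE)
    ratio <- Mod(pair$eps2[act]) / Mod(pair$eps1[act])
    I <- .check_if_positive(.if_spc(ratio, pair$h1_mm, coeffs$values), "SPC")
    inv <- (1 / pair$eps1[act] - 1 / pair$eps2[act]) / (I * scale) + 1 / below[act]
    out[act] <- 1 / inv
  }
  out
}

## ---------------------------------------------------------------------------
## Vectorized recurrent reduction core.
##
## p_abs, p_rel: [n_freq x n_layer] complex matrices of "generalized
## permittivities" -- eps* (absolute) with eps*/eps0 as the IF/class argument
## at f > 0, or sigma (real) in both roles at DC, where sigma2/sigma1 is the
## exact DC limit of the relative-permittivity ratio.  h_mm: upper-layer
## thicknesses (last entry, the infinite bottom layer, is ignored).
## Returns per-layer partial elements and the reduced total: capacitances
## when fed eps*, admittances/conductances when fed kappa.
pc_reduce <- function(p_abs, p_rel, h_mm, g2, coeffs = default_if_coefficients(),
                      scale = 1, tol = 1e-9) {
  p_abs <- as.matrix(p_abs); p_rel <- as.matrix(p_rel)
  n <- ncol(p_abs); nf <- nrow(p_abs)
  if (n < 1L) stop("empty stack", call. = FALSE)
  elems <- matrix(complex(real = NA_real_), nf, n)
  classes <- if (n > 1L) matrix(NA_character_, nf, n - 1L) else
    matrix(character(0), nf, 0L)
  total <- p_abs[, n] * g2
  elems[, n] <- total
  if (n == 1L) return(list(total = total, elems = elems, classes = classes))
  for (i in seq(n - 1L, 1L)) {
    cls <- classify_pair(p_rel[, i], p_rel[, i + 1L], tol = tol)
    classes[, i] <- cls
    e <- rep(complex(real = Inf), nf)
    ppc <- cls == "PPC"; spc <- cls == "SPC"
    if (any(ppc)) {
      delta <- Mod(p_rel[ppc, i] - p_rel[ppc, i + 1L])
      I <- .check_if_positive(.if_ppc(delta, h_mm[i], coeffs$PPC$values), "PPC")
      e[ppc] <- (p_abs[ppc, i] - p_abs[ppc, i + 1L]) * I * scale
      total[ppc] <- e[ppc] + total[ppc]
    }
    if (any(spc)) {
      ratio <- Mod(p_rel[spc, i + 1L]) / Mod(p_rel[spc, i])
      I <- .check_if_positive(.if_spc(ratio, h_mm[i], coeffs$SPC$values), "SPC")
      e[spc] <- I * scale / (1 / p_abs[spc, i] - 1 / p_abs[spc, i + 1L])
      total[spc] <- 1 / (1 / e[spc] + 1 / total[spc])
    }
    ## HOMOGENEOUS: layer i merges into the structure below; its partial
    ## element is an infinite capacitance (zero series impedance)
    elems[, i] <- e
  }
  list(total = total, elems = elems, classes = classes)
}

.warn_crossover <- function(classes, frequency) {
  if (ncol(classes) == 0L || length(frequency) < 2L) return(invisible(NULL))
  for (i in seq_len(ncol(classes))) {
    cl <- classes[, i]
    flip <- which(cl[-1] != cl[-length(cl)])
    if (length(flip))
      warning(sprintf("interface %d changes PC class across the frequency grid near %s Hz",
                      i, paste(signif(sqrt(frequency[flip] * frequency[flip + 1]), 3),
                               collapse = ", ")), call. = FALSE)
  }
  invisible(NULL)
}

#' Recurrent reduction of an N-layer stack to one complex capacitance
#'
#' Applies the pairwise PPC/SPC composition recurrently: the bottom
#' (effectively infinite) layer contributes \eqn{\varepsilon_N g_2}; each
#' layer above is then folded in through its interface with the layer
#' immediately below, the already-reduced structure standing in for that
#' layer's infinite-bottom term.  Also returns the per-layer partial
#' capacitors used to build the series/parallel impedance network.
#'
#' @param layers list of layers, top to bottom; each a list with elements
#'   `material` (a [dispersive_material][tabulated_material]) and
#'   `thickness_mm` (ignored for the bottom layer, which is treated as
#'   infinite).  A bottom layer thinner than 10x the layer above triggers a
#'   warning (the infinite-layer assumption degrades).
#' @param frequency frequency grid, Hz (> 0).
#' @param g2 bottom geometric factor, m, or `NULL` to estimate it from
#'   `geometry` via [gf_halfspace()].
#' @param coeffs named list with `PPC` and `SPC` [if_coefficients()].
#' @param geometry an [electrode_geometry()], used only when `g2` is `NULL`.
#' @param scale IF unit-calibration scale factor.
#' @return list with `c_total` (complex vector over `frequency`), `partials`
#'   (complex matrix, one column per layer; `Inf` marks a layer merged
#'   through a homogeneous interface), `classes` (character matrix, one
#'   column per interface) and `frequency`.  A PC class changing within one
#'   interface across the grid triggers a crossover warning.
#' @export
reduce_stack <- function(layers, frequency, g2 = NULL,
                         coeffs = default_if_coefficients(), geometry = NULL,
                         scale = 1) {
  if (length(layers) < 1L) stop("empty stack", call. = FALSE)
  if (any(frequency <= 0)) stop("frequencies must be > 0", call. = FALSE)
  g2 <- g2 %||% gf_halfspace(geometry %||% electrode_geometry())
  n <- length(layers); nf <- length(frequency)
  h <- vapply(layers, function(l) l$thickness_mm %||% Inf, numeric(1))
  if (n > 1L && is.finite(h[n]) && h[n] < 10 * h[n - 1L])
    warning("bottom layer is less than 10x the thickness of the layer above; the infinite-layer assumption degrades",
            call. = FALSE)
  if (n > 1L && any(h[-n] <= 0)) stop("layer thickness must be > 0", call. = FALSE)
  eps <- vapply(layers, function(l) evaluate_permittivity(l$material, frequency),
                complex(nf))
  eps <- matrix(eps, nf, n)
  red <- pc_reduce(eps, eps / EPS0, h, g2, coeffs, scale)
  .warn_crossover(red$classes, frequency)
  list(c_total = red$total, partials = red$elems, classes = red$classes,
       frequency = frequency, g2 = g2)
}
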