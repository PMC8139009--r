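## Synthetic stand-ins for physically measured inputs: the salted/pure agar
## material pair, the double-layer phantom prediction harness, and the
## synthetic tissue starter pack.  None of these tables are measured data;
## they are order-of-magnitude constructions whose *relationships* (salted
## above pure, muscle above fat above skin) reproduce the documented study
## conditions.

#' Synthetic agar material pair
#'
#' Builds two tabulated materials on the standard 201-point log grid
#' (0.1 Hz to 10 kHz): `pure` (DI-water agar) and `salted` (10 g/L NaCl
#' agar).  The NaCl ions raise the conductivity, so the salted complex
#' permittivity magnitude exceeds the pure one at every grid frequency --
#' the PPC/SPC-deciding ordering.  The conductivity defaults (0.05 and
#' 1.6 S/m) are plausible fixture values for DI-agar versus 10 g/L saline
#' agar, not measured ones.  A mild low-frequency dispersion rides on a
#' water-like baseline permittivity; optional seeded multiplicative noise
#' emulates measurement scatter.
#'
#' @param seed optional RNG seed for the noise.
#' @param sigma_pure,sigma_salted conductivities, S/m; must satisfy
#'   `0 < sigma_pure < sigma_salted`.
#' @param noise_sd multiplicative table noise (0 = clean tables).
#' @param frequencies grid, Hz.
#' @return object of class `agar_pair`: list with `pure`, `salted`
#'   (materials) and `salt_g_per_l` metadata.
#' @export
gen_agar_pair <- function(seed = NULL, sigma_pure = 0.05, sigma_salted = 1.6,
                          noise_sd = 0, frequencies = default_frequency_grid()) {
  .tpb_stopifnot_scalar(sigma_pure, "sigma_pure")
  .tpb_stopifnot_scalar(sigma_salted, "sigma_salted")
  if (sigma_pure >= sigma_salted)
    stop("need sigma_pure < sigma_salted: NaCl raises the conductivity, the pair ordering is fixed",
         call. = FALSE)
  f <- frequencies
  eps_pure <- 80 + 500 / (1 + f / 100)
  eps_salt <- 80 + 5000 / (1 + f / 100)
  sig_pure <- rep(sigma_pure, length(f))
  sig_salt <- rep(sigma_salted, length(f))
  if (noise_sd > 0) {
    noise <- .with_seed(seed, matrix(stats::rnorm(4 * length(f), 0, noise_sd),
                                     ncol = 4))
    eps_pure <- eps_pure * (1 + noise[, 1]); sig_pure <- sig_pure * (1 + noise[, 2])
    eps_salt <- eps_salt * (1 + noise[, 3]); sig_salt <- sig_salt * (1 + noise[, 4])
  }
  pure <- tabulated_material("agar_pure", f, eps_pure, sig_pure,
                             check_physical = noise_sd == 0)
  salted <- tabulated_material("agar_salt", f, eps_salt, sig_salt,
                               check_physical = noise_sd == 0)
  ord <- Mod(evaluate_permittivity(salted, f)) > Mod(evaluate_permittivity(pure, f))
  if (!all(ord))
    stop("agar pair ordering violated at ", sum(!ord),
         " grid point(s): |eps*_salted| must exceed |eps*_pure| everywhere",
         call. = FALSE)
  structure(list(pure = pure, salted = salted, salt_g_per_l = 10),
            class = "agar_pair")
}

#' Double-layer phantom specification
#'
#' @param top,bottom `dispersive_material` objects for Layer 1 / Layer 2.
#' @param top_mm,bottom_mm thicknesses, mm; defaults mirror the in vitro
#'   phantom (2 mm over 50 mm, satisfying the >= 10x infinite-layer rule;
#'   thinner bottoms warn).
#' @param geometry an [electrode_geometry()].
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(top, bottom, top_mm = 2, bottom_mm = 50,
                         geometry = electrode_geometry()) {
  stopifnot(inherits(top, "dispersive_material"),
            inherits(bottom, "dispersive_material"))
  .tpb_stopifnot_scalar(top_mm, "top_mm")
  .tpb_stopifnot_scalar(bottom_mm, "bottom_mm")
  if (bottom_mm < 10 * top_mm)
    warning("bottom layer thinner than 10x the top layer: the infinite-layer assumption degrades",
            call. = FALSE)
  structure(list(top = top, bottom = bottom, top_mm = top_mm,
                 bottom_mm = bottom_mm, geometry = geometry),
            class = "phantom_spec")
}

#' Modelled complex capacitance of a double-layer phantom
#'
#' Classifies the pair at each frequency (salted-on-pure gives PPC,
#' pure-on-salted gives SPC), composes the total capacitance through the
#' IF-corrected PC model and returns the real and imaginary parts
#' separately for comparison plots.
#'
#' @param spec a [phantom_spec()].
#' @param coeffs IF coefficient list.
#' @param frequencies grid, Hz.
#' @param g2 bottom geometric factor; defaults to the conformal-mapping
#'   estimate for the spec's geometry.
#' @param scale IF unit-calibration scale.
#' @return data.frame `frequency_hz, c_real, c_imag, class` with the
#'   complex capacitance vector attached as attribute `c_complex`.
#' @export
predict_phantom_capacitance <- function(spec, coeffs = default_if_coefficients(),
                                        frequencies = default_frequency_grid(),
                                        g2 = NULL, scale = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  layers <- list(list(material = spec$top, thickness_mm = spec$top_mm),
                 list(material = spec$bottom, thickness_mm = spec$bottom_mm))
  red <- reduce_stack(layers, frequencies,
                      g2 = g2 %||% gf_halfspace(spec$geometry),
                      coeffs = coeffs, scale = scale)
  structure(data.frame(frequency_hz = frequencies,
                       c_real = Re(red$c_total), c_imag = Im(red$c_total),
                       class = red$classes[, 1]),
            c_complex = red$c_total)
}

#' Model-versus-synthetic-measurement correlation harness
#'
#' Pipeline property check standing in for a physical phantom measurement:
#' per replicate, a synthetic "measured" capacitance spectrum is produced by
#' perturbing the modelled one with independent multiplicative Gaussian
#' noise on the real and imaginary parts, and the Pearson correlations
#' between model and measurement are recorded for both parts and both
#' phantom orientations (PPC: salted-on-pure; SPC: pure-on-salted).
#'
#' @param n_seeds number of noise replicates.
#' @param noise_sd multiplicative noise level (0.05 = 5\%).
#' @param seed master seed (replicate r uses `seed + r`).
#' @param pair an [gen_agar_pair()] result; defaults to the clean pair.
#' @param frequencies grid, Hz.
#' @return data.frame with one row per replicate and phantom:
#'   `seed, phantom, cor_real, cor_imag`.
#' @export
agar_correlation_harness <- function(n_seeds = 200, noise_sd = 0.05, seed = 1,
                                     pair = gen_agar_pair(),
                                     frequencies = default_frequency_grid()) {
  specs <- list(
    PPC = phantom_spec(pair$salted, pair$pure),
    SPC = phantom_spec(pair$pure, pair$salted))
  models <- lapply(specs, function(s)
    attr(predict_phantom_capacitance(s, frequencies = frequencies), "c_complex"))
  rows <- list()
  for (r in seq_len(n_seeds)) {
    noise <- .with_seed(seed + r,
                        matrix(stats::rnorm(4 * length(frequencies), 0, noise_sd),
                               ncol = 4))
    for (j in seq_along(models)) {
      cm <- models[[j]]
      meas_re <- Re(cm) * (1 + noise[, 2 * j - 1])
      meas_im <- Im(cm) * (1 + noise[, 2 * j])
      rows[[length(rows) + 1L]] <- data.frame(
        seed = seed + r, phantom = names(models)[j],
        cor_real = stats::cor(Re(cm), meas_re),
        cor_imag = stats::cor(Im(cm), meas_im))
    }
  }
  do.call(rbind, rows)
}

#' Synthetic tissue starter pack (skin, fat, muscle)
#'
#' Loads the shipped parametric dielectric models for gel-moistened skin,
#' subcutaneous fat and skeletal muscle.  These are SYNTHETIC stand-ins
#' with literature-scale Cole-Cole parameters, not a transcription of any
#' measured database; they are constructed so that
#' \eqn{|\varepsilon^*_{muscle}| > |\varepsilon^*_{fat}| >
#' |\varepsilon^*_{skin}|} holds over the whole 0.1 Hz to 10 kHz analysis
#' grid (the all-SPC forearm condition).  Swap in your own material file
#' for quantitative work.
#'
#' @return named list of three `dispersive_material` objects.
#' @export
synthetic_tissue_pack <- function() {
  read_material_json(system.file("extdata", "tissues_synthetic.json",
                                 package = "tpbecm", mustWork = TRUE))
}

#' Three-layer forearm body built from the synthetic tissue pack
#'
#' Skin and fat over an effectively infinite muscle layer, standard 1 cm
#' electrode geometry, 160 Ohm series gel resistance.
#'
#' @param skin_mm,fat_mm finite layer thicknesses, mm.
#' @param gel_ohms series gel resistance, Ohm.
#' @param g2 bottom geometric factor (m) or `"estimate"`.
#' @param if_scale IF unit-calibration scale factor.
#' @return a [layered_body()].
#' @export
forearm_body <- function(skin_mm = 1.5, fat_mm = 2.5, gel_ohms = 160,
                         g2 = "estimate", if_scale = 1) {
  tp <- synthetic_tissue_pack()
  layered_body(list(tissue_layer(tp$skin, skin_mm),
                    tissue_layer(tp$fat, fat_mm),
                    tissue_layer(tp$muscle, infinite = TRUE)),
               geometry = electrode_geometry(),
               gel_ohms = gel_ohms, g2 = g2, if_scale = if_scale,
               name = "forearm_synthetic")
}
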