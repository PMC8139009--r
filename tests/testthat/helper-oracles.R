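# Shared fixtures and independent oracles.  Everything here is built in
# code at test time; nothing is read from disk except shipped extdata.

EPS0_T <- 8.8541878128e-12

# frequency-independent material (one-line parametric: eps_inf only)
const_material <- function(name, eps_r, sigma, f_max_hz = Inf) {
  parametric_material(name, eps_inf = eps_r, sigma_static = sigma,
                      f_max_hz = f_max_hz)
}

# independent oracle: impedance of R parallel C at angular frequency w,
# straight complex arithmetic on the textbook formula
rc_parallel_z <- function(R, C, w) {
  zc <- 1 / (complex(real = 0, imaginary = 1) * w * C)
  R * zc / (R + zc)
}

# single layer whose lumped equivalent is exactly R parallel C for a given
# geometric factor: R = 1/(sigma*g), C = eps0*eps_r*g
rc_layer_material <- function(R, C, g) {
  const_material("rc_layer", eps_r = C / (EPS0_T * g), sigma = 1 / (R * g))
}

# closed-form periodic response of source -- Rs -- (R || C) to an ideal
# square pulse of amplitude V, width W, period T (edge ramps ignored).
# Returns the source current i(t) = (v_src - v_c)/Rs at times t in [0, T).
rc_transient_current_oracle <- function(t, V, W, T, Rs, R, C) {
  tau <- C * Rs * R / (Rs + R)
  vss <- V * R / (R + Rs)            # capacitor voltage plateau while on
  # periodic steady state: v0 at pulse start, vW at pulse end
  eon <- exp(-W / tau); eoff <- exp(-(T - W) / tau)
  # vW = vss + (v0 - vss) eon ; v0 = vW eoff
  vW <- vss * (1 - eon) / (1 - eon * eoff)
  v0 <- vW * eoff
  vc <- ifelse(t < W,
               vss + (v0 - vss) * exp(-t / tau),
               vW * exp(-(t - W) / tau))
  src <- ifelse(t < W, V, 0)
  (src - vc) / Rs
}

# standard two-layer-over-infinite test stack with constant materials
two_layer_body <- function(eps1, sig1, h1, eps2, sig2, gel = 0, g2 = 0.01,
                           if_scale = 1) {
  layered_body(list(tissue_layer(const_material("top", eps1, sig1), h1),
                    tissue_layer(const_material("bottom", eps2, sig2),
                                 infinite = TRUE)),
               gel_ohms = gel, g2 = g2, if_scale = if_scale)
}

# calibrated synthetic forearm shared by network/stimulation/acceptance
# tests (calibration anchored once at a 30 kOhm low-frequency total)
calibrated_forearm <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      b <- forearm_body()
      b$if_scale <- as.numeric(calibrate_if_scale(b, 30e3, frequency = 0.1))
      memo <<- b
    }
    memo
  }
})
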