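---
title: "Modelling layered-body impedance and stimulation response with tissue-property-based equivalent circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling layered-body impedance and stimulation response with tissue-property-based equivalent circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpbecm)
```

## The modelling problem

Transcutaneous electrical nerve stimulation (TENS) drives pulsed currents
through a stack of electrically very different tissues: a thin, poorly
conducting skin layer, a fat layer, and a highly conductive muscle bulk.
Classical equivalent circuit models (ECMs) of this system use lumped R and C
values fitted to measured impedance, which makes them non-parametric: a
change in skin thickness or tissue permittivity cannot be propagated into
the circuit. `tpbecm` implements the alternative — a *tissue-property-based*
ECM whose every element is an explicit function of conductivity,
permittivity and layer thickness — so that inter-individual variability in
those physical properties maps directly onto impedance and pulse-response
predictions.

## The complex-capacitor abstraction

Each tissue layer is represented by one *complex capacitor*.  With the
engineering sign convention $e^{+j\omega t}$, the complex permittivity

$$\varepsilon^*(\omega) = \varepsilon - j\,\frac{\sigma}{\omega}$$

fuses the layer's dielectric and conductive behaviour, and a layer with
geometric factor $g = C/\varepsilon$ (metres; $A/d$ for a parallel plate)
becomes the element $C^* = \varepsilon^* g$, whose impedance
$Z = 1/(j\omega C^*)$ is exactly the parallel combination of
$R = 1/(\sigma g)$ and $C = \varepsilon g$.  The package keeps everything in
SI units internally (F/m, S/m, m, Hz); relative permittivity appears only at
I/O boundaries and inside the regression arguments described below.

Because $\varepsilon^*$ diverges at DC, all network algebra is carried in
the admittance-form twin $\kappa^*(\omega) = j\omega\varepsilon^* =
\sigma + j\omega\varepsilon$, which is finite at $\omega = 0$ and reduces to
the conductivity there.  The DC bin of the pulse synthesis therefore sees a
purely resistive network without any special casing; the one exception is a
parallel (PPC) interface, whose correction factor diverges logarithmically
at DC — attempting a DC evaluation of such a stack is an error rather than a
silently wrong number.

Materials are either *tabulated* (a strictly increasing frequency grid with
$\varepsilon_r$ and $\sigma$ columns; interpolation is linear in
log-frequency, and evaluation outside the grid is an error, never an
extrapolation) or *parametric* Cole–Cole models

$$\varepsilon_r^*(\omega) = \varepsilon_\infty + \sum_k
  \frac{\Delta\varepsilon_k}{1 + (j\omega\tau_k)^{1-\alpha_k}}
  - j\frac{\sigma_s}{\omega\varepsilon_0},$$

optionally with an explicit upper validity bound that is enforced the same
way as a table edge.

## Partial capacitance and the interdimensional factor

The partial-capacitance (PC) method decomposes the total capacitance of a
layered structure into per-layer capacitors.  The branch is decided by the
permittivity-magnitude ratio at each interface:

* **PPC** (parallel): $|\varepsilon_1^*| > |\varepsilon_2^*|$ — field lines
  shunt along the high-permittivity upper layer;
  $C = (\varepsilon_1 - \varepsilon_2)\,I + C_{below}$.
* **SPC** (serial): $|\varepsilon_1^*| < |\varepsilon_2^*|$ — the field
  penetrates the upper layer;
  $1/C = (1/\varepsilon_1 - 1/\varepsilon_2)/I + 1/C_{below}$.

$C_{below}$ is $\varepsilon_2 g_2$ for an effectively infinite bottom layer
(a bottom layer at least ten times thicker than the one above it; thinner
bottoms trigger an advisory warning).  An $N$-layer stack is reduced
recurrently: the bottom pair is composed first and the result stands in for
the $\varepsilon_2 g_2$ term of the next interface up.  The per-layer
partial capacitors produced along the way are the elements of the impedance
network; for an all-SPC stack their impedances sum exactly to the total.

The plain 2D PC formulas acquire secondary errors when applied to real 3D
electrode geometries.  The *interdimensional factor* (IF) replaces the
upper layer's geometric factor with a regressed correction:

$$I_{PPC} = a_0 + a_1 \ln|\Delta\varepsilon_r| + a_2 \ln h_1, \qquad
  I_{SPC} = \frac{b_0 + b_1 \ln(\varepsilon_{2r}/\varepsilon_{1r})}{h_1} + c_0,$$

with $h_1$ in **millimetres** and the permittivity arguments **relative**
and dimensionless.  The shipped default triples are
$(a_0,a_1,a_2) = 10^{-3}(4.69, 1.12, 4.40)$ and
$(b_0,b_1,c_0) = 10^{3}(2.83, 1.00, 1.30)$.

Three notational decisions deserve a record:

* The parallel branch requires $\varepsilon_1 > \varepsilon_2$, so the
  logarithm's argument is taken as $|\Delta\varepsilon_r|$ (a difference
  ordered the other way would be negative and the regression was plotted
  against a positive difference axis).
* With complex (lossy) layers the log and ratio arguments use complex
  magnitudes, keeping the IF real; the complex character of the layers
  enters through the $(\varepsilon_1 - \varepsilon_2)$ and
  $1/\varepsilon$ terms of the composition itself.  The coefficients were
  fitted on real permittivities, so a complex log would attribute phase
  structure to a model that never saw any.
* Pairs equal in magnitude within a relative tolerance of $10^{-9}$ are
  *homogeneous*: the upper layer merges into the structure below
  ($C \to C_{below}$), which is also the analytic limit of both branches as
  $\varepsilon_1 \to \varepsilon_2$.  The classification is per frequency;
  if an interface changes branch across a grid, the composition follows the
  per-frequency class and a crossover warning names the frequencies.

### The unresolved absolute unit, and calibration

The PPC and SPC coefficient sets differ in scale by roughly $10^5$–$10^6$,
and no single unit convention reconciles them with SI geometric factors.
The package therefore treats the IF unit as an open calibration question: a
single multiplicative scale factor (default 1) travels with every
composition, and `calibrate_if_scale()` solves for the value that makes a
body's total impedance magnitude match one reference value at one
frequency.  All forearm-level magnitudes downstream are conditional on that
one-time calibration; the bottom layer's $\varepsilon g_2$ term is genuinely
SI and does not carry the IF unit, which is the main reason deep-layer
magnitudes are harder to place than skin-path ones.

The bottom geometric factor $g_2$ itself has two providers: a direct
numeric value (used when given), or a conformal-mapping estimate for two
coplanar strip electrodes over a half-space,
$g_2 = \tfrac{L}{2}\,K(k')/K(k)$ with $k = s/(s + 2w)$ and $K$ the complete
elliptic integral of the first kind — about $7.8\times10^{-3}$ m for the
standard 1 cm electrodes separated by 1 cm.

## Refitting the IF: regression design

`fit_if()` is the package's central fitting function.  Each
$(h_1, \varepsilon_1, \varepsilon_2, C_{tot})$ row is first transformed to
the *observed Layer-1 geometric factor* — the exact algebraic inverse of
the composition (for SPC,
$(1/\varepsilon_1 - 1/\varepsilon_2)\,/\,(1/C - 1/(\varepsilon_2 g_2))$) —
and the IF model is then fitted by ordinary least squares on its exact
linear-in-coefficients form (regressors $1, \ln\Delta\varepsilon, \ln h_1$
for PPC; $1/h_1, \ln(r)/h_1, 1$ for SPC).  No nonlinear optimiser, hence no
initialisation or convergence question; rank-deficient designs are refused
with the collinear regressors named.  The result is a classed model object
with the usual `coef`, `summary`, `predict`, `residuals`, `simulate` and
`plot` methods.

`generate_fem_surrogate()` supplies the datasets a 3D field simulation
campaign would: the full factorial of ten ordered relative-permittivity
pairs per branch (all ordered pairs from $\{10, 20, 30, 40, 50\}$) times
thicknesses $h_1 \in \{2, 4, 6\}$ mm — 30 rows — with responses from the
forward model.  Two generator choices matter:

* **Default bottom GF per kind.** The surrogate's $g_2$ must be
  commensurate with the coefficient scale of its branch, or the bottom term
  swamps the Layer-1 term and the transform amplifies any response noise
  catastrophically (a campaign in that regime could never have identified
  the IF at all).  The default is the conformal half-space estimate for
  PPC and that value $\times 10^5$ — the ratio of the two shipped
  coefficient scales — for SPC.  Noise-free recovery is exact for *any*
  positive $g_2$.
* **Where noise enters.** `noise_on = "capacitance"` perturbs the
  capacitance response; `noise_on = "gf"` perturbs the factor itself, which
  is both the regression's response after the transform and the domain
  where the 2D-to-3D fluctuation error the IF absorbs actually lives.  At
  1 % GF-level noise the coefficient estimates stay within about 4 %
  relative RMSE over replicated designs (design-limited); capacitance-level
  noise is amplified by one plus the bottom-to-layer-term ratio and does
  not admit such a bound.

## The impedance network

`build_network()` evaluates all layer permittivities over a frequency grid
(default: 201 points, log-spaced 0.1 Hz–10 kHz, mirroring a standard
impedance-analyzer protocol), classifies every interface, composes the
per-layer partial capacitors, converts to impedances and appends the
conductive-gel contact resistance (160 Ω for the shipped forearm
configuration) in series.  Thickness sweeps (1–3 mm in 0.5 mm steps for
skin and fat) and uniform permittivity scalings (±20 % in 10 % steps)
return one spectrum per setting and never mutate the input body.

## Pulse response

A stimulation pulse is a periodic trapezoid: amplitude $A$ (1 V or 1 mA
typical), width $W$ (3 ms), repetition frequency $F$ (10 Hz), linear edge
ramps $t_r$ (1 μs).  Its Fourier coefficients have the closed form

$$c_0 = A\,W F, \qquad
  c_k = \frac{A}{T}\,\frac{(1 - e^{-j\omega_k W})
  (1 - e^{-j\omega_k t_r})}{(j\omega_k)^2\,t_r},$$

the network is evaluated at every harmonic frequency $kF$ (DC through the
resistive limit), the response is formed per harmonic — current
$V_k/Z_{tot}$, layer drop $V_k Z_{layer}/Z_{tot}$ in voltage mode, and
$V_k = I_k Z_{tot}$ in current mode — and one period of time traces is
reconstructed by an inverse real FFT on $2K$ uniform samples.  The default
$K = 4096$ harmonics resolves a 3 ms pulse at 10 Hz to 12 μs sampling; when
a material's validity range would be exceeded, $K$ is truncated with a
warning instead of evaluating the material outside its table.  Kirchhoff
closure (layer drops plus gel drop equal the source, per time sample) and
Parseval's identity are exact properties of this construction and are
enforced in the test suite at $10^{-8}$ and $10^{-6}$ relative.

### The dose-map metric

Pulse-parameter sweeps (widths 0.05–5 ms, frequencies 1–300 Hz) need a
scalar "amount of current" per cell, and the choice is not innocent.  The
*peak* current of a voltage pulse through this network is the onset inrush
$V/|Z_{hf}|$, set by the high-frequency impedance — it is nearly
independent of pulse width once the pulse outlasts the network time
constant, and mildly *increasing* with width.  The *mean current during the
pulse* (charge per width) is the quantity that decreases as the pulse
widens, which is the clinically discussed behaviour (short pulses slip
charge through the skin capacitance before the resistive limit takes over).
`dose_map()` therefore defaults to `metric = "mean_pulse"` and exposes
`"peak"` as the alternative.

## Synthetic stand-ins, and what the tests do and do not show

Three inputs of the original workflow are physical or proprietary and are
replaced by labelled synthetic constructions:

* **Agar pair** (`gen_agar_pair()`): DI-water agar vs 10 g/L NaCl agar as
  tabulated materials on the standard grid, conductivities 0.05 and
  1.6 S/m (plausible fixture values — the source prints none), a mild
  low-frequency dispersion on a water-like baseline, and optional seeded
  measurement noise.  The construction guarantees the one property the
  composition logic depends on: the salted magnitude exceeds the pure one
  at every frequency, so salted-on-pure is PPC and pure-on-salted is SPC.
* **Tissue pack** (`synthetic_tissue_pack()`,
  `inst/extdata/tissues_synthetic.json`): Cole–Cole parameters at the
  scale of the standard literature database for gel-moistened skin,
  non-infiltrated subcutaneous fat and skeletal muscle ($\sigma_s$ =
  4.3e-4, 0.01, 0.2 S/m).  It is *not* a transcription of measured data;
  it is constructed once so that
  $|\varepsilon^*_{muscle}| > |\varepsilon^*_{fat}| >
  |\varepsilon^*_{skin}|$ — the all-SPC forearm condition — holds over the
  whole analysis band, with validity capped at 41 kHz (the constructed
  ordering crosses over near 56 kHz).
* **Phantom comparison harness** (`agar_correlation_harness()`): replaces
  the physical measurement side of model validation with a synthetic
  measurement (independent 5 % multiplicative noise on the real and
  imaginary capacitance parts) and checks that model-measurement
  correlations stay above 0.9 in at least 95 % of 200 seeded replicates.

Consequently the passing tests demonstrate the *pipeline*: exact
coefficient recovery, exact circuit identities, correct branch selection,
correct transform algebra, correct harmonic synthesis.  They do not
demonstrate quantitative agreement with any real forearm.  With the scale
factor calibrated once against a 30 kΩ low-frequency total, the synthetic
forearm reproduces skin-path magnitudes (skin ≈ 27.5 kΩ, short-pulse mean
current ≈ 96 μA) within ±30 % of the reference picture, while fat/muscle
magnitudes, the 80 kΩ thickness-sweep extreme and the exact 100 Hz corner
do not all land inside that band — as expected for a stand-in dielectric
table combined with the unresolved IF unit, and recorded as such in the
test suite rather than hidden.

## Numerical choices

* Homogeneous tie tolerance: relative $10^{-9}$ on $|\varepsilon^*|$.
* Interpolation of tables: linear in log-frequency for both
  $\varepsilon_r$ and $\sigma$ (log-grid measurements suggest log-domain
  behaviour; no extrapolation ever).
* IF positivity: a non-positive evaluated IF (inputs far outside the
  calibrated design) composes but warns.
* Calibration: `uniroot` on $\log_{10}$ of the scale over $[10^{-12},
  10^{8}]$, exploiting monotonicity for series stacks.
* Problem sizes in the shipped tests: 201-point spectra, 1000-draw
  equivalence properties, 2048–4096 harmonics, 200-replicate noise and
  correlation studies — sized so the whole suite runs in seconds while
  leaving the asymptotic headroom obvious.

## Known limitations

* No electrode–skin interface element: low-frequency capacitive
  polarisation at the contact is outside the model, and is the usual
  explanation for low-frequency discrepancies against measured spectra.
* One capacitor per layer: no lateral discretisation, no current-density
  maps; fringing effects live entirely inside IF and $g_2$.
* The absolute IF unit is calibrated, not derived; quantitative absolute
  impedances inherit that one degree of freedom.
* PPC stacks have no DC limit (logarithmic divergence of the PPC IF);
  current-mode pulses through a σ = 0 stack are refused as singular.
* Cole–Cole evaluation only — the package deliberately does not fit
  Cole–Cole parameters to measured spectra.
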