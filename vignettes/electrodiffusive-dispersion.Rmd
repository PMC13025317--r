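---
title: "Simulating beta-dispersion with a non-stationary electrodiffusive model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating beta-dispersion with a non-stationary electrodiffusive model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edisim)
```

## The model

Tissue impedance spectra show step-like features ("dispersions") as the
excitation frequency rises. The beta-dispersion, conventionally attributed
to cell-scale polarization, appears where the applied field starts changing
faster than ions inside a cell can redistribute: below that frequency the
cell polarizes fully each cycle and the response amplitude is flat; above
it the polarization no longer catches up and the amplitude rolls off.

`edisim` simulates this with a minimal electrodiffusive model of a single
cell. A dimensionless electric potential $\psi(x, y, t)$ evolves on a
rectangular domain according to

$$\frac{\partial \psi}{\partial t} = \nabla^2 \psi
  \;-\; \kappa^2 \sinh \psi \;+\; w(x)\, s(t),$$

which bridges the stationary Poisson–Boltzmann equation (set the left side
to zero) and the plain diffusion equation ($\kappa = 0$, no drive). The
three right-hand terms are:

* **Diffusion** $\nabla^2\psi$ — ionic redistribution; in physical units
  the right-hand side is multiplied by a diffusion constant $D$, which
  here sets the (dimensionless) time scale.
* **Screening** $-\kappa^2 \sinh\psi$ — the nonlinear Boltzmann response
  of mobile charge. $1/\kappa$ plays the role of a Debye length: larger
  $\kappa$ means stronger screening, shallower field penetration, weaker
  response.
* **Drive** $w(x)\,s(t)$ — the external field enters through the left
  edge with harmonic time dependence $s(t) = A \sin(2\pi f t)$ and spatial
  weight $w(i) = 1 - \ln(1+i)/\ln(n_x)$, a log-smoothed stand-in for an
  edge impulse ($w$ is 1 at the left edge, strictly decreasing, 0 at the
  right edge).

Boundaries are zero-flux: the five-point Laplacian uses first-order mirror
ghost points (the value outside the border equals the adjacent border
value). This makes the discrete Laplacian sum to zero over the domain, so
unforced, unscreened dynamics conserve the field mean exactly — a property
the test suite checks to $10^{-10}$.

After every step the field is re-centred to zero spatial mean ("zero-mean"
normalization). The physical statement behind it is that the total charge
density in the closed domain stays constant; since the linearized charge
density is proportional to $\sinh\psi \approx \psi$, zero mean is the
simplest condition consistent with that, it is idempotent, and it changes
the dynamics only by a spatially uniform shift. Two alternatives we
considered but did not adopt: conserving $\sum \sinh\psi$ exactly
(nonlinear, requires an implicit correction), and per-subdomain
conservation (only meaningful once impermeable internal structures exist,
which are out of scope). `normalization = "none"` is exposed for
experiments; note that without normalization a drive profile with nonzero
mean pumps the spatially uniform mode, which for small $\kappa$ grows
essentially unchecked at low frequency.

The readout is the mean of $\psi$ over the right-edge column — the far side
of the domain, reflecting the end result of polarization. A column mean is
used rather than a corner sample because it is insensitive to the parity of
$n_y$ and averages residual noise.

## Numerical scheme and its parameters

The integrator is explicit Euler. Relevant parameters, defaults, units:

| parameter | meaning | default | notes |
|---|---|---|---|
| `nx, ny` | domain cells | 50 × 20 | the single-cell domain size |
| `h` | grid spacing (numerical length) | 1 | scale factors map to physical units at reporting time only |
| `kappa` | screening, 1/length | 0.001 | sweep range 0.001–0.005 |
| `amplitude` | drive amplitude, dimensionless | 0.01 | keeps $\sinh\psi$ near linear on the default domain |
| `dt` | time step | `0.2 * h^2/4` | hard error above the 2-D stability bound $h^2/4$ |
| `normalization` | charge condition | zero-mean | see above |

The stability bound $dt \le h^2/4$ is enforced whenever a step is taken; an
unstable `dt` in a config file is rejected at load time. A separate guard
raises a classed stability error if $|\psi|$ exceeds 30 anywhere: the
hyperbolic sine makes the equation astronomically stiff long before double
precision overflows (near 710), and the model is physically meaningless
well before that.

Initial conditions are IID uniform on $[-0.05, +0.05]$, seeded. A single
root seed deterministically derives per-frequency seeds, so identical
configurations reproduce bit-identical sweeps.

### Reaching and measuring the steady state

The response amplitude at drive frequency $f$ is estimated by a
single-frequency Fourier projection over an integer number of periods:
$\hat A = \tfrac{2}{T}\left|\sum_k y_k e^{-i 2\pi f t_k}\,\Delta t\right|$.
Over integer periods this is exact for a sampled pure tone, exactly
rejects constant offsets, and attenuates residual transients as $1/(2\pi f
T)$ — far more robust than a (max−min)/2 estimate.

Two refinements keep the estimate faithful across the whole frequency
axis, both chosen from linear analysis of the scheme:

* **Sampling**: each period is resolved by at least 32 steps (`dt` is
  reduced below its default where needed). The explicit-Euler bias on a
  resolved mode's response modulus is second order, roughly
  $(2\pi/\text{spp})^2/8 \approx 0.5\%$ at 32 samples per period, which
  keeps the time-domain solver inside the 2% band of the frequency-domain
  oracle.
* **Settling**: the transient window lasts at least `transient_periods`
  (default 5) drive periods *and* at least 4 e-folding times of the
  slowest decaying spatial mode, whose rate is
  $\lambda_1 = 2(1-\cos(\pi/n_x))/h^2 + \kappa^2$. At high frequency a
  period is far shorter than the domain's relaxation time, so
  period-counting alone would measure against a still-decaying random
  start.

Measurement lasts `measure_periods` (default 4) integer periods, extended
so both windows cover at least 200 steps. Each run records the maximum
$|\psi|$ seen, so incipient instability is visible in logs before blow-up.

Each frequency point starts from a fresh seeded initialization rather than
continuing from the previous frequency: results are then independent of
sweep order and trivially parallelizable. Per-point seeds depend only on
the root seed and the frequency index — *not* on $\kappa$ or $n_x$ — so the
curves of a parameter family see identical initial noise point by point and
family comparisons (e.g. amplitude monotonicity in $\kappa$) are made under
common random numbers.

## The linearized oracle

The strongest correctness check in the package plays the nonlinear
time-domain solver against an independent solver built on different
principles. For small drive amplitude, $\sinh\psi \approx \psi$ and the
steady state at drive frequency $f$ satisfies the stationary complex system

$$\left(i\,2\pi f + \kappa^2 - \nabla^2\right)\hat\Psi = A\,\tilde w(x),$$

with the same zero-flux discretization, where $\tilde w = w - \bar w$ under
zero-mean normalization (the per-step mean subtraction is equivalent, in
the linear regime, to driving with the re-centred profile).
`linearized_reference_response()` solves this by a direct sparse solve of
the equivalent real $2n \times 2n$ block system and returns the modulus of
the right-edge mean of $\hat\Psi$. No time stepping, no transient, no
estimator — a genuinely independent route. At $A = 0.01$, $\kappa = 0.001$
the two routes agree to better than 0.3% over four decades of frequency;
the acceptance suite requires 2% over three decades on a 25 × 10 domain.

## Spectra, knees, uncertainty

A simulated sweep or a measured spectrum (`freq_Hz, Zmod_ohm, Zphase_deg`
tabular text; a decimal-comma dialect flag accommodates potentiostat
exports) is analysed with the same tools:

* `log_frequency_grid(fmin, fmax, ppd)` builds the instrument-style grid
  $f_i = f_{\min} 10^{i/\text{ppd}}$; 100 mHz–500 kHz at 10 points per
  decade gives the familiar 67-point layout.
* `detect_dispersion_frequency()` makes the visually identified "departure
  point" operational: the plateau level is the mean of the first $k = 3$
  points (which must agree within the relative tolerance, default 5%, or a
  no-plateau error is raised), and the knee is the lowest frequency whose
  modulus deviates from the plateau by more than the tolerance, refined by
  log-linear interpolation between the bracketing points. A spectrum that
  never departs returns a clearly marked not-found sentinel rather than a
  number. The same rule is applied to simulated and measured curves. A
  mirrored high-frequency-plateau mode exists but is off by default.
* `bode_assemble()` produces the paired $(\log f, \log|Z|)$ and
  $(\log f, \varphi)$ panels as a long-format table. Phase is plotted
  linearly: phases cross zero, so a logarithmic phase axis is ill-defined.
* `synth_debye_spectrum()` generates single-relaxation fixtures
  $Z(f) = R_\infty + \Delta R/(1 + i 2\pi f\tau)$ with seeded
  multiplicative noise. It exists purely as a test stand-in for measured
  data; the package deliberately does no equivalent-circuit fitting.
* `type_b_uncertainty()` combines two uniform-distribution half-widths in
  quadrature, $u = \sqrt{\Delta x^2/3 + \Delta x_e^2/3}$; uncertainties
  are reported at two decimals (1.0 °C and 0.5 °C give 0.65 °C).

For the knee detector the 5% threshold is this package's operational
definition of "departure"; on a noise-free single-relaxation spectrum with
$\Delta R / R_\infty = 0.25$ the analytic 5%-crossing sits at
$x^* = 2\pi f\tau \approx 0.61$, within a factor 2 of the relaxation
frequency $1/(2\pi\tau)$, and the tests verify the detector lands on the
analytic crossing across four decades of $\tau$.

## What the simulations show — and what they do not

Two sweep drivers reproduce the model's qualitative phenomenology:

* `kappa_sweep()` (50 × 20 domain, $\kappa = 0.001 \ldots 0.005$): the
  response amplitude is pointwise non-increasing in $\kappa$ — stronger
  screening, higher effective impedance. The effect is small (the
  screening rate $\kappa^2$ competes with the slowest diffusive rate
  $\lambda_1 \approx 3.9\times10^{-3}$), which is precisely why the
  common-random-numbers seeding matters.
* `domain_sweep()` ($n_x = 25, 50, 100$ at fixed $n_y = 20$): the knee
  frequency falls as the domain lengthens, close to the diffusive
  $1/n_x^2$ scaling ($\approx 8.9\times10^{-4}$, $2.2\times10^{-4}$,
  $5.6\times10^{-5}$ numerical frequency units respectively). Longer
  cells polarize more slowly.

Frequencies here are in cycles per numerical time unit; outputs label them
"Hz" with an explicit `time_per_unit` scale factor (default 1) recorded in
the sidecar, so the labelling is honest and reversible. Calibration of the
length and time scales against a real tissue (cell size from microscopy,
$\tau_\beta$ from a measured knee, ionic strength into $\kappa$) is
exposed only as these two reporting-time factors and is otherwise out of
scope, as are impermeable internal structures, membrane surface effects,
and any mechanism for the low-frequency alpha-dispersion.

The synthetic fixtures and the simulator emulate: a flat low-frequency
plateau with a single roll-off, screening- and size-dependence of that
shape, and instrument-style grids and file layouts. They do not emulate:
electrode polarization artefacts, multiple overlapping dispersions,
measurement noise correlated across frequency, drift during a sweep, or
phase data from the simulator (the model's readout is a real amplitude).
Passing tests therefore validate the solver and the analysis chain, not
any claim that a particular vegetable's spectrum is reproduced
quantitatively.

## Problem sizes and numerical choices in the tests

The test and acceptance runs use the domain sizes above with reduced
transient/measure windows (2 + 2 periods) and, for the two monotonicity
families, `dt = 0.2` (80% of the stability bound): monotonicity
comparisons are insensitive to the small integrator bias, and the slowest
points of those families integrate millions of steps. The oracle
comparison keeps the default `dt = 0.05`, where the integrator bias is far
below the 2% band. Degenerate inputs are rejected loudly and early:
non-plateau spectra, undersampled or non-integer measurement windows,
unstable time steps (at config load, before any computation), non-finite
amplitudes in files (with the offending point named), unknown config keys.

## Limitations

* Explicit Euler only; the cost of a low-frequency point scales as
  $1/(f\,dt)$. The compiled kernel makes this tractable, but a frequency
  two decades below a 100-cell domain's knee is minutes of CPU.
* The knee depends (weakly) on the 5% threshold and the grid density; it
  is an operational estimate of a visually defined feature, not a fitted
  time constant.
* The amplitude–impedance correspondence is qualitative (response down ⇔
  impedance up); no attempt is made to convert amplitudes to ohms.
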