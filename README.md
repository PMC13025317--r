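# edisim

Electrodiffusive simulation of beta-dispersion in impedance spectra.

Biological tissue measured by electric impedance spectroscopy (EIS) shows
step-like "dispersions": below some frequency the cells polarize fully each
cycle and the response is flat; above it the ions inside a cell can no
longer follow the field and the response rolls off. `edisim` is for
computational biophysicists who want a first-principles, mesoscale account
of that beta-dispersion knee — rather than an equivalent-circuit fit — and
for anyone who needs the surrounding EIS plumbing (log frequency grids,
Bode tables, knee detection, type-B uncertainty) in R.

## The model

A dimensionless potential field ψ(x, y, t) on a rectangular domain (a
single cell, default 50 × 20) evolves as

    ∂ψ/∂t = ∇²ψ − κ² sinh ψ + w(x) s(t)

— diffusion, nonlinear Boltzmann screening with inverse-Debye-length
parameter κ, and a harmonic drive s(t) = A sin(2πft) entering through the
left edge with log-decaying weight w(x). Boundaries are zero-flux
(first-order mirror ghosts); the field is re-centred to zero mean each step
(constant total charge); the integrator is explicit Euler (compiled kernel,
with a pure-R reference stepper pinned to it by tests). The simulated
"spectrum" is the steady-state amplitude of the right-edge mean versus
drive frequency, extracted by single-frequency Fourier projection over
integer periods. An independent linearized frequency-domain solver —
`(i2πf + κ² − ∇²)Ψ = A w̃`, one sparse solve, no time stepping — serves as
a correctness oracle for the nonlinear time-domain route.

Two phenomena structure the package: raising κ (stronger ionic screening)
lowers the response amplitude at every frequency, i.e. raises the effective
impedance; and lengthening the domain moves the dispersion knee to lower
frequency, roughly as 1/nx² (longer cells polarize more slowly).

## Worked example

Simulate the 50 × 20 domain across its knee, locate the dispersion
frequency, and cross-check against the linearized oracle:

```r
library(edisim)
grid   <- grid_spec(nx = 50, ny = 20)
params <- model_params(kappa = 0.001, dt = 0.2)
freqs  <- (2 - 2 * cos(pi / 50)) * 10^seq(-2, 0.25, by = 0.25)
proto  <- sweep_protocol(transient_periods = 2, measure_periods = 2, seed = 1)
sw <- frequency_sweep(grid, params, freqs, proto)
data.frame(frequency = signif(sw$frequency, 4), amplitude = signif(sw$amplitude, 4))
#>    frequency amplitude
#> 1  3.947e-05   0.66290
#> 2  7.018e-05   0.66010
#> 3  1.248e-04   0.65120
#> 4  2.219e-04   0.62530
#> 5  3.947e-04   0.55960
#> 6  7.018e-04   0.43620
#> 7  1.248e-03   0.28600
#> 8  2.219e-03   0.16490
#> 9  3.947e-03   0.09080
#> 10 7.018e-03   0.05162
```

The amplitude is flat near 0.66 at low frequency (the cell polarizes fully
every cycle), then rolls off once the drive outruns the diffusive
polarization time. The knee detector makes the departure point
operational — lowest frequency deviating more than 5% from the plateau,
log-interpolated:

```r
detect_dispersion_frequency(sw)
#> <dispersion_estimate> knee at 0.000222223 Hz (plateau 0.658057, rel tol 0.05)
```

(frequencies are in cycles per numerical time unit, labelled Hz under the
default time-scale factor of 1). The independent frequency-domain solve
agrees with the simulation to a fraction of a percent:

```r
max(abs(sw$amplitude / linearized_reference_response(grid, 0.001, 0.01, freqs) - 1))
#> 0.00338
```

The EIS utilities stand alone:

```r
round(type_b_uncertainty(1.0, 0.5), 2)      # thermometer graduation + experimenter
#> 0.65
length(log_frequency_grid(0.1, 5e5, 10))    # 100 mHz - 500 kHz, 10 pts/decade
#> 67
```

A command-line wrapper (`inst/cli/edisim.R`) exposes the same operations as
subcommands (`simulate`, `sweep-kappa`, `sweep-domain`, `analyze`, `synth`,
`grid`) over YAML configs; see `?cli_run`. The methods vignette
(`vignettes/electrodiffusive-dispersion.Rmd`) documents the model,
the steady-state protocol, the knee definition and the design choices.

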