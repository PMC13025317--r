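# Shared small fixtures: grids and protocols small enough that every
# simulation-backed test runs in seconds.

tiny_grid <- function() grid_spec(10L, 6L)

fast_protocol <- function(seed = 1L)
  sweep_protocol(transient_periods = 2, measure_periods = 2, seed = seed)

# Exact modulus-crossing frequency of a noise-free single-relaxation
# spectrum: |Z(x)|^2 = r_inf^2 + (2 r_inf dr + dr^2) / (1 + x^2) with
# x = 2 pi f tau, solved for |Z| = (1 - rel_tol) * (r_inf + dr).
debye_exact_knee <- function(r_inf, delta_r, tau, rel_tol = 0.05) {
  target <- ((1 - rel_tol) * (r_inf + delta_r))^2
  x2 <- (2 * r_inf * delta_r + delta_r^2) / (target - r_inf^2) - 1
  sqrt(x2) / (2 * pi * tau)
}
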