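test_that("log frequency grid matches the instrument layout", {
  g <- log_frequency_grid(0.1, 5e5, 10)
  expect_length(g, 67L)
  expect_identical(g[1L], 0.1)
  expect_true(all(diff(g) > 0))

  expect_length(log_frequency_grid(3.7, 3.7, 10), 1L)

  g2 <- log_frequency_grid(1, 10, 10)
  expect_length(g2, 11L)
  expect_equal(g2[11L], 10)

  expect_error(log_frequency_grid(0, 10, 10), class = "edisim_domain_error")
  expect_error(log_frequency_grid(10, 1, 10), class = "edisim_domain_error")
})

test_that("grid point count equals floor(ppd * log10(fmax/fmin)) + 1", {
  set.seed(7)
  for (rep in 1:25) {
    fmin <- 10^runif(1, -3, 2)
    fmax <- fmin * 10^runif(1, 0, 5)
    ppd <- sample(1:20, 1)
    expect_length(log_frequency_grid(fmin, fmax, ppd),
                  floor(ppd * log10(fmax / fmin) + 1e-9) + 1)
  }
})

test_that("a flat spectrum has no departure point", {
  f <- log_frequency_grid(1, 1e4, 5)
  est <- detect_dispersion_frequency(eis_spectrum(f, rep(2.5, length(f))))
  expect_false(est$found)
  expect_true(is.na(est$knee_frequency))
  expect_equal(est$plateau_level, 2.5)
})

test_that("a step spectrum yields a knee at the interpolated crossing", {
  f <- log_frequency_grid(1, 1e4, 10)
  m <- ifelse(f < 100, 1.0, 0.5)
  est <- detect_dispersion_frequency(eis_spectrum(f, m), rel_tolerance = 0.05)
  expect_true(est$found)
  expect_lt(est$knee_frequency, 100)
  expect_gt(est$knee_frequency, 70)  # between the bracketing grid points
  expect_equal(est$plateau_level, 1.0)
})

test_that("the knee is invariant under modulus rescaling", {
  f <- log_frequency_grid(0.1, 1e3, 8)
  sp <- synth_debye_spectrum(1, 0.25, tau = 0.05, f)
  k1 <- detect_dispersion_frequency(sp)$knee_frequency
  for (c_scale in c(0.01, 3, 1e4)) {
    scaled <- eis_spectrum(sp$frequency, sp$modulus * c_scale, sp$phase)
    expect_equal(detect_dispersion_frequency(scaled)$knee_frequency, k1,
                 tolerance = 1e-12)
  }
})

test_that("detected knees track the analytic crossing over 4 decades of tau", {
  for (tau in 10^c(-5, -3, -1, 0)) {
    fmid <- 1 / (2 * pi * tau)
    f <- log_frequency_grid(fmid * 1e-3, fmid * 1e2, 10)
    sp <- synth_debye_spectrum(100, 25, tau, f)
    est <- detect_dispersion_frequency(sp, rel_tolerance = 0.05)
    expect_true(est$found)
    exact <- debye_exact_knee(100, 25, tau, 0.05)
    # log-linear refinement lands close to the exact threshold crossing
    expect_equal(est$knee_frequency, exact, tolerance = 0.1)
    # and for this shallow dispersion the knee sits within a factor 2 of
    # the relaxation frequency itself
    expect_gt(est$knee_frequency, fmid / 2)
    expect_lt(est$knee_frequency, fmid * 2)
  }
})

test_that("spectra without a plateau or with too few points are rejected", {
  f <- log_frequency_grid(1, 1e3, 3)
  ramp <- eis_spectrum(f, seq(1, 3, length.out = length(f)))
  expect_error(detect_dispersion_frequency(ramp), class = "edisim_no_plateau_error")
  expect_error(detect_dispersion_frequency(eis_spectrum(1:4, rep(1, 4))),
               class = "edisim_domain_error")
})

test_that("high-frequency-plateau mode mirrors the detection", {
  # rising spectrum: flat at high f, departs downward at low f
  f <- log_frequency_grid(0.1, 1e4, 10)
  m <- 1 + 1 / (1 + (f / 10)^2)
  est <- detect_dispersion_frequency(eis_spectrum(f, m), side = "high")
  expect_true(est$found)
  expect_equal(est$plateau_level, 1, tolerance = 1e-3)
  expect_gt(est$knee_frequency, 1); expect_lt(est$knee_frequency, 100)
})

test_that("Bode assembly produces paired log-log and phase panels", {
  f <- log_frequency_grid(1, 100, 5)
  sp10 <- eis_spectrum(f, rep(10, length(f)), label = "flat10")
  tab <- bode_assemble(list(sp10))
  expect_equal(tab$log10_Zmod, rep(1, length(f)))
  expect_equal(tab$log10_f, log10(f))

  sp2 <- eis_spectrum(f, rep(2, length(f)), label = "flat2")
  tab2 <- bode_assemble(list(sp10, sp2))
  expect_identical(unique(tab2$curve_label), c("flat10", "flat2"))
  expect_equal(nrow(tab2), 2L * length(f))

  expect_error(bode_assemble(list()), class = "edisim_empty_error")
  bad <- structure(data.frame(frequency = f, modulus = c(-1, rep(1, length(f) - 1)),
                              phase = rep(0, length(f))),
                   class = c("eis_spectrum", "data.frame"), label = "bad")
  expect_error(bode_assemble(list(bad)), class = "edisim_domain_error")
  expect_error(bode_assemble(list(bad)), "point 1")
})

test_that("synthetic single-relaxation spectra obey the closed form", {
  tau <- 2e-3
  f <- log_frequency_grid(1e-2, 1e6, 10)
  sp <- synth_debye_spectrum(50, 200, tau, f)
  # static limit
  expect_equal(sp$modulus[1L], 250, tolerance = 1e-3)
  expect_equal(sp$phase[1L], 0, tolerance = 0.1)
  # midpoint identity: at f = 1/(2 pi tau), Im(Z - r_inf) = -delta_r / 2
  fm <- 1 / (2 * pi * tau)
  z <- 50 + 200 / (1 + 2i * pi * fm * tau)
  expect_equal(Im(z - 50), -100)
  zf <- complex(modulus = sp$modulus, argument = sp$phase * pi / 180)
  i_near <- which.min(abs(sp$frequency - fm))
  expect_equal(Im(zf[i_near] - 50), -100, tolerance = 3)  # nearest grid point

  # noise is multiplicative, seeded, reproducible
  n1 <- synth_debye_spectrum(50, 200, tau, f, noise_sd = 0.02, seed = 8L)
  n2 <- synth_debye_spectrum(50, 200, tau, f, noise_sd = 0.02, seed = 8L)
  expect_identical(n1$modulus, n2$modulus)
  expect_false(identical(n1$modulus, sp$modulus))
  expect_lt(sd(n1$modulus / sp$modulus), 0.05)

  # detection closes the loop with the generator
  est <- detect_dispersion_frequency(synth_debye_spectrum(100, 25, tau, f))
  expect_gt(est$knee_frequency, fm / 2)
  expect_lt(est$knee_frequency, fm * 2)
})

test_that("type-B uncertainty combines uniform components in quadrature", {
  expect_equal(round(type_b_uncertainty(1.0, 0.5), 2), 0.65)
  expect_equal(type_b_uncertainty(1.0, 0.5), sqrt(1 / 3 + 0.25 / 3))
  expect_identical(type_b_uncertainty(0, 0), 0)
  expect_equal(type_b_uncertainty(1.0, 0), sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(type_b_uncertainty(1.0, 0), 0.5774, tolerance = 1e-4)
  expect_error(type_b_uncertainty(-1, 0.5), class = "edisim_domain_error")
})
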