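test_that("weight profile peaks at the left edge and decays log-like to zero", {
  for (nx in c(3L, 10L, 50L)) {
    g <- grid_spec(nx, 5L)
    w <- make_weight_profile(g)
    expect_length(w, nx)
    expect_identical(w[1L], 1)
    expect_equal(w[nx], 0)
    expect_true(all(diff(w) < 0))
    expect_true(all(w >= 0 & w <= 1))
  }
  # hand evaluation of the profile at an interior cell
  w50 <- make_weight_profile(grid_spec(50L, 5L))
  expect_equal(w50[10L], 1 - log(10) / log(50), tolerance = 1e-12)
  expect_equal(w50[10L], 0.4114, tolerance = 1e-4)
})

test_that("invalid grids are rejected with a grid error", {
  expect_error(grid_spec(2L, 5L), class = "edisim_grid_error")
  expect_error(grid_spec(10L, 2L), class = "edisim_grid_error")
  expect_error(grid_spec(10L, 5L, h = 0), class = "edisim_grid_error")
  expect_error(make_weight_profile(list(nx = 50)), class = "edisim_grid_error")
})

test_that("harmonic forcing follows A sin(2 pi f t)", {
  g <- tiny_grid()
  spec <- forcing_spec(g, frequency = 2, amplitude = 0.3)
  expect_equal(forcing_value(0, spec), 0)
  expect_equal(forcing_value(1 / (4 * 2), spec), 0.3)
  expect_equal(forcing_value(0.37, spec), 0.3 * sin(2 * pi * 2 * 0.37))
  zero_f <- forcing_spec(g, frequency = 0, amplitude = 0.3)
  expect_equal(forcing_value(c(0, 0.1, 5), zero_f), c(0, 0, 0))
})

test_that("zero-flux Laplacian annihilates constants and reproduces the stencil", {
  g <- tiny_grid()
  const <- field_state(matrix(3.7, g$nx, g$ny))
  expect_equal(laplacian_neumann(const, g), matrix(0, g$nx, g$ny))

  spike <- matrix(0, g$nx, g$ny)
  spike[5L, 3L] <- 1
  lap <- laplacian_neumann(field_state(spike), g)
  expect_equal(lap[5L, 3L], -4)
  expect_equal(lap[4L, 3L], 1); expect_equal(lap[6L, 3L], 1)
  expect_equal(lap[5L, 2L], 1); expect_equal(lap[5L, 4L], 1)
  expect_equal(sum(abs(lap)), 8)
})

test_that("zero-flux Laplacian sums to zero for arbitrary fields", {
  g <- grid_spec(10L, 7L)
  set.seed(42)
  for (rep in 1:10) {
    psi <- matrix(rnorm(g$nx * g$ny), g$nx, g$ny)
    expect_lt(abs(sum(laplacian_neumann(field_state(psi), g))), 1e-10)
  }
  expect_error(laplacian_neumann(field_state(matrix(0, 4, 4)), g),
               class = "edisim_dim_error")
})

test_that("charge normalization subtracts the mean, idempotently", {
  g <- tiny_grid()
  psi <- matrix(runif(g$nx * g$ny), g$nx, g$ny) + 0.3
  st <- field_state(psi)
  expect_identical(normalize_charge(st, "none")$psi, psi)
  z <- normalize_charge(st, "zero-mean")
  expect_equal(mean(z$psi), 0, tolerance = 1e-14)
  expect_equal(z$psi - min(z$psi), psi - min(psi))  # deviations preserved
  expect_equal(normalize_charge(z, "zero-mean")$psi, z$psi)
})

test_that("random initial field is uniform on [-0.05, 0.05] and seed-reproducible", {
  g <- grid_spec(50L, 20L)
  f1 <- init_field(g, 123L)
  f2 <- init_field(g, 123L)
  expect_identical(f1$psi, f2$psi)
  expect_identical(f1$t, 0)
  expect_true(all(abs(f1$psi) <= 0.05))
  expect_false(identical(init_field(g, 124L)$psi, f1$psi))

  # aggregate moments over 100 seeded draws (1e5 entries):
  # uniform(-a, a) has mean 0, sd a/sqrt(3)
  draws <- unlist(lapply(1:100, function(s) init_field(g, s)$psi))
  se <- 0.05 / sqrt(3) / sqrt(length(draws))
  expect_lt(abs(mean(draws)), 3 * se)

  # the session RNG stream is not disturbed
  set.seed(99); a <- runif(3)
  set.seed(99); init_field(g, 5L); b <- runif(3)
  expect_identical(a, b)
})

test_that("euler step fixed points: zero and uniform unforced fields", {
  g <- tiny_grid()
  f0 <- forcing_spec(g, frequency = 0.1, amplitude = 0)
  p <- model_params(kappa = 0.2, normalization = "none")
  st <- field_state(matrix(0, g$nx, g$ny))
  for (i in 1:5) st <- euler_step(st, g, p, f0)
  expect_equal(st$psi, matrix(0, g$nx, g$ny))

  p0 <- model_params(kappa = 0, normalization = "none")
  stc <- field_state(matrix(0.4, g$nx, g$ny))
  out <- euler_step(stc, g, p0, f0)
  expect_equal(out$psi, matrix(0.4, g$nx, g$ny))
  expect_equal(out$t, 0.2 * stability_dt(g))  # auto dt: a fifth of the bound
})

test_that("euler step matches the exact sinh sink on a uniform field", {
  g <- tiny_grid()
  p <- model_params(kappa = 0.1, dt = 0.1, normalization = "none")
  f0 <- forcing_spec(g, frequency = 0.1, amplitude = 0)
  st <- field_state(matrix(0.01, g$nx, g$ny))
  out <- euler_step(st, g, p, f0)
  exact <- 0.01 - 0.1 * 0.1^2 * sinh(0.01)
  expect_equal(out$psi[3, 3], exact, tolerance = 1e-15)
  # sinh(x) ~ x for small x: the linearized decay factor agrees closely
  expect_equal(out$psi[3, 3], 0.01 * (1 - 0.1 * 0.1^2), tolerance = 1e-7)
})

test_that("unstable configurations raise stability errors", {
  g <- tiny_grid()
  f0 <- forcing_spec(g, frequency = 0.1, amplitude = 0)
  expect_error(
    euler_step(init_field(g, 1L), g, model_params(dt = 1), f0),
    class = "edisim_stability_error")
  # a field near the sinh guard blows past it in one step
  p <- model_params(kappa = 1, dt = 0.05, normalization = "none")
  st <- field_state(matrix(29, g$nx, g$ny))
  expect_error(euler_step(st, g, p, f0), class = "edisim_stability_error")
  expect_error(run_model(st, g, p, f0, 5L), class = "edisim_stability_error")
})

test_that("compiled kernel reproduces the R reference stepper", {
  g <- tiny_grid()
  p <- model_params(kappa = 0.05, amplitude = 0.02, dt = 0.04)
  fr <- forcing_spec(g, frequency = 0.3, amplitude = 0.02)
  st_r <- st0 <- init_field(g, 77L)
  for (i in 1:25) st_r <- euler_step(st_r, g, p, fr)
  out <- run_model(st0, g, p, fr, 25L, record = TRUE)
  expect_equal(out$state$psi, st_r$psi, tolerance = 1e-12)
  expect_equal(out$state$t, st_r$t, tolerance = 1e-12)
  expect_length(out$edge, 25L)
  expect_equal(out$edge[25L], mean(st_r$psi[g$nx, ]), tolerance = 1e-12)
})

test_that("unforced dynamics conserve the mean and relax the maximum", {
  g <- grid_spec(20L, 12L)
  p <- model_params(kappa = 0, normalization = "none")
  f0 <- forcing_spec(g, frequency = 0, amplitude = 0)
  st <- init_field(g, 3L)
  m0 <- mean(st$psi)
  out <- run_model(st, g, p, f0, 2000L)
  expect_equal(mean(out$state$psi), m0, tolerance = 1e-10)

  # discrete maximum principle + odd monotone sink: max|psi| non-increasing
  p2 <- model_params(kappa = 0.3, dt = 0.9 * stability_dt(g), normalization = "none")
  st <- init_field(g, 4L)
  prev <- max(abs(st$psi))
  for (chunk in 1:10) {
    out <- run_model(st, g, p2, f0, 20L)
    expect_lte(out$max_abs_psi, prev + 1e-14)
    st <- out$state
    prev <- max(abs(st$psi))
  }
})

test_that("field snapshots dump as plain text, one row per y-line", {
  g <- tiny_grid()
  st <- init_field(g, 9L)
  path <- withr::local_tempfile(fileext = ".txt")
  write_field(st, path)
  m <- as.matrix(utils::read.table(path))
  expect_equal(unname(m), unname(t(st$psi)), tolerance = 1e-12)
})
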