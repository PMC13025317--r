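#' Computational grid specification
#'
#' Defines the rectangular computational domain: `nx` cells along the
#' horizontal (the direction of field penetration, drive on the left edge,
#' readout on the right), `ny` cells along the vertical, spacing `h` in
#' numerical length units.
#'
#' @param nx integer, horizontal cell count (>= 3). Default 50, the domain
#'   length used for the single-cell simulations.
#' @param ny integer, vertical cell count (>= 3). Default 20.
#' @param h grid spacing in numerical length units (> 0). Default 1.
#' @return An object of class `"edisim_grid"`.
#' @examples
#' g <- grid_spec(50, 20)
#' g
#' @export
grid_spec <- function(nx = 50L, ny = 20L, h = 1) {
  if (length(nx) != 1L || !is.finite(nx) || nx != round(nx) || nx < 3)
    stop_edisim("edisim_grid_error", sprintf("nx must be an integer >= 3, got %s", format(nx)))
  if (length(ny) != 1L || !is.finite(ny) || ny != round(ny) || ny < 3)
    stop_edisim("edisim_grid_error", sprintf("ny must be an integer >= 3, got %s", format(ny)))
  if (length(h) != 1L || !is.finite(h) || h <= 0)
    stop_edisim("edisim_grid_error", "h must be a positive number")
  structure(list(nx = as.integer(nx), ny = as.integer(ny), h = as.numeric(h)),
            class = "edisim_grid")
}

#' @export
print.edisim_grid <- function(x, ...) {
  cat(sprintf("<edisim_grid> %d x %d cells, h = %g\n", x$nx, x$ny, x$h))
  invisible(x)
}

#' Largest stable explicit-Euler time step
#'
#' The 2D explicit Euler diffusion scheme is stable for `dt <= h^2/4`; the
#' screening sink only adds damping and does not relax the bound.
#'
#' @param grid an [grid_spec()] object.
#' @return The stability bound `h^2 / 4` in numerical time units.
#' @export
stability_dt <- function(grid) {
  stopifnot(inherits(grid, "edisim_grid"))
  grid$h^2 / 4
}

#' Model parameters fixed over one simulation run
#'
#' @param kappa screening parameter (inverse numerical length, >= 0); its
#'   inverse plays the role of a Debye length. Larger `kappa` means stronger
#'   ionic screening and weaker field penetration. Default 0.001, the lower
#'   end of the screening sweep.
#' @param amplitude dimensionless forcing amplitude `A`. Default 0.01, small
#'   enough that the hyperbolic-sine screening term stays near its linear
#'   regime on the default domain.
#' @param dt time step in numerical time units, or `NULL` (default) to
#'   resolve `0.2 * h^2 / 4` against the grid at run time — one fifth of the
#'   explicit-Euler stability bound. Values beyond `h^2/4` are rejected when
#'   the stepper is invoked.
#' @param normalization either `"zero-mean"` (default; subtract the domain
#'   mean of psi after every step, keeping total linearized charge density
#'   constant) or `"none"`.
#' @return An object of class `"edisim_params"`.
#' @examples
#' model_params(kappa = 0.003)
#' @export
model_params <- function(kappa = 0.001, amplitude = 0.01, dt = NULL,
                         normalization = c("zero-mean", "none")) {
  normalization <- match.arg(normalization)
  if (length(kappa) != 1L || !is.finite(kappa) || kappa < 0)
    stop_edisim("edisim_domain_error", "kappa must be a finite number >= 0")
  if (length(amplitude) != 1L || !is.finite(amplitude))
    stop_edisim("edisim_domain_error", "amplitude must be a finite number")
  if (!is.null(dt) && (length(dt) != 1L || !is.finite(dt) || dt <= 0))
    stop_edisim("edisim_domain_error", "dt must be NULL or a positive number")
  structure(list(kappa = as.numeric(kappa), amplitude = as.numeric(amplitude),
                 dt = if (is.null(dt)) NULL else as.numeric(dt),
                 normalization = normalization),
            class = "edisim_params")
}

#' @export
print.edisim_params <- function(x, ...) {
  cat(sprintf("<edisim_params> kappa = %g, amplitude = %g, dt = %s, normalization = %s\n",
              x$kappa, x$amplitude,
              if (is.null(x$dt)) "auto (0.2 * h^2/4)" else format(x$dt),
              x$normalization))
  invisible(x)
}

# Resolve the possibly-NULL dt of a params object against a grid, enforcing
# the stability bound.
resolve_dt <- function(params, grid) {
  bound <- stability_dt(grid)
  dt <- if (is.null(params$dt)) 0.2 * bound else params$dt
  if (dt > bound * (1 + 1e-12))
    stop_edisim("edisim_stability_error",
                sprintf("dt = %g exceeds the explicit-Euler stability bound h^2/4 = %g",
                        dt, bound))
  dt
}

#' Spatial weight profile of the external forcing
#'
#' The drive enters the domain through a fixed spatial profile that is
#' maximal (1) at the left edge and decays logarithmically to 0 at the right
#' edge — a log-smoothed stand-in for a Dirac impulse at the boundary that
#' improves numerical convergence:
#' `w(i) = 1 - log(1 + i) / log(nx)` for cell index `i = 0 ... nx-1`.
#'
#' @param grid an [grid_spec()] object.
#' @return Numeric vector of length `nx` with values in `[0, 1]`, strictly
#'   decreasing, `w[1] = 1`, `w[nx] = 0`.
#' @examples
#' w <- make_weight_profile(grid_spec(50, 20))
#' w[1]; w[50]
#' @export
make_weight_profile <- function(grid) {
  if (!inherits(grid, "edisim_grid"))
    stop_edisim("edisim_grid_error", "grid must be an edisim_grid object")
  i <- seq_len(grid$nx) - 1
  w <- 1 - log(1 + i) / log(grid$nx)
  pmin(pmax(w, 0), 1)
}

#' Harmonic forcing specification
#'
#' Bundles the temporal drive `s(t) = A sin(2 pi f t)` with the spatial
#' weight `w(x)` it is applied through.
#'
#' @param grid an [grid_spec()] object (sets the weight length).
#' @param frequency drive frequency in cycles per numerical time unit (>= 0).
#' @param amplitude dimensionless drive amplitude `A`.
#' @param weight optional length-`nx` profile with entries in `[0, 1]` whose
#'   first entry is its maximum; defaults to [make_weight_profile()].
#' @return An object of class `"edisim_forcing"`.
#' @export
forcing_spec <- function(grid, frequency, amplitude,
                         weight = make_weight_profile(grid)) {
  stopifnot(inherits(grid, "edisim_grid"))
  if (length(frequency) != 1L || !is.finite(frequency) || frequency < 0)
    stop_edisim("edisim_domain_error", "frequency must be a finite number >= 0")
  if (length(weight) != grid$nx)
    stop_edisim("edisim_dim_error",
                sprintf("weight has length %d but grid has nx = %d", length(weight), grid$nx))
  if (any(weight < 0 | weight > 1))
    stop_edisim("edisim_domain_error", "weight entries must lie in [0, 1]")
  if (weight[1L] < max(weight))
    stop_edisim("edisim_domain_error", "weight must attain its maximum at the left edge")
  structure(list(frequency = as.numeric(frequency), amplitude = as.numeric(amplitude),
                 weight = as.numeric(weight)),
            class = "edisim_forcing")
}

#' Instantaneous forcing value
#'
#' `s(t) = A sin(2 pi f t)`. With the sine convention the drive starts at 0,
#' and a zero frequency yields no drive at any time.
#'
#' @param t time in numerical time units.
#' @param spec an [forcing_spec()] object.
#' @return The scalar drive value at time `t` (vectorized over `t`).
#' @export
forcing_value <- function(t, spec) {
  stopifnot(inherits(spec, "edisim_forcing"))
  spec$amplitude * sin(2 * pi * spec$frequency * t)
}

#' Random initial field
#'
#' Draws every cell independently from the uniform distribution on
#' `[-0.05, +0.05]` and sets the clock to zero. Equal seeds give bit-equal
#' fields. The RNG state of the session is left untouched.
#'
#' @param grid an [grid_spec()] object.
#' @param seed integer seed.
#' @return An object of class `"edisim_field"`: a list with `psi`, an
#'   `nx x ny` matrix (rows index x), and elapsed time `t`.
#' @export
init_field <- function(grid, seed) {
  stopifnot(inherits(grid, "edisim_grid"))
  psi <- withr_seed(seed, function() {
    matrix(stats::runif(grid$nx * grid$ny, -0.05, 0.05), nrow = grid$nx, ncol = grid$ny)
  })
  field_state(psi, t = 0)
}

# Evaluate fn() under a temporary RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  fn()
}

#' Construct a field state
#'
#' @param psi numeric matrix of potentials, rows indexing x.
#' @param t elapsed time in numerical time units.
#' @return An object of class `"edisim_field"`.
#' @export
field_state <- function(psi, t = 0) {
  if (!is.matrix(psi) || !is.numeric(psi))
    stop_edisim("edisim_dim_error", "psi must be a numeric matrix")
  if (!all(is.finite(psi)))
    stop_edisim("edisim_stability_error", "psi contains non-finite entries")
  structure(list(psi = psi, t = as.numeric(t)), class = "edisim_field")
}

#' @export
print.edisim_field <- function(x, ...) {
  cat(sprintf("<edisim_field> %d x %d, t = %g, mean = %.3e, max|psi| = %.3e\n",
              nrow(x$psi), ncol(x$psi), x$t, mean(x$psi), max(abs(x$psi))))
  invisible(x)
}

#' Five-point Laplacian with zero-flux boundaries
#'
#' Discrete Laplacian `(psiE + psiW + psiN + psiS - 4 psiC) / h^2` where
#' ghost points outside the border take the value of the adjacent border
#' point (first-order mirror): the potential outside the border is
#' approximated by the border value, giving zero normal flux. With these
#' ghosts the Laplacian sums to zero over the domain (discrete divergence
#' theorem), so unforced, unscreened dynamics conserve the field mean.
#'
#' @param state an [field_state()] object.
#' @param grid an [grid_spec()] object matching the field shape.
#' @return An `nx x ny` numeric matrix.
#' @export
laplacian_neumann <- function(state, grid) {
  stopifnot(inherits(state, "edisim_field"), inherits(grid, "edisim_grid"))
  psi <- state$psi
  if (nrow(psi) != grid$nx || ncol(psi) != grid$ny)
    stop_edisim("edisim_dim_error",
                sprintf("field is %d x %d but grid is %d x %d",
                        nrow(psi), ncol(psi), grid$nx, grid$ny))
  nx <- grid$nx; ny <- grid$ny
  # mirror ghosts: shifted copies clamped at the border
  west  <- psi[c(1L, seq_len(nx - 1L)), , drop = FALSE]
  east  <- psi[c(seq_len(nx - 1L) + 1L, nx), , drop = FALSE]
  south <- psi[, c(1L, seq_len(ny - 1L)), drop = FALSE]
  north <- psi[, c(seq_len(ny - 1L) + 1L, ny), drop = FALSE]
  (east + west + north + south - 4 * psi) / grid$h^2
}

#' Charge-density normalization
#'
#' The model keeps the total charge density constant by re-centering the
#' potential after every step: in `"zero-mean"` mode the spatial mean of psi
#' is subtracted from every cell (the linearized charge density is
#' proportional to `sinh(psi) ~ psi`, so a zero-mean field carries zero net
#' linearized charge). `"none"` is the identity, exposed for experiments.
#' The operation is idempotent.
#'
#' @param state an [field_state()] object.
#' @param mode `"zero-mean"` or `"none"`.
#' @return The normalized [field_state()].
#' @export
normalize_charge <- function(state, mode = c("zero-mean", "none")) {
  mode <- match.arg(mode)
  stopifnot(inherits(state, "edisim_field"))
  if (mode == "none") return(state)
  field_state(state$psi - mean(state$psi), t = state$t)
}

# Shared blow-up guard threshold: sinh is astronomically stiff long before
# double overflow; the model is meaningless by |psi| = 30.
PSI_GUARD <- 30

#' Advance the field one explicit-Euler step
#'
#' One step of `psi <- psi + dt * (laplacian(psi) - kappa^2 sinh(psi) +
#' w(x) s(t))`, followed by charge normalization if enabled; the clock
#' advances by `dt`. This is the pure-R reference stepper; [run_model()]
#' drives the equivalent compiled kernel for long runs.
#'
#' @param state an [field_state()] object.
#' @param grid an [grid_spec()] object.
#' @param params an [model_params()] object; `dt` is resolved against the
#'   grid and checked against the stability bound.
#' @param forcing an [forcing_spec()] object.
#' @return The advanced [field_state()].
#' @export
euler_step <- function(state, grid, params, forcing) {
  stopifnot(inherits(params, "edisim_params"), inherits(forcing, "edisim_forcing"))
  dt <- resolve_dt(params, grid)
  lap <- laplacian_neumann(state, grid)
  s_t <- forcing_value(state$t, forcing)
  psi <- state$psi +
    dt * (lap - params$kappa^2 * sinh(state$psi) + forcing$weight * s_t)
  if (!all(is.finite(psi)) || max(abs(psi)) > PSI_GUARD)
    stop_edisim("edisim_stability_error",
                sprintf("field blew up: max |psi| reached %g at dt = %g",
                        suppressWarnings(max(abs(psi[is.finite(psi)]), 0)), dt))
  out <- field_state(psi, t = state$t + dt)
  normalize_charge(out, params$normalization)
}

#' Advance the field many steps with the compiled kernel
#'
#' Runs `n_steps` explicit-Euler steps in compiled code, optionally
#' recording the right-edge mean after every step. Numerically identical to
#' iterating [euler_step()].
#'
#' @inheritParams euler_step
#' @param n_steps number of steps to take.
#' @param record logical; record the mean of psi over the right-edge column
#'   after each step.
#' @return A list with `state` (the advanced [field_state()]), `edge`
#'   (numeric vector of recorded right-edge means, length `n_steps` if
#'   `record` else 0), and `max_abs_psi` (largest `|psi|` seen, a stability
#'   diagnostic).
#' @export
run_model <- function(state, grid, params, forcing, n_steps, record = FALSE) {
  stopifnot(inherits(state, "edisim_field"), inherits(grid, "edisim_grid"),
            inherits(params, "edisim_params"), inherits(forcing, "edisim_forcing"))
  if (nrow(state$psi) != grid$nx || ncol(state$psi) != grid$ny)
    stop_edisim("edisim_dim_error", "field shape does not match grid")
  dt <- resolve_dt(params, grid)
  res <- tryCatch(
    cpp_run_model(state$psi, grid$h, params$kappa, dt, forcing$amplitude,
                  forcing$frequency, forcing$weight, state$t, as.integer(n_steps),
                  params$normalization == "zero-mean", isTRUE(record)),
    error = function(e) {
      if (grepl("blew up", conditionMessage(e)))
        stop_edisim("edisim_stability_error", conditionMessage(e))
      stop(e)
    }
  )
  list(state = field_state(res$psi, t = res$t),
       edge = as.numeric(res$edge),
       max_abs_psi = res$max_abs_psi)
}

#' Write a field snapshot as plain text
#'
#' Dumps psi as a whitespace-separated numeric grid, one row per y-line
#' (i.e. the transpose of the internal rows-index-x layout), for debugging.
#'
#' @param state an [field_state()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_field <- function(state, path) {
  stopifnot(inherits(state, "edisim_field"))
  utils::write.table(t(state$psi), path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
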