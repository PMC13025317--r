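#' Logarithmic measurement-frequency grid
#'
#' Frequencies with equal spacing in the logarithm, the standard layout of
#' potentiostat frequency-response analysers:
#' `f_i = fmin * 10^(i / ppd)` for `i = 0 ... floor(ppd * log10(fmax/fmin))`.
#' The first point is exactly `fmin`; the last does not exceed `fmax`. The
#' instrument range 100 mHz to 500 kHz at 10 points per decade gives 67
#' points.
#'
#' @param fmin lowest frequency in Hz (> 0).
#' @param fmax highest frequency in Hz (>= fmin).
#' @param points_per_decade points per factor-of-10 of frequency (>= 1).
#' @return Ascending numeric vector of frequencies in Hz.
#' @examples
#' length(log_frequency_grid(0.1, 5e5, 10))  # 67
#' @export
log_frequency_grid <- function(fmin, fmax, points_per_decade = 10L) {
  if (fmin <= 0)
    stop_edisim("edisim_domain_error", "fmin must be > 0")
  if (fmax < fmin)
    stop_edisim("edisim_domain_error", "fmax must be >= fmin")
  if (points_per_decade < 1)
    stop_edisim("edisim_domain_error", "points_per_decade must be >= 1")
  imax <- floor(points_per_decade * log10(fmax / fmin) + 1e-9)
  fmin * 10^((0:imax) / points_per_decade)
}

#' Construct an EIS spectrum record
#'
#' @param frequency strictly increasing positive frequencies in Hz.
#' @param modulus impedance modulus in ohms (or a dimensionless response
#'   amplitude); same length as `frequency`.
#' @param phase phase in degrees in (-180, 180]; negative for capacitive
#'   behaviour. Defaults to zeros when only a modulus curve is available.
#' @param label free-text label.
#' @return An object of class `"eis_spectrum"`: a data frame with columns
#'   `frequency`, `modulus`, `phase`.
#' @export
eis_spectrum <- function(frequency, modulus, phase = rep(0, length(frequency)),
                         label = "spectrum") {
  if (length(frequency) != length(modulus) || length(frequency) != length(phase))
    stop_edisim("edisim_dim_error", "frequency, modulus and phase must have equal lengths")
  if (length(frequency) == 0L)
    stop_edisim("edisim_empty_error", "spectrum is empty")
  if (any(frequency <= 0) || any(diff(frequency) <= 0))
    stop_edisim("edisim_domain_error", "frequencies must be positive and strictly increasing")
  if (any(!is.finite(modulus)))
    stop_edisim("edisim_domain_error", "modulus contains non-finite values")
  if (any(phase <= -180 | phase > 180))
    stop_edisim("edisim_domain_error", "phase must lie in (-180, 180] degrees")
  structure(data.frame(frequency = as.numeric(frequency),
                       modulus = as.numeric(modulus),
                       phase = as.numeric(phase)),
            class = c("eis_spectrum", "data.frame"), label = label)
}

#' @export
print.eis_spectrum <- function(x, ...) {
  cat(sprintf("<eis_spectrum> '%s': %d points, %g Hz - %g Hz\n",
              attr(x, "label"), nrow(x), min(x$frequency), max(x$frequency)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Convert a simulated sweep to an EIS spectrum
#'
#' The simulated response amplitude plays the role of the modulus (note the
#' sample impedance varies inversely with the response amplitude: weaker
#' response means higher impedance); phase is not simulated and set to 0.
#'
#' @param sweep an `"edisim_sweep"` object from [frequency_sweep()].
#' @param time_scale seconds per numerical time unit used to label the
#'   frequency axis in Hz (default 1: numerical frequencies reported as Hz).
#' @return An `"eis_spectrum"` object.
#' @export
as_spectrum <- function(sweep, time_scale = 1) {
  stopifnot(inherits(sweep, "edisim_sweep"))
  eis_spectrum(sweep$frequency / time_scale, sweep$amplitude,
               label = attr(sweep, "label"))
}

#' Detect the dispersion (knee) frequency of a spectrum
#'
#' Operational definition of the "departure point" at which a spectrum
#' leaves its low-frequency plateau: the plateau level is the mean modulus
#' of the first `k` points (which must agree within the relative tolerance,
#' otherwise there is no plateau to depart from); the knee is the lowest
#' frequency where the modulus deviates from the plateau by more than
#' `rel_tolerance * plateau`, refined by interpolating log10(frequency)
#' linearly against the modulus between the bracketing points. With
#' `side = "high"` the mirrored definition is applied from the
#' high-frequency plateau downward.
#'
#' @param spectrum an [eis_spectrum()] (or an `"edisim_sweep"`, converted
#'   via [as_spectrum()]); at least 5 points.
#' @param rel_tolerance relative deviation defining departure, in (0, 1).
#'   Default 0.05.
#' @param k number of points defining the plateau. Default 3.
#' @param side `"low"` (default) or `"high"`: which plateau to depart from.
#' @return An object of class `"dispersion_estimate"`: list with
#'   `knee_frequency` (Hz; `NA` when the spectrum never departs),
#'   `plateau_level`, `rel_tolerance`, and logical `found`.
#' @export
detect_dispersion_frequency <- function(spectrum, rel_tolerance = 0.05, k = 3L,
                                        side = c("low", "high")) {
  side <- match.arg(side)
  if (inherits(spectrum, "edisim_sweep")) spectrum <- as_spectrum(spectrum)
  stopifnot(inherits(spectrum, "eis_spectrum"))
  if (rel_tolerance <= 0 || rel_tolerance >= 1)
    stop_edisim("edisim_domain_error", "rel_tolerance must be in (0, 1)")
  n <- nrow(spectrum)
  if (n < 5L)
    stop_edisim("edisim_domain_error", "spectrum must have at least 5 points")
  f <- spectrum$frequency
  m <- spectrum$modulus
  if (side == "high") { f <- rev(1 / f); m <- rev(m) }  # mirror in log-f

  plateau_pts <- m[seq_len(k)]
  plateau <- mean(plateau_pts)
  if (any(abs(plateau_pts - plateau) > rel_tolerance * abs(plateau)))
    stop_edisim("edisim_no_plateau_error",
                sprintf("first %d points vary beyond rel_tolerance = %g: no plateau",
                        k, rel_tolerance))
  dev <- abs(m - plateau)
  thr <- rel_tolerance * abs(plateau)
  beyond <- which(dev > thr)
  beyond <- beyond[beyond > k]
  if (length(beyond) == 0L) {
    return(structure(list(knee_frequency = NA_real_, plateau_level = plateau,
                          rel_tolerance = rel_tolerance, found = FALSE),
                     class = "dispersion_estimate"))
  }
  j <- beyond[1L]
  # log-linear refinement between the last in-plateau point and the first
  # departing point: where the deviation crosses the threshold
  lf1 <- log10(f[j - 1L]); lf2 <- log10(f[j])
  d1 <- dev[j - 1L]; d2 <- dev[j]
  frac <- if (d2 > d1) (thr - d1) / (d2 - d1) else 0
  knee <- 10^(lf1 + frac * (lf2 - lf1))
  if (side == "high") knee <- 1 / knee
  structure(list(knee_frequency = knee, plateau_level = plateau,
                 rel_tolerance = rel_tolerance, found = TRUE),
            class = "dispersion_estimate")
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  if (x$found)
    cat(sprintf("<dispersion_estimate> knee at %g Hz (plateau %g, rel tol %g)\n",
                x$knee_frequency, x$plateau_level, x$rel_tolerance))
  else
    cat(sprintf("<dispersion_estimate> no departure found (plateau %g, rel tol %g)\n",
                x$plateau_level, x$rel_tolerance))
  invisible(x)
}

#' Assemble Bode-diagram data from spectra
#'
#' The Bode diagram pairs a log-log modulus curve with a phase curve on a
#' log frequency axis. Returns the plot-ready long-format table; phase is
#' kept linear (phases near zero make a log axis ill-defined).
#'
#' @param spectra a non-empty list of [eis_spectrum()] objects (a single
#'   spectrum is accepted and wrapped).
#' @return A data frame with columns `curve_label`, `log10_f`,
#'   `log10_Zmod`, `phase_deg`, curves in input order.
#' @export
bode_assemble <- function(spectra) {
  if (inherits(spectra, "eis_spectrum")) spectra <- list(spectra)
  if (length(spectra) == 0L)
    stop_edisim("edisim_empty_error", "no spectra to assemble")
  tabs <- lapply(seq_along(spectra), function(i) {
    sp <- spectra[[i]]
    stopifnot(inherits(sp, "eis_spectrum"))
    bad <- which(sp$modulus <= 0)
    if (length(bad) > 0L)
      stop_edisim("edisim_domain_error",
                  sprintf("spectrum '%s' has non-positive modulus at point %d (f = %g Hz)",
                          attr(sp, "label"), bad[1L], sp$frequency[bad[1L]]))
    data.frame(curve_label = attr(sp, "label"),
               log10_f = log10(sp$frequency),
               log10_Zmod = log10(sp$modulus),
               phase_deg = sp$phase)
  })
  do.call(rbind, tabs)
}

#' Plot a Bode diagram
#'
#' Two stacked panels: log10 modulus and phase, both against log10
#' frequency, one curve per spectrum.
#'
#' @param spectra a list of [eis_spectrum()] objects (or one spectrum).
#' @param ... passed to [graphics::matplot()].
#' @return The [bode_assemble()] table, invisibly.
#' @export
bode_plot <- function(spectra, ...) {
  tab <- bode_assemble(spectra)
  labs <- unique(tab$curve_label)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  for (panel in c("log10_Zmod", "phase_deg")) {
    graphics::plot(range(tab$log10_f), range(tab[[panel]]), type = "n",
                   xlab = "log10 f [Hz]",
                   ylab = if (panel == "log10_Zmod") "log10 |Z|" else "phase [deg]",
                   ...)
    for (s in seq_along(labs)) {
      sub <- tab[tab$curve_label == labs[s], ]
      graphics::lines(sub$log10_f, sub[[panel]], col = s, type = "b", pch = s)
    }
  }
  invisible(tab)
}

#' Synthetic single-relaxation (Debye) spectrum
#'
#' Test fixture emulating a measured spectrum with one relaxation:
#' `Z(f) = r_inf + delta_r / (1 + i 2 pi f tau)`, with optional
#' multiplicative Gaussian noise on the modulus. At low frequency the
#' modulus tends to `r_inf + delta_r` with zero phase; the dispersion is
#' centred on `f = 1/(2 pi tau)`.
#'
#' @param r_inf high-frequency resistance in ohms (> 0).
#' @param delta_r dispersion magnitude in ohms (>= 0).
#' @param tau relaxation time constant in seconds (> 0).
#' @param frequencies Hz, e.g. from [log_frequency_grid()].
#' @param noise_sd relative standard deviation of multiplicative Gaussian
#'   noise on the modulus (0 = noise-free).
#' @param seed seed for the noise.
#' @param label spectrum label.
#' @return An [eis_spectrum()] object.
#' @export
synth_debye_spectrum <- function(r_inf, delta_r, tau, frequencies,
                                 noise_sd = 0, seed = 1L,
                                 label = sprintf("debye tau=%g", tau)) {
  if (r_inf <= 0) stop_edisim("edisim_domain_error", "r_inf must be > 0")
  if (delta_r < 0) stop_edisim("edisim_domain_error", "delta_r must be >= 0")
  if (tau <= 0) stop_edisim("edisim_domain_error", "tau must be > 0")
  z <- r_inf + delta_r / (1 + 2i * pi * frequencies * tau)
  modulus <- Mod(z)
  if (noise_sd > 0) {
    noise <- withr_seed(seed, function()
      stats::rnorm(length(frequencies), mean = 1, sd = noise_sd))
    modulus <- modulus * noise
  }
  eis_spectrum(frequencies, modulus, phase = Arg(z) * 180 / pi, label = label)
}

#' Type-B combined uncertainty
#'
#' Combines a calibration uncertainty (instrument graduation) and an
#' experimenter uncertainty, each treated as the half-width of a uniform
#' distribution (variance `delta^2 / 3`), in quadrature:
#' `u = sqrt(delta_cal^2/3 + delta_exp^2/3)`. For the thermometer with 1
#' degree C graduation and 0.5 degree C experimenter uncertainty this gives
#' 0.65 degrees C at two decimals.
#'
#' @param delta_cal calibration uncertainty half-width, degrees C (>= 0).
#' @param delta_exp experimenter uncertainty half-width, degrees C (>= 0).
#' @return The combined standard uncertainty in degrees C (full precision;
#'   report at two decimals).
#' @examples
#' round(type_b_uncertainty(1.0, 0.5), 2)  # 0.65
#' @export
type_b_uncertainty <- function(delta_cal, delta_exp) {
  if (any(delta_cal < 0) || any(delta_exp < 0))
    stop_edisim("edisim_domain_error", "uncertainty components must be >= 0")
  sqrt(delta_cal^2 / 3 + delta_exp^2 / 3)
}
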