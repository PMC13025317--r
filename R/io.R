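#' Write an EIS spectrum as tabular text
#'
#' Comma-separated columns `freq_Hz, Zmod_ohm, Zphase_deg` with a header
#' line — the layout of potentiostat frequency-response-analyser exports.
#' The `"comma"` dialect writes decimal commas with semicolon separators,
#' as some instrument software does on comma-decimal locales.
#'
#' @param spectrum an [eis_spectrum()] object.
#' @param path output file path.
#' @param dialect `"point"` (default: decimal points, comma separator) or
#'   `"comma"` (decimal commas, semicolon separator).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, dialect = c("point", "comma")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(spectrum, "eis_spectrum"))
  df <- data.frame(freq_Hz = spectrum$frequency, Zmod_ohm = spectrum$modulus,
                   Zphase_deg = spectrum$phase)
  sep <- if (dialect == "point") "," else ";"
  dec <- if (dialect == "point") "." else ","
  utils::write.table(format(df, digits = 17, trim = TRUE, decimal.mark = dec,
                            scientific = FALSE),
                     path, sep = sep, dec = dec, row.names = FALSE,
                     col.names = c("freq_Hz", "Zmod_ohm", "Zphase_deg"),
                     quote = FALSE)
  invisible(path)
}

#' Read an EIS spectrum from tabular text
#'
#' @inheritParams write_spectrum
#' @param path input file path.
#' @param label label for the spectrum; defaults to the file name.
#' @return An [eis_spectrum()] object.
#' @export
read_spectrum <- function(path, dialect = c("point", "comma"), label = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop_edisim("edisim_io_error", sprintf("no such file: %s", path))
  sep <- if (dialect == "point") "," else ";"
  dec <- if (dialect == "point") "." else ","
  df <- tryCatch(utils::read.table(path, header = TRUE, sep = sep, dec = dec),
                 error = function(e)
                   stop_edisim("edisim_io_error",
                               sprintf("cannot parse %s: %s", path, conditionMessage(e))))
  need <- c("freq_Hz", "Zmod_ohm", "Zphase_deg")
  if (!all(need %in% names(df)))
    stop_edisim("edisim_io_error",
                sprintf("%s: expected columns %s", path, paste(need, collapse = ", ")))
  eis_spectrum(df$freq_Hz, df$Zmod_ohm, df$Zphase_deg, label = label)
}

#' Export Bode-diagram data as tabular text
#'
#' Long-format table `curve_label, log10_f, log10_Zmod, phase_deg`.
#'
#' @param spectra list of [eis_spectrum()] objects (or one spectrum).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bode <- function(spectra, path) {
  tab <- bode_assemble(spectra)
  utils::write.table(tab, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Sidecar path for a sweep file.
sweep_sidecar <- function(path) paste0(path, ".yml")

SWEEP_FORMAT_VERSION <- 1L

#' Write a simulated sweep with its configuration sidecar
#'
#' The sweep itself is comma-separated `frequency, amplitude` text; a YAML
#' sidecar (`<path>.yml`) stores the full run configuration — grid, model
#' parameters, protocol and seed — so the run can be regenerated
#' bit-identically.
#'
#' @param sweep an `"edisim_sweep"` object.
#' @param path output file path (sidecar written next to it).
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "edisim_sweep"))
  df <- data.frame(frequency = sweep$frequency, amplitude = sweep$amplitude)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  g <- attr(sweep, "grid"); p <- attr(sweep, "params"); pr <- attr(sweep, "protocol")
  side <- list(format_version = SWEEP_FORMAT_VERSION,
               label = attr(sweep, "label"),
               grid = list(nx = g$nx, ny = g$ny, h = g$h),
               model = list(kappa = p$kappa, amplitude = p$amplitude,
                            dt = p$dt, normalization = p$normalization),
               protocol = unclass(pr))
  yaml::write_yaml(side, sweep_sidecar(path))
  invisible(path)
}

#' Read a simulated sweep written by [write_sweep()]
#'
#' @param path sweep file path; the `<path>.yml` sidecar must exist.
#' @return An `"edisim_sweep"` object (diagnostic columns are not
#'   round-tripped; frequencies and amplitudes are).
#' @export
read_sweep <- function(path) {
  if (!file.exists(path))
    stop_edisim("edisim_io_error", sprintf("no such file: %s", path))
  if (!file.exists(sweep_sidecar(path)))
    stop_edisim("edisim_io_error", sprintf("missing sidecar: %s", sweep_sidecar(path)))
  side <- yaml::read_yaml(sweep_sidecar(path))
  if (is.null(side$format_version) || side$format_version != SWEEP_FORMAT_VERSION)
    stop_edisim("edisim_io_error",
                sprintf("sidecar format version %s is not supported (expected %d)",
                        format(side$format_version), SWEEP_FORMAT_VERSION))
  df <- utils::read.table(path, header = TRUE, sep = ",")
  bad <- which(!is.finite(df$amplitude))
  if (length(bad) > 0L)
    stop_edisim("edisim_io_error",
                sprintf("%s: non-finite amplitude at point %d", path, bad[1L]))
  grid <- grid_spec(side$grid$nx, side$grid$ny, side$grid$h)
  params <- model_params(side$model$kappa, side$model$amplitude,
                         side$model$dt, side$model$normalization)
  pr <- side$protocol
  protocol <- sweep_protocol(pr$transient_periods, pr$measure_periods,
                             pr$min_samples_per_period, pr$settle_efolds,
                             pr$min_window_steps, pr$seed)
  structure(data.frame(frequency = df$frequency, amplitude = df$amplitude),
            class = c("edisim_sweep", "data.frame"),
            grid = grid, params = params, protocol = protocol,
            label = side$label)
}
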