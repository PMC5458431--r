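#' Write a waveform to the package's CSV dialect
#'
#' Writes a comment header carrying the metadata, then full-precision
#' \code{time_s,value} rows:
#' \preformatted{# quantity=pressure fs=500 t0=0
#' time_s,value
#' 0.00000000000000000,99.812...}
#' 17 significant digits make the write/read round trip lossless for
#' doubles.
#'
#' @param w a \code{\link{waveform}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_waveform <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# quantity=%s fs=%s t0=%s", w$quantity,
                     format(w$fs, digits = 17),
                     format(w$t0, digits = 17)), con)
  writeLines("time_s,value", con)
  writeLines(sprintf("%.17g,%.17g", waveform_times(w), w$values), con)
  invisible(path)
}

#' Read a waveform from the package's CSV dialect
#'
#' Accepts the two-column \code{time_s,value} format written by
#' \code{\link{write_waveform}} (sampling rate and quantity taken from
#' the comment header, uniform sampling verified against the time
#' column) or a headerless single-column file with \code{fs} and
#' \code{quantity} supplied as arguments.
#'
#' @param path input file path.
#' @param expected_quantity if given, reading fails unless the file's
#'   quantity matches.
#' @param fs,quantity metadata for headerless single-column files;
#'   ignored when the file carries a header.
#' @param max_jitter maximum tolerated deviation of any time stamp from
#'   the uniform grid, s.
#' @return A \code{\link{waveform}}.
#' @export
read_waveform <- function(path, expected_quantity = NULL, fs = NULL,
                          quantity = NULL, max_jitter = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#")) {
    meta <- parse_header(first)
    tab <- utils::read.csv(path, comment.char = "#",
                           colClasses = "numeric")
    if (!all(c("time_s", "value") %in% names(tab)))
      stop("expected columns time_s,value in ", path)
    bad <- which(!is.finite(tab$value))
    if (length(bad) > 0)
      stop(sprintf("non-finite sample at row %d of %s", bad[1L], path))
    n <- nrow(tab)
    expected_t <- meta$t0 + (seq_len(n) - 1L) / meta$fs
    jit <- max(abs(tab$time_s - expected_t))
    if (jit > max_jitter)
      stop(sprintf("non-uniform time base in %s (max jitter %.3g s)",
                   path, jit))
    w <- waveform(tab$value, fs = meta$fs, t0 = meta$t0,
                  quantity = meta$quantity)
  } else {
    if (is.null(fs) || is.null(quantity))
      stop("headerless file: supply fs and quantity")
    vals <- scan(path, what = numeric(), sep = if (grepl(",", first)) "," else "",
                 quiet = TRUE)
    if (anyNA(vals) || !all(is.finite(vals)))
      stop(sprintf("non-finite sample at row %d of %s",
                   which(!is.finite(vals))[1L], path))
    w <- waveform(vals, fs = fs, quantity = quantity)
  }
  if (!is.null(expected_quantity) && w$quantity != expected_quantity)
    stop(sprintf("expected a %s waveform but %s declares %s",
                 expected_quantity, path, w$quantity))
  w
}

parse_header <- function(line) {
  kv <- regmatches(line, gregexpr("[a-z0-9_]+=[^ ]+", line))[[1L]]
  pairs <- strsplit(kv, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(pairs, `[`, "", 2L),
                          vapply(pairs, `[`, "", 1L))
  if (!"fs" %in% names(vals)) stop("waveform header lacks fs")
  list(quantity = if ("quantity" %in% names(vals)) vals[["quantity"]]
                  else "pressure",
       fs = as.numeric(vals[["fs"]]),
       t0 = if ("t0" %in% names(vals)) as.numeric(vals[["t0"]]) else 0)
}

#' Export a Kalman filter trace as CSV
#'
#' One row per sample: index \code{k} (0-based), time, measurement,
#' input, a priori and a posteriori states, gain components, innovation
#' and denoised output.
#'
#' @param trace a \code{\link{run_kalman}} trace.
#' @param flow,measured the waveforms the filter was run on.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_trace_csv <- function(trace, flow, measured, path) {
  stopifnot(inherits(trace, "kf_trace"))
  n <- nrow(trace$x_post)
  tab <- data.frame(k = seq_len(n) - 1L,
                    t = waveform_times(measured),
                    z = measured$values,
                    u = flow$values,
                    x_prior_vC = trace$x_prior[, 1L],
                    x_prior_iL = trace$x_prior[, 2L],
                    x_post_vC = trace$x_post[, 1L],
                    x_post_iL = trace$x_post[, 2L],
                    K_vC = trace$K[, 1L],
                    K_iL = trace$K[, 2L],
                    innovation = trace$innovation,
                    denoised = trace$denoised$values)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Export a power spectrum as CSV
#' @param s a \code{\link{power_spectrum}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "power_spectrum"))
  utils::write.csv(data.frame(frequency_hz = s$frequency, power = s$power),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' Parses a JSON or YAML configuration (chosen by file extension) into a
#' validated \code{run_config}: Windkessel parameters, sampling period,
#' noise covariances, flow spec, artifact spec and spectral options.
#' Missing blocks fall back to the package defaults, so a minimal config
#' may override only what it needs. The shipped default,
#' \code{system.file("extdata", "default_config.json",
#' package = "abpkalman")}, carries the published systemic-circulation
#' Windkessel constants together with this package's calibrated noise
#' covariances.
#'
#' @param path path to a \code{.json}, \code{.yaml} or \code{.yml} file;
#'   default is the shipped configuration.
#' @return An object of class \code{"run_config"}: list with
#'   \code{params} (\code{wk_params}), \code{Ts}, \code{noise}
#'   (\code{kf_noise}), \code{flow} (\code{flow_spec}), \code{artifact}
#'   (\code{artifact_spec}), \code{settle_periods} and \code{spectral}
#'   options.
#' @export
read_run_config <- function(path = system.file("extdata",
                                               "default_config.json",
                                               package = "abpkalman")) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  config_from_list(raw)
}

config_from_list <- function(raw) {
  dflt <- function(block, key, fallback)
    if (!is.null(raw[[block]][[key]]) && !is.na(raw[[block]][[key]][1]))
      raw[[block]][[key]] else fallback
  wk <- windkessel_params(R = dflt("windkessel", "R", 1.72),
                          C = dflt("windkessel", "C", 0.48),
                          r = dflt("windkessel", "r", 0.105),
                          L = dflt("windkessel", "L", 0.0059))
  Ts <- if (!is.null(raw$Ts)) raw$Ts else 0.002
  noise <- noise_covariances(Qproc = dflt("noise", "Qproc", c(1.58, 0.01)),
                             Rmeas = dflt("noise", "Rmeas", 25))
  fl <- flow_spec(heart_rate = dflt("flow", "heart_rate", 60),
                  stroke_volume = dflt("flow", "stroke_volume", 70),
                  systolic_fraction = dflt("flow", "systolic_fraction", 0.35),
                  fs = dflt("flow", "fs", 1 / Ts),
                  duration = dflt("flow", "duration", 10))
  sw <- raw$artifact$artifact_window
  if (!is.null(sw)) sw <- as.numeric(sw)
  art <- artifact_spec(gaussian_sigma = dflt("artifact", "gaussian_sigma", 5),
                       spike_times = dflt("artifact", "spike_times", numeric()),
                       spike_amplitudes = dflt("artifact", "spike_amplitudes",
                                               numeric()),
                       artifact_window = sw,
                       seed = dflt("artifact", "seed", 42L))
  spectral <- list(window = dflt("spectral", "window", "rectangular"),
                   n_peaks = dflt("spectral", "n_peaks", 2L),
                   floor_hz = dflt("spectral", "floor_hz", 0.25))
  structure(list(params = wk, Ts = Ts, noise = noise, flow = fl,
                 artifact = art,
                 settle_periods = if (!is.null(raw$settle_periods))
                   raw$settle_periods else 5,
                 spectral = spectral),
            class = "run_config")
}

#' Serialize a run configuration
#'
#' Writes a \code{run_config} back to JSON or YAML (by extension). The
#' dump/parse cycle is idempotent: re-reading the written file yields an
#' identical configuration.
#'
#' @param config a \code{\link{read_run_config}} object.
#' @param path output path ending in \code{.json}, \code{.yaml} or
#'   \code{.yml}.
#' @return \code{path}, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  raw <- list(
    windkessel = unclass(config$params),
    Ts = config$Ts,
    noise = list(Qproc = diag(config$noise$Qproc),
                 Rmeas = config$noise$Rmeas),
    flow = unclass(config$flow)[c("heart_rate", "stroke_volume",
                                  "systolic_fraction", "fs", "duration")],
    artifact = Filter(Negate(is.null),
                      unclass(config$artifact)[c("gaussian_sigma",
                                                 "spike_times",
                                                 "spike_amplitudes",
                                                 "artifact_window",
                                                 "seed")]),
    settle_periods = config$settle_periods,
    spectral = config$spectral)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(raw, path)
  else
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(path)
}

#' Run the full synthesis/denoising pipeline
#'
#' Convenience wrapper tying the modules together: generate the
#' synthetic dataset from a configuration, run the Kalman filter, and
#' score the result (error summary, SNR improvement, harmonic peaks of
#' the denoised spectrum).
#'
#' @param config a \code{\link{read_run_config}} object (default: the
#'   shipped configuration).
#' @return List with \code{dataset}, \code{trace}, \code{error},
#'   \code{snr_db}, \code{spectrum} and \code{peaks}.
#' @export
run_pipeline <- function(config = read_run_config()) {
  stopifnot(inherits(config, "run_config"))
  ds <- make_dataset(config$flow, config$params, config$artifact,
                     settle_periods = config$settle_periods)
  model <- wk_discretize(config$params, config$Ts)
  trace <- run_kalman(model, config$noise, ds$flow, ds$noisy)
  err <- estimation_error(ds$noisy, trace$denoised)
  spec <- power_spectrum(trace$denoised, window = config$spectral$window)
  peaks <- harmonic_peaks(spec, n_peaks = config$spectral$n_peaks,
                          floor_hz = config$spectral$floor_hz)
  list(dataset = ds, trace = trace, error = err,
       snr_db = snr_improvement(ds$clean, ds$noisy, trace$denoised),
       spectrum = spec, peaks = peaks)
}
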