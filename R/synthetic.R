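#' Pulsatile aortic-flow specification
#'
#' Describes a synthetic periodic aortic-flow waveform: each beat ejects
#' \code{stroke_volume} ml as a half-sine systolic pulse occupying
#' \code{systolic_fraction} of the cardiac period, followed by zero
#' diastolic flow. The defaults (60 bpm, 70 ml, fraction 0.35, 500 Hz,
#' 10 s) place the cardiac fundamental at 1 Hz and give a physiologic
#' mean flow of 70 ml/s; they are a synthetic stand-in, not recorded
#' animal data.
#'
#' @param heart_rate beats per minute.
#' @param stroke_volume ejected volume per beat, ml.
#' @param systolic_fraction fraction of the period spent in ejection,
#'   in (0, 1).
#' @param fs sampling rate, Hz.
#' @param duration record length, s; at least one period.
#' @param shape ejection shape; only \code{"half-sine"} is implemented.
#' @return An object of class \code{"flow_spec"}.
#' @export
flow_spec <- function(heart_rate = 60, stroke_volume = 70,
                      systolic_fraction = 0.35, fs = 500,
                      duration = 10, shape = "half-sine") {
  shape <- match.arg(shape, "half-sine")
  if (!is.finite(heart_rate) || heart_rate <= 0)
    stop("heart_rate must be positive")
  if (!is.finite(stroke_volume) || stroke_volume < 0)
    stop("stroke_volume must be >= 0")
  if (!is.finite(systolic_fraction) ||
      systolic_fraction <= 0 || systolic_fraction >= 1)
    stop("systolic_fraction must lie strictly in (0, 1)")
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  period <- 60 / heart_rate
  spb <- period * fs                       # samples per beat
  # beats must tile the sample grid; tolerate only float fuzz so that
  # beat-to-beat waveforms are sample-identical
  if (abs(spb - round(spb)) > 0.01)
    stop(sprintf("period %g s is not a whole number of samples at %g Hz",
                 period, fs))
  if (duration < period - 0.5 / fs)
    stop("duration must cover at least one cardiac period")
  structure(list(heart_rate = heart_rate, stroke_volume = stroke_volume,
                 systolic_fraction = systolic_fraction, fs = fs,
                 duration = duration, shape = shape),
            class = "flow_spec")
}

#' Generate a pulsatile aortic-flow waveform
#'
#' Builds the half-sine ejection waveform described by a
#' \code{\link{flow_spec}}. With systolic duration \code{t_sys} the peak
#' flow is \code{Qp = SV * pi / (2 t_sys)} so that the per-beat integral
#' of the pulse equals the stroke volume exactly; diastolic samples are
#' exactly zero.
#'
#' @param spec a \code{\link{flow_spec}}.
#' @return A flow \code{\link{waveform}}.
#' @examples
#' f <- generate_flow(flow_spec(duration = 2))
#' max(f$values)   # ~ 70 * pi / 0.7 = 314.16 ml/s
#' @export
generate_flow <- function(spec) {
  stopifnot(inherits(spec, "flow_spec"))
  period <- 60 / spec$heart_rate
  spb <- round(period * spec$fs)
  t_sys <- spec$systolic_fraction * period
  Qp <- spec$stroke_volume * pi / (2 * t_sys)
  t_beat <- (seq_len(spb) - 1L) / spec$fs
  beat <- ifelse(t_beat < t_sys, Qp * sin(pi * t_beat / t_sys), 0)
  beat[beat < 0] <- 0
  # continuous-time pulse integrates to SV exactly; the Riemann sum at fs
  # is within 0.5% — rescale systolic samples so the discrete sum is exact
  sys_idx <- beat > 0
  discrete_sv <- sum(beat) / spec$fs
  beat[sys_idx] <- beat[sys_idx] * spec$stroke_volume / discrete_sv
  n <- round(spec$duration * spec$fs)
  values <- rep_len(beat, n)
  waveform(values, fs = spec$fs, t0 = 0, quantity = "flow")
}

#' Synthesize a clean pressure waveform at periodic steady state
#'
#' Runs the Euler-forward Windkessel simulation on a generated flow
#' waveform, discarding a settling interval (default 5 cardiac periods)
#' so that the retained pressure is at periodic steady state free of the
#' initial transient. The retained flow and pressure are aligned and
#' re-based to start at t = 0.
#'
#' @param spec a \code{\link{flow_spec}}.
#' @param params a \code{\link{windkessel_params}} object.
#' @param settle_periods cardiac periods discarded from the start.
#' @return List with \code{flow} and \code{pressure} waveforms of length
#'   \code{spec$duration * spec$fs}.
#' @export
generate_clean_pressure <- function(spec, params = windkessel_params(),
                                    settle_periods = 5) {
  stopifnot(inherits(spec, "flow_spec"), inherits(params, "wk_params"))
  period <- 60 / spec$heart_rate
  spb <- round(period * spec$fs)
  ext <- spec
  ext$duration <- spec$duration + settle_periods * period
  flow_ext <- generate_flow(ext)
  model <- wk_discretize(params, 1 / spec$fs)
  # start at the DC operating point so the settling discard only has to
  # absorb the pulsatile component of the transient
  mf <- mean(flow_ext$values)
  sim <- wk_simulate(model, flow_ext, init = c(params$R * mf, mf))
  keep <- seq.int(settle_periods * spb + 1L, length(flow_ext$values))
  n <- round(spec$duration * spec$fs)
  keep <- keep[seq_len(min(n, length(keep)))]
  list(flow = waveform(flow_ext$values[keep], fs = spec$fs, t0 = 0,
                       quantity = "flow"),
       pressure = waveform(sim$pressure$values[keep], fs = spec$fs, t0 = 0,
                           quantity = "pressure"))
}

#' Noise and artifact specification
#'
#' Additive corruption applied to a clean pressure waveform: zero-mean
#' Gaussian noise of standard deviation \code{gaussian_sigma} on every
#' sample, plus optional isolated spikes. Spikes may be confined to an
#' artifact window, emulating recordings in which noise and artifacts
#' concentrate in a known interval. Corruption is purely additive and
#' bit-reproducible under a fixed seed.
#'
#' @param gaussian_sigma noise standard deviation, mmHg (>= 0).
#' @param spike_times spike onset times, s (may be empty).
#' @param spike_amplitudes spike amplitudes, mmHg; recycled to
#'   \code{length(spike_times)}.
#' @param artifact_window optional \code{c(start, end)} in s; spike times
#'   must fall inside it when given.
#' @param seed integer RNG seed.
#' @return An object of class \code{"artifact_spec"}.
#' @export
artifact_spec <- function(gaussian_sigma = 5, spike_times = numeric(),
                          spike_amplitudes = numeric(),
                          artifact_window = NULL, seed = 42L) {
  if (!is.finite(gaussian_sigma) || gaussian_sigma < 0)
    stop("gaussian_sigma must be >= 0")
  if (length(spike_times) > 0)
    spike_amplitudes <- rep_len(spike_amplitudes, length(spike_times))
  if (!is.null(artifact_window)) {
    if (length(artifact_window) != 2L || artifact_window[1] >= artifact_window[2])
      stop("artifact_window must be c(start, end) with start < end")
    if (length(spike_times) > 0 &&
        any(spike_times < artifact_window[1] | spike_times > artifact_window[2]))
      stop("spike_times must fall inside the artifact window")
  }
  structure(list(gaussian_sigma = gaussian_sigma,
                 spike_times = as.numeric(spike_times),
                 spike_amplitudes = as.numeric(spike_amplitudes),
                 artifact_window = artifact_window,
                 seed = as.integer(seed)),
            class = "artifact_spec")
}

#' Corrupt a pressure waveform with noise and artifacts
#'
#' @param pressure a pressure \code{\link{waveform}}.
#' @param spec an \code{\link{artifact_spec}}.
#' @return The corrupted pressure \code{waveform}.
#' @export
corrupt <- function(pressure, spec) {
  stopifnot(inherits(pressure, "waveform"), inherits(spec, "artifact_spec"))
  n <- length(pressure$values)
  tmax <- pressure$t0 + (n - 1L) / pressure$fs
  if (length(spec$spike_times) > 0 &&
      any(spec$spike_times < pressure$t0 | spec$spike_times > tmax))
    stop("spike_times outside the waveform's time span")
  noise <- local_seed(spec$seed, stats::rnorm(n, 0, spec$gaussian_sigma))
  out <- pressure$values + noise
  if (length(spec$spike_times) > 0) {
    idx <- 1L + round((spec$spike_times - pressure$t0) * pressure$fs)
    out[idx] <- out[idx] + spec$spike_amplitudes
  }
  waveform(out, fs = pressure$fs, t0 = pressure$t0, quantity = "pressure")
}

# evaluate expr under a local RNG seed without disturbing the global stream
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a complete synthetic dataset
#'
#' Produces the three aligned series a denoising experiment needs — the
#' known flow input, the clean model pressure, and the noise/artifact
#' corrupted pressure — together with a metadata record from which the
#' bundle can be regenerated bit-exactly.
#'
#' @param fspec a \code{\link{flow_spec}}.
#' @param params a \code{\link{windkessel_params}} object.
#' @param aspec an \code{\link{artifact_spec}}.
#' @param settle_periods settling periods discarded before retention.
#' @return An object of class \code{"abp_dataset"}: list with
#'   \code{flow}, \code{clean}, \code{noisy} waveforms and
#'   \code{metadata} (all spec fields, seed, settling discarded).
#' @export
make_dataset <- function(fspec = flow_spec(), params = windkessel_params(),
                         aspec = artifact_spec(), settle_periods = 5) {
  gen <- generate_clean_pressure(fspec, params, settle_periods)
  noisy <- corrupt(gen$pressure, aspec)
  metadata <- list(flow_spec = unclass(fspec),
                   windkessel = unclass(params),
                   artifact_spec = unclass(aspec),
                   settle_periods = settle_periods)
  structure(list(flow = gen$flow, clean = gen$pressure, noisy = noisy,
                 metadata = metadata),
            class = "abp_dataset")
}

#' @export
print.abp_dataset <- function(x, ...) {
  cat("Synthetic ABP dataset\n")
  cat(sprintf("  %d samples @ %g Hz (%.3g s), HR %g bpm, SV %g ml\n",
              length(x$flow$values), x$flow$fs,
              length(x$flow$values) / x$flow$fs,
              x$metadata$flow_spec$heart_rate,
              x$metadata$flow_spec$stroke_volume))
  cat(sprintf("  noise sigma %g mmHg, %d spikes, seed %d\n",
              x$metadata$artifact_spec$gaussian_sigma,
              length(x$metadata$artifact_spec$spike_times),
              x$metadata$artifact_spec$seed))
  invisible(x)
}

#' Rebuild a dataset from its metadata record
#'
#' @param metadata the \code{metadata} element of an
#'   \code{\link{make_dataset}} bundle (e.g. parsed back from JSON).
#' @return The regenerated \code{"abp_dataset"} (bit-identical to the
#'   original for the same metadata).
#' @export
dataset_from_metadata <- function(metadata) {
  fs <- metadata$flow_spec
  wk <- metadata$windkessel
  as_ <- metadata$artifact_spec
  aw <- as_$artifact_window
  if (length(aw) < 2L) aw <- NULL else aw <- as.numeric(aw)
  make_dataset(
    fspec = flow_spec(heart_rate = fs$heart_rate,
                      stroke_volume = fs$stroke_volume,
                      systolic_fraction = fs$systolic_fraction,
                      fs = fs$fs, duration = fs$duration, shape = fs$shape),
    params = windkessel_params(R = wk$R, C = wk$C, r = wk$r, L = wk$L),
    aspec = artifact_spec(gaussian_sigma = as_$gaussian_sigma,
                          spike_times = as.numeric(as_$spike_times),
                          spike_amplitudes = as.numeric(as_$spike_amplitudes),
                          artifact_window = aw,
                          seed = as_$seed),
    settle_periods = metadata$settle_periods)
}
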