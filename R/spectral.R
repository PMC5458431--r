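#' One-sided periodogram of a waveform
#'
#' Power-spectrum estimate from the squared magnitude of the DFT, folded
#' onto 0..fs/2. The normalization conserves energy: the per-bin powers
#' sum to the mean square of the (optionally windowed) input, i.e.
#' Parseval's identity holds to numerical precision. The DC bin is
#' retained; excluding it is the peak finder's job.
#'
#' @param w a \code{\link{waveform}} of length >= 4.
#' @param window taper applied before the DFT: \code{"rectangular"}
#'   (default, no taper) or \code{"hann"}.
#' @return An object of class \code{"power_spectrum"}: a data.frame with
#'   columns \code{frequency} (Hz, 0..fs/2, spacing fs/N) and
#'   \code{power}, with attributes \code{fs}, \code{n} and \code{window}.
#' @examples
#' w <- waveform(sin(2 * pi * 1.25 * (0:3999) / 500), fs = 500)
#' s <- power_spectrum(w)
#' s$frequency[which.max(s$power)]   # 1.25 Hz
#' @export
power_spectrum <- function(w, window = c("rectangular", "hann")) {
  stopifnot(inherits(w, "waveform"))
  window <- match.arg(window)
  x <- w$values
  n <- length(x)
  if (n < 4L) stop("waveform too short for a power spectrum")
  if (window == "hann")
    x <- x * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n))
  X <- stats::fft(x)
  full <- Mod(X)^2 / n^2          # two-sided, sums to mean-square(x)
  half <- n %/% 2L
  idx <- seq_len(half + 1L)       # 0 .. fs/2
  power <- full[idx]
  # fold the negative-frequency half onto the interior bins
  interior <- 2:(if (n %% 2L == 0L) half else half + 1L)
  power[interior] <- power[interior] + rev(full[(half + 2L):n])
  freq <- (idx - 1L) * w$fs / n
  structure(data.frame(frequency = freq, power = power),
            fs = w$fs, n = n, window = window,
            class = c("power_spectrum", "data.frame"))
}

#' Locate harmonic peaks in a power spectrum
#'
#' Finds local maxima of the per-bin power and returns the
#' \code{n_peaks} largest, ordered by ascending frequency. With
#' \code{exclude_dc = TRUE} (default) the 0 Hz bin and all bins below
#' \code{floor_hz} are ignored, since the DC component only reflects the
#' mean of the samples, not a cardiac harmonic.
#'
#' @param s a \code{\link{power_spectrum}}.
#' @param n_peaks number of peaks requested (>= 1).
#' @param exclude_dc drop the DC bin and bins below \code{floor_hz}.
#' @param floor_hz low-frequency exclusion floor, Hz.
#' @return A data.frame with columns \code{frequency} and \code{power},
#'   ascending in frequency; attribute \code{incomplete} is TRUE when
#'   fewer local maxima exist than requested.
#' @export
harmonic_peaks <- function(s, n_peaks = 2L, exclude_dc = TRUE,
                           floor_hz = 0.25) {
  stopifnot(inherits(s, "power_spectrum"), n_peaks >= 1L)
  p <- s$power
  f <- s$frequency
  n <- length(p)
  # local maximum: strictly above the left neighbour, >= the right;
  # endpoints compare against their single neighbour
  left  <- c(-Inf, p[-n])
  right <- c(p[-1L], -Inf)
  is_max <- p > left & p >= right
  if (exclude_dc) is_max[f < floor_hz] <- FALSE
  cand <- which(is_max)
  incomplete <- length(cand) < n_peaks
  take <- cand[order(p[cand], decreasing = TRUE)][seq_len(min(n_peaks,
                                                              length(cand)))]
  take <- sort(take)
  out <- data.frame(frequency = f[take], power = p[take])
  attr(out, "incomplete") <- incomplete
  out
}

#' Estimation error between measured and estimated waveforms
#'
#' Pointwise difference \code{measured - estimated} plus a summary of
#' its magnitude and drift: the early-vs-late ratio compares the mean
#' absolute error over the last \code{edge_window} seconds against the
#' first, quantifying whether estimation error accumulates over the
#' record.
#'
#' @param measured,estimated aligned \code{\link{waveform}}s (same
#'   length, fs and t0).
#' @param edge_window length of the early and late comparison windows, s.
#' @return List with \code{error} (a \code{waveform}) and \code{summary}
#'   (mean, rmse, max_abs, early_mae, late_mae, late_early_ratio).
#' @export
estimation_error <- function(measured, estimated, edge_window = 0.25) {
  stopifnot(inherits(measured, "waveform"), inherits(estimated, "waveform"))
  if (length(measured$values) != length(estimated$values) ||
      abs(measured$fs - estimated$fs) > 1e-9 * measured$fs ||
      abs(measured$t0 - estimated$t0) > 1e-9)
    stop("waveforms are not aligned (length, fs and t0 must match)")
  e <- measured$values - estimated$values
  n <- length(e)
  m <- max(1L, min(n, round(edge_window * measured$fs)))
  early <- mean(abs(e[seq_len(m)]))
  late <- mean(abs(e[seq.int(n - m + 1L, n)]))
  list(error = waveform(e, fs = measured$fs, t0 = measured$t0,
                        quantity = "pressure"),
       summary = list(mean = mean(e), rmse = sqrt(mean(e^2)),
                      max_abs = max(abs(e)), early_mae = early,
                      late_mae = late,
                      late_early_ratio = late / early))
}

#' Signal-to-noise improvement of a denoiser
#'
#' Power ratio, in dB, of the error before and after denoising:
#' \code{10 log10( MS(noisy - clean) / MS(denoised - clean) )}. Positive
#' values mean the denoiser moved the signal closer to the clean
#' reference; a perfect reconstruction returns \code{Inf}.
#'
#' @param clean,noisy,denoised aligned \code{\link{waveform}}s.
#' @return Improvement in dB (possibly \code{Inf}).
#' @export
snr_improvement <- function(clean, noisy, denoised) {
  stopifnot(inherits(clean, "waveform"), inherits(noisy, "waveform"),
            inherits(denoised, "waveform"))
  n <- length(clean$values)
  if (length(noisy$values) != n || length(denoised$values) != n)
    stop("waveforms are not aligned")
  ms_before <- mean((noisy$values - clean$values)^2)
  ms_after <- mean((denoised$values - clean$values)^2)
  if (ms_after == 0) return(Inf)
  10 * log10(ms_before / ms_after)
}
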