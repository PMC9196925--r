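#' Acquisition configuration for a maFLIM dermoscope
#'
#' Describes the sampling geometry of a multispectral time-resolved
#' fluorescence acquisition: pixel grid, temporal sampling, and the three
#' emission channels (collagen / NADH / FAD bands, referred to by their
#' nominal centre wavelengths 390, 452 and 500 nm).
#'
#' Defaults correspond to a handheld maFLIM dermoscope digitising at 2.5 GHz
#' (0.4 ns temporal resolution), 149 temporal samples per channel (59.6 ns),
#' 140 x 140 pixels at a 10 kHz pixel rate.
#'
#' @param rows,cols Pixel grid dimensions.
#' @param sampling_rate_hz Digitiser sampling rate in Hz.
#' @param n_samples Temporal samples per emission channel. Either a single
#'   count shared by all channels or a length-3 vector of per-channel decay
#'   lengths (channels may be recorded shorter than the longest one).
#' @param pixel_rate_hz Pixel scan rate in Hz.
#' @param channels Ordered emission-band labels (nm). Must have length 3.
#' @return An object of class `maflim_config`.
#' @examples
#' cfg <- acquisition_config()
#' cfg$dt_ns                      # 0.4 ns
#' acquisition_time_s(cfg)        # 1.96 s
#' channel_duration_ns(cfg)       # 59.6 ns
#' @export
acquisition_config <- function(rows = 140, cols = 140,
                               sampling_rate_hz = 2.5e9,
                               n_samples = 149,
                               pixel_rate_hz = 1e4,
                               channels = c(390, 452, 500)) {
  stopifnot(rows >= 1, cols >= 1, sampling_rate_hz > 0, pixel_rate_hz > 0)
  if (length(channels) != 3L)
    stop("exactly 3 emission channels are required")
  if (length(n_samples) == 1L) n_samples <- rep(as.integer(n_samples), 3L)
  if (length(n_samples) != 3L || any(n_samples < 1L))
    stop("n_samples must be a positive count (scalar or one per channel)")
  cfg <- list(
    rows = as.integer(rows), cols = as.integer(cols),
    sampling_rate_hz = sampling_rate_hz,
    dt_ns = 1e9 / sampling_rate_hz,
    n_samples = as.integer(n_samples),
    pixel_rate_hz = pixel_rate_hz,
    channels = channels
  )
  class(cfg) <- "maflim_config"
  cfg
}

#' @export
print.maflim_config <- function(x, ...) {
  cat("maFLIM acquisition config\n")
  cat(sprintf("  grid: %d x %d pixels @ %g kHz pixel rate\n",
              x$rows, x$cols, x$pixel_rate_hz / 1e3))
  cat(sprintf("  sampling: %g GHz (dt = %g ns), samples/channel: %s\n",
              x$sampling_rate_hz / 1e9, x$dt_ns,
              paste(x$n_samples, collapse = "/")))
  cat(sprintf("  channels: %s nm\n", paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Per-image acquisition time in seconds
#'
#' Pixel count divided by the pixel rate (1.96 s for the 140 x 140 / 10 kHz
#' default).
#' @param config A `maflim_config`.
#' @export
acquisition_time_s <- function(config) {
  config$rows * config$cols / config$pixel_rate_hz
}

#' Per-channel decay duration in nanoseconds
#'
#' Longest channel length times the temporal resolution (59.6 ns for 149
#' samples at 0.4 ns).
#' @param config A `maflim_config`.
#' @export
channel_duration_ns <- function(config) {
  max(config$n_samples) * config$dt_ns
}

#' Concatenated signal length (3 * M samples)
#'
#' M is the longest channel length; shorter channels are zero-padded to M
#' before concatenation, so the concatenated three-channel signal always has
#' 3 * M samples.
#' @param config A `maflim_config`.
#' @export
concat_length <- function(config) 3L * max(config$n_samples)

#' Harmonic frequency grid of the concatenated signal
#'
#' The discrete Fourier spectrum of the concatenated three-channel signal has
#' a frequency resolution of fs / (3 * M) (5.6 MHz for fs = 2.5 GHz, M = 149).
#' Phasor features are computed at the first `n_harmonics` harmonics of that
#' grid, which cover the ~60 MHz bandwidth of skin autofluorescence decays.
#'
#' @param config A `maflim_config`.
#' @param n_harmonics Number of harmonics (default 9).
#' @return Frequencies in Hz, `k * fs / (3 * M)` for `k = 1..n_harmonics`.
#' @export
harmonic_frequencies <- function(config, n_harmonics = 9) {
  stopifnot(n_harmonics >= 1)
  f1 <- config$sampling_rate_hz / concat_length(config)
  seq_len(n_harmonics) * f1
}

#' Display labels for the harmonic frequencies
#'
#' Labels are multiples of the fundamental rounded to 0.1 MHz (5.6, 11.2, ...,
#' 50.4 MHz for the default configuration), the convention used when naming
#' phasor features.
#' @param config A `maflim_config`.
#' @param n_harmonics Number of harmonics.
#' @return Character vector like `"5.6MHz"`.
#' @export
harmonic_labels <- function(config, n_harmonics = 9) {
  f1_mhz <- round(config$sampling_rate_hz / concat_length(config) / 1e6, 1)
  sprintf("%gMHz", seq_len(n_harmonics) * f1_mhz)
}
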