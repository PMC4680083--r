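# Shared STFT framing (Hann window, fractional overlap). Both the PSD and
# the spectrogram use this one framing so that band energies seen by the
# model cell match the plotted spectra.
stft_frames <- function(x, nw, hop) {
  if (nw > length(x)) {
    stop("analysis window is longer than the signal", call. = FALSE)
  }
  win <- 0.5 * (1 - cos(2 * pi * (seq_len(nw) - 1) / nw))
  starts <- seq(1, length(x) - nw + 1, by = hop)
  pow <- vapply(starts, function(s) {
    X <- stats::fft(x[s:(s + nw - 1)] * win)
    Mod(X[seq_len(nw %/% 2)])^2
  }, numeric(nw %/% 2))
  list(power = pow,                       # freq x frame, linear power
       frequencies = (seq_len(nw %/% 2) - 1) * NA_real_,  # filled by caller
       starts = starts, win = win)
}

#' Welch power spectral density
#'
#' Averaged-periodogram PSD with a Hann window. The window length is set
#' from the requested frequency resolution (`nw = sample_rate /
#' resolution`), with 75% overlap. Power is reported in dB relative to
#' `ref` (by default this spectrum's own maximum), so a stimulus-set-wide
#' reference can be passed to put a whole suite on one dB scale.
#'
#' @param w A [waveform()].
#' @param resolution Frequency resolution in Hz (default 1000, i.e. a 1 ms
#'   window at 400 kHz).
#' @param overlap Window overlap fraction (default 0.75).
#' @param ref Linear-power reference for the dB scale; default the maximum
#'   of this spectrum.
#' @return A `spectral_density` tibble with columns `frequency`,
#'   `power_db` and `power` (linear), and attributes `resolution` and
#'   `ref`.
#' @export
psd <- function(w, resolution = 1000, overlap = 0.75, ref = NULL) {
  stopifnot(inherits(w, "waveform"), resolution > 0, overlap >= 0, overlap < 1)
  nw <- round(w$sample_rate / resolution)
  hop <- max(1, round(nw * (1 - overlap)))
  fr <- stft_frames(w$samples, nw, hop)
  p <- rowMeans(fr$power)
  f <- (seq_along(p) - 1) * w$sample_rate / nw
  if (is.null(ref)) ref <- max(p)
  out <- tibble::tibble(frequency = f, power = p,
                        power_db = 10 * log10(pmax(p, .Machine$double.xmin) / ref))
  attr(out, "resolution") <- w$sample_rate / nw
  attr(out, "ref") <- ref
  class(out) <- c("spectral_density", class(out))
  out
}

#' Short-time Fourier spectrogram
#'
#' Hann-windowed STFT power, the time-frequency representation used both
#' for display and as the front end of the model neuron (band energies
#' are integrated from these frames).
#'
#' @param w A [waveform()].
#' @param window Window length in seconds (default 1 ms).
#' @param overlap Overlap fraction (default 0.75).
#' @return A `spectrogram` object: list with `power` (frequency x time
#'   matrix, linear), `frequencies` (Hz), `times` (s, frame centers) and
#'   `sample_rate`.
#' @export
spectrogram <- function(w, window = 0.001, overlap = 0.75) {
  stopifnot(inherits(w, "waveform"), window > 0, overlap >= 0, overlap < 1)
  nw <- round(window * w$sample_rate)
  hop <- max(1, round(nw * (1 - overlap)))
  fr <- stft_frames(w$samples, nw, hop)
  structure(list(
    power = fr$power,
    frequencies = (seq_len(nrow(fr$power)) - 1) * w$sample_rate / nw,
    times = (fr$starts - 1 + nw / 2) / w$sample_rate,
    sample_rate = w$sample_rate
  ), class = "spectrogram")
}

#' Band energy envelope from a spectrogram
#'
#' Mean linear power across the spectrogram bins inside `[lo, hi]`,
#' per time frame; the square root gives an amplitude-like envelope used
#' by the model cell.
#'
#' @param sg A [spectrogram()].
#' @param lo,hi Band edges in Hz.
#' @param amplitude If TRUE (default) return the square root of band
#'   power (amplitude envelope); otherwise linear power.
#' @return Numeric vector, one value per spectrogram frame.
#' @export
band_energy <- function(sg, lo, hi, amplitude = TRUE) {
  stopifnot(inherits(sg, "spectrogram"), lo < hi)
  sel <- sg$frequencies >= lo & sg$frequencies <= hi
  if (!any(sel)) stop("no spectrogram bins in requested band", call. = FALSE)
  p <- colMeans(sg$power[sel, , drop = FALSE])
  if (amplitude) sqrt(p) else p
}

# Peak band level in dB relative to the spectrum's maximum; convenience
# used throughout the distortion-product analyses.
band_peak_db <- function(sd, lo, hi) {
  sel <- sd$frequency >= lo & sd$frequency <= hi
  if (!any(sel)) return(-Inf)
  max(sd$power_db[sel])
}

#' Quantify distortion energy introduced in a low-frequency band
#'
#' Compares the PSD of an original and a processed stimulus inside a band
#' (default 10--35 kHz, where the characteristic frequencies of the model
#' neuron population lie) on a common dB scale referenced to each
#' spectrum's own peak.
#'
#' @param original,processed [waveform()]s of equal sample rate.
#' @param lo,hi Band edges in Hz.
#' @param resolution PSD resolution in Hz.
#' @return A one-row tibble: `band_db_in`, `band_db_out` (peak in-band
#'   levels in dB re each spectrum's max) and `introduced_db` (their
#'   difference).
#' @export
distortion_gain <- function(original, processed, lo = 10000, hi = 35000,
                            resolution = 1000) {
  din <- band_peak_db(psd(original, resolution), lo, hi)
  dout <- band_peak_db(psd(processed, resolution), lo, hi)
  tibble::tibble(band_db_in = din, band_db_out = dout,
                 introduced_db = dout - din)
}

#' Write a PSD to CSV
#'
#' @param sd A `spectral_density` from [psd()].
#' @param path Output CSV path (columns `frequency_hz`, `power_db`).
#' @return `path`, invisibly.
#' @export
write_psd_csv <- function(sd, path) {
  stopifnot(inherits(sd, "spectral_density"))
  utils::write.csv(
    data.frame(frequency_hz = sd$frequency, power_db = sd$power_db),
    path, row.names = FALSE)
  invisible(path)
}

#' @exportS3Method ggplot2::autoplot
autoplot.spectral_density <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frequency / 1000,
                                       y = .data$power_db)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (kHz)", y = "power (dB re max)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.spectrogram <- function(object, floor_db = -80, ...) {
  df <- tidyr::expand_grid(
    time = object$times,
    frequency = object$frequencies
  )
  db <- 10 * log10(pmax(t(object$power), .Machine$double.xmin) / max(object$power))
  df$power_db <- pmax(as.vector(db), floor_db)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time * 1000,
                                   y = .data$frequency / 1000,
                                   fill = .data$power_db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dB") +
    ggplot2::labs(x = "time (ms)", y = "frequency (kHz)")
}
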