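#' Sampled acoustic waveform
#'
#' A `waveform` is a sampled acoustic pressure signal in dimensionless,
#' peak-normalized units, together with its sample rate. Stimuli in this
#' package are synthesized and analysed at 400 kHz so that ultrasonic
#' vocalization energy (50--100 kHz) sits well below the Nyquist frequency.
#'
#' @param samples Numeric vector of pressure amplitudes. Must be nonempty
#'   and finite.
#' @param sample_rate Sampling rate in Hz (default 400000).
#' @return An object of class `waveform`: a list with elements `samples`
#'   and `sample_rate`.
#' @examples
#' w <- waveform(sin(2 * pi * 70e3 * seq(0, 0.01, by = 1 / 400e3)))
#' duration(w)
#' @export
waveform <- function(samples, sample_rate = 400000) {
  samples <- as.numeric(samples)
  if (length(samples) == 0) {
    stop("waveform must contain at least one sample", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("waveform samples must all be finite", call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    stop("sample_rate must be a single positive number", call. = FALSE)
  }
  structure(list(samples = samples, sample_rate = sample_rate),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g kHz, %.2f ms, peak %.3g>\n",
              length(x$samples), x$sample_rate / 1000,
              1000 * duration(x), max(abs(x$samples))))
  invisible(x)
}

#' @rdname waveform
#' @param w A `waveform`.
#' @export
duration <- function(w) length(w$samples) / w$sample_rate

#' @rdname waveform
#' @export
time_axis <- function(w) (seq_along(w$samples) - 1) / w$sample_rate

#' Convert a waveform to a tibble
#'
#' @param x A `waveform`.
#' @param ... Unused.
#' @return A tibble with columns `time` (s) and `amplitude`.
#' @exportS3Method tibble::as_tibble
as_tibble.waveform <- function(x, ...) {
  tibble::tibble(time = time_axis(x), amplitude = x$samples)
}

#' Time-reverse a waveform
#'
#' Reverses the sample order. Used to turn a downsweep stimulus into the
#' matched upsweep control: reversal happens on the raw waveform, before
#' any cochlear processing, mirroring how a reversed vocalization would
#' reach the ear.
#'
#' @param w A `waveform`.
#' @return The reversed `waveform`.
#' @export
reverse_waveform <- function(w) {
  waveform(rev(w$samples), w$sample_rate)
}

#' @exportS3Method ggplot2::autoplot
autoplot.waveform <- function(object, ...) {
  df <- as_tibble.waveform(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time * 1000, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (ms)", y = "amplitude")
}
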