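#' Reverberation stage parameters
#'
#' The first stage of the cochlea model adds exponentially attenuated,
#' delayed copies of the waveform to itself (a comb filter), emulating
#' reverberation on the basilar membrane. Output sample `t` is
#' `sum_{n=0..N} w(t - n*delay) * exp(-n*delay/decay)`.
#'
#' @param delay Echo delay in seconds (default 1 ms). Must resolve to a
#'   whole number of samples at the waveform's rate.
#' @param decay Exponential decay time constant in seconds (default 2 ms).
#' @param n_echoes Number of delayed copies added, `N` (default 5);
#'   `n_echoes = 0` leaves the waveform unchanged.
#' @return A `reverb_params` list.
#' @export
reverb_params <- function(delay = 0.001, decay = 0.002, n_echoes = 5) {
  stopifnot(delay > 0, decay > 0, n_echoes >= 0)
  structure(list(delay = delay, decay = decay, n_echoes = as.integer(n_echoes)),
            class = "reverb_params")
}

#' Boltzmann (double-sigmoid) distortion stage parameters
#'
#' The second stage is a memoryless saturating nonlinearity
#' `D(x) = 1 / ((1 + exp(a2 (x2 - x))) (1 + exp(a1 (x1 - x))))`,
#' a two-state Boltzmann model of mechanoelectrical transduction. Acting on
#' a multi-component signal it generates intermodulation distortion
#' products at combination frequencies such as `f2 - f1` and `2 f1 - f2`.
#'
#' @param x1,x2 Operating points (default -0.2 each; at the operating
#'   point each sigmoid factor is 1/2, so `D(-0.2) = 1/4`).
#' @param a1 Slope of the sharp factor (default 12.8).
#' @param a2 Slope of the shallow factor (default `a1 / 3`).
#' @return A `boltzmann_params` list.
#' @export
boltzmann_params <- function(x1 = -0.2, x2 = -0.2, a1 = 12.8, a2 = a1 / 3) {
  stopifnot(a1 > 0, a2 > 0)
  structure(list(x1 = x1, x2 = x2, a1 = a1, a2 = a2),
            class = "boltzmann_params")
}

#' Apply the reverberation comb filter
#'
#' Adds `n_echoes` delayed, exponentially attenuated copies of the
#' waveform to itself. Delayed copies that overrun the end of the signal
#' are truncated so that output length equals input length. By default
#' the result is rescaled so its maximum absolute amplitude equals the
#' input's; `normalize = FALSE` exposes the raw (linear) comb output.
#'
#' @param w A [waveform()].
#' @param params A [reverb_params()].
#' @param normalize Rescale the output peak to the input peak? Default TRUE.
#' @return A [waveform()] of the same length and sample rate.
#' @export
reverberate <- function(w, params = reverb_params(), normalize = TRUE) {
  stopifnot(inherits(w, "waveform"), inherits(params, "reverb_params"))
  d_exact <- params$delay * w$sample_rate
  d <- round(d_exact)
  if (abs(d_exact - d) > 1e-9) {
    stop(sprintf(
      "reverberation delay (%g s) is not a whole number of samples at %g Hz",
      params$delay, w$sample_rate), call. = FALSE)
  }
  x <- w$samples
  y <- numeric(length(x))
  for (n in 0:params$n_echoes) {
    lag <- n * d
    if (lag >= length(x)) break
    wgt <- exp(-n * params$delay / params$decay)
    idx <- (lag + 1):length(x)
    y[idx] <- y[idx] + wgt * x[seq_len(length(x) - lag)]
  }
  if (normalize && max(abs(y)) > 0) {
    y <- y * (max(abs(x)) / max(abs(y)))
  }
  waveform(y, w$sample_rate)
}

#' Apply the Boltzmann distortion nonlinearity
#'
#' Maps each sample through the memoryless double sigmoid
#' `D(x)` (see [boltzmann_params()]). Output values lie in (0, 1) and the
#' mapping is monotonically increasing, so distortion arises purely from
#' waveform compression, not from memory.
#'
#' @param w A [waveform()] (typically peak-normalized so the operating
#'   point of the nonlinearity is meaningful).
#' @param params A [boltzmann_params()].
#' @return A [waveform()] with samples in (0, 1).
#' @export
boltzmann <- function(w, params = boltzmann_params()) {
  stopifnot(inherits(w, "waveform"), inherits(params, "boltzmann_params"))
  waveform(boltzmann_map(w$samples, params), w$sample_rate)
}

boltzmann_map <- function(x, p) {
  1 / ((1 + exp(p$a2 * (p$x2 - x))) * (1 + exp(p$a1 * (p$x1 - x))))
}

#' Full cochlear distortion filter
#'
#' The two-stage phenomenological cochlea model: reverberation first, then
#' the Boltzmann nonlinearity. The input is rescaled so its peak equals
#' `level` before the nonlinearity (the drive level determines how hard
#' the nonlinearity is driven: at `level = 1` distortion products are
#' strong; at `level ~ 1e-3` the sigmoid is locally linear and distortion
#' collapses). The distorted signal is then mean-removed (the double
#' sigmoid has a positive DC offset) and re-normalized to the input's
#' original peak amplitude, so original and distorted stimuli are
#' presented at matched levels.
#'
#' @param w A [waveform()].
#' @param reverb A [reverb_params()].
#' @param boltz A [boltzmann_params()].
#' @param level Peak amplitude driving the nonlinearity (default 1).
#' @param normalize_input If TRUE (default), rescale the input so its
#'   peak equals `level` before the nonlinearity -- the
#'   stimulus-preparation convention, where every stimulus is presented
#'   at the same level. If FALSE, the input is used at its native
#'   amplitude (scaled by `level`), so quieter signals drive the
#'   nonlinearity less -- the convention for modeling an ear receiving
#'   stimuli whose relative levels matter.
#' @return A [waveform()]: the distorted stimulus.
#' @export
apply_cochlea_filter <- function(w, reverb = reverb_params(),
                                 boltz = boltzmann_params(), level = 1,
                                 normalize_input = TRUE) {
  stopifnot(level > 0)
  pk <- max(abs(w$samples))
  if (pk == 0) {
    # silence: D(0) constant, mean removal yields zeros
    return(waveform(numeric(length(w$samples)), w$sample_rate))
  }
  x <- if (normalize_input) {
    waveform(w$samples / pk * level, w$sample_rate)
  } else {
    waveform(w$samples * level, w$sample_rate)
  }
  y <- boltzmann(reverberate(x, reverb), boltz)$samples
  y <- y - mean(y)
  if (max(abs(y)) > 0) y <- y * (pk / max(abs(y)))
  waveform(y, w$sample_rate)
}

# Zero-phase Butterworth filter (forward-backward). After filtfilt squares
# the magnitude response, order 8 gives ~56 dB attenuation even half an
# octave beyond the cutoff (a 60 kHz tone through the 40 kHz lowpass drops
# >50 dB) and ~96 dB at the octave, with no passband ripple.
butter_zero_phase <- function(w, cutoff, type, order = 8) {
  nyq <- w$sample_rate / 2
  if (cutoff >= nyq) {
    stop(sprintf("cutoff (%g Hz) must be below Nyquist (%g Hz)", cutoff, nyq),
         call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / nyq, type = type)
  y <- signal::filtfilt(bf, w$samples)
  waveform(y, w$sample_rate)
}

#' 40 kHz high-pass / low-pass stimulus manipulations
#'
#' Zero-phase (forward-backward Butterworth, order 8) filters used to
#' separate a stimulus into its ultrasound band and its low-frequency
#' distortion-product band. `highpass_40k()` removes everything below the
#' cutoff so an original vocalization carries no low-frequency energy;
#' `lowpass_40k()` keeps only the distortion products of a distorted
#' stimulus. Zero-phase filtering preserves distortion-product timing.
#'
#' @param w A [waveform()].
#' @param cutoff Cutoff frequency in Hz (default 40000). Must be below
#'   Nyquist.
#' @return A filtered [waveform()].
#' @export
highpass_40k <- function(w, cutoff = 40000) {
  butter_zero_phase(w, cutoff, "high")
}

#' @rdname highpass_40k
#' @export
lowpass_40k <- function(w, cutoff = 40000) {
  butter_zero_phase(w, cutoff, "low")
}
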