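#' Specify a synthetic ultrasonic-vocalization syllable
#'
#' Synthetic stand-ins for mouse courtship syllables. All kinds keep their
#' spectral energy in the 50--100 kHz ultrasound band:
#' * `flat`: constant-frequency tone at `f_start`.
#' * `upsweep` / `downsweep`: linear FM between `f_start` and `f_end`.
#' * `jump`: instantaneous frequency step from `f_start` to `f_end` at
#'   `jump_time` (phase-continuous).
#' * `harmonic`: FM fundamental plus a second component at
#'   `harmonic_ratio` times the instantaneous frequency; the two
#'   components interact in the cochlear nonlinearity to create a
#'   difference-frequency distortion product that sweeps with the
#'   fundamental.
#'
#' @param kind One of `"flat"`, `"upsweep"`, `"downsweep"`, `"jump"`,
#'   `"harmonic"`.
#' @param f_start,f_end Start/end frequency in Hz (50--100 kHz typical).
#'   `f_end` is ignored for `flat`.
#' @param duration Syllable duration in seconds.
#' @param amplitude Peak amplitude (default 1).
#' @param jump_time Time of the frequency step in seconds (jump kind
#'   only; default mid-syllable).
#' @param harmonic_ratio Frequency ratio of the second component
#'   (harmonic kind only; default 1.5).
#' @param harmonic_level Relative amplitude of the second component
#'   (default 0.5).
#' @return A one-row tibble describing the syllable.
#' @export
syllable_spec <- function(kind, f_start, f_end = f_start, duration = 0.05,
                          amplitude = 1, jump_time = duration / 2,
                          harmonic_ratio = 1.5, harmonic_level = 0.5) {
  kind <- match.arg(kind, c("flat", "upsweep", "downsweep", "jump", "harmonic"))
  stopifnot(f_start > 0, f_end > 0, duration > 0, amplitude > 0,
            jump_time > 0, jump_time < duration)
  if (kind == "upsweep" && f_end <= f_start) {
    stop("upsweep requires f_end > f_start", call. = FALSE)
  }
  if (kind == "downsweep" && f_end >= f_start) {
    stop("downsweep requires f_end < f_start", call. = FALSE)
  }
  tibble::tibble(kind = kind, f_start = f_start, f_end = f_end,
                 duration = duration, amplitude = amplitude,
                 jump_time = jump_time, harmonic_ratio = harmonic_ratio,
                 harmonic_level = harmonic_level)
}

#' Synthesize a USV-like waveform from a syllable spec
#'
#' Generates a phase-continuous tone/chirp with 1 ms raised-cosine on/off
#' ramps (avoiding onset splatter), so that spectral energy below 50 kHz
#' stays at least 50 dB under the peak for all in-band syllables.
#'
#' @param spec A one-row tibble from [syllable_spec()] (or a list with
#'   the same fields).
#' @param sample_rate Sampling rate in Hz (default 400000).
#' @param ramp Ramp duration in seconds (default 1 ms).
#' @return A [waveform()].
#' @export
generate_usv <- function(spec, sample_rate = 400000, ramp = 0.001) {
  nyq <- sample_rate / 2
  fmax <- max(spec$f_start, spec$f_end) *
    (if (spec$kind == "harmonic") spec$harmonic_ratio else 1)
  if (fmax >= nyq) {
    stop(sprintf("syllable frequency %g Hz exceeds Nyquist (%g Hz)", fmax, nyq),
         call. = FALSE)
  }
  n <- round(spec$duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  f_inst <- switch(spec$kind,
    flat = rep(spec$f_start, n),
    upsweep = ,
    downsweep = ,
    harmonic = spec$f_start + (spec$f_end - spec$f_start) * t / spec$duration,
    jump = {
      # raised-cosine transition over 0.5 ms: fast against the 1 ms echo
      # delay (so delayed copies still straddle the step and distortion
      # products form) but slow enough to avoid sub-50 kHz splatter
      tw <- 5e-4
      u <- pmin(pmax((t - spec$jump_time) / tw + 0.5, 0), 1)
      spec$f_start + (spec$f_end - spec$f_start) * 0.5 * (1 - cos(pi * u))
    }
  )
  phase <- 2 * pi * cumsum(f_inst) / sample_rate
  x <- sin(phase)
  if (spec$kind == "harmonic") {
    x <- x + spec$harmonic_level * sin(spec$harmonic_ratio * phase)
  }
  x <- apply_ramps(x, round(ramp * sample_rate))
  x <- x / max(abs(x)) * spec$amplitude
  waveform(x, sample_rate)
}

apply_ramps <- function(x, nr) {
  if (nr * 2 > length(x)) stop("ramps longer than syllable", call. = FALSE)
  if (nr > 0) {
    r <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    x[seq_len(nr)] <- x[seq_len(nr)] * r
    x[(length(x) - nr + 1):length(x)] <- x[(length(x) - nr + 1):length(x)] * rev(r)
  }
  x
}

#' The default 35-syllable synthetic stimulus suite
#'
#' A fixed suite of 35 synthetic syllables emulating a male courtship
#' repertoire: mostly jump and harmonic syllables (the kinds whose
#' frequency structure generates strong low-frequency distortion
#' products in a nonlinear cochlea), plus FM sweeps and a few flat tones,
#' all with spectral energy confined to 50--100 kHz and durations of
#' 30--70 ms. Deterministic: parameters are laid out on fixed grids, not
#' sampled.
#'
#' @return A 35-row tibble of syllable specs with a `stimulus_id` column.
#' @export
usv_suite_default35 <- function() {
  specs <- list()
  # 3 flat tones
  for (f in c(60e3, 75e3, 90e3)) {
    specs <- c(specs, list(syllable_spec("flat", f, duration = 0.05)))
  }
  # 7 upsweeps / 7 downsweeps, spans 15-40 kHz, 30-50 ms; lower edges kept
  # at/above 55 kHz so window leakage below 50 kHz stays under -50 dB
  up <- cbind(f0 = c(55, 56, 58, 60, 62, 65, 70) * 1e3,
              f1 = c(70, 80, 88, 95, 85, 92, 98) * 1e3,
              dur = c(30, 40, 50, 35, 45, 30, 40) / 1000)
  for (i in seq_len(nrow(up))) {
    specs <- c(specs, list(syllable_spec("upsweep", up[i, "f0"], up[i, "f1"],
                                         duration = up[i, "dur"])))
    specs <- c(specs, list(syllable_spec("downsweep", up[i, "f1"], up[i, "f0"],
                                         duration = up[i, "dur"])))
  }
  # 9 jumps, step sizes 12-35 kHz both directions, 40-70 ms
  jp <- cbind(f0 = c(60, 85, 55, 90, 70, 95, 65, 80, 75) * 1e3,
              f1 = c(75, 65, 80, 60, 95, 70, 90, 62, 98) * 1e3,
              dur = c(40, 50, 60, 45, 55, 70, 40, 50, 60) / 1000)
  for (i in seq_len(nrow(jp))) {
    specs <- c(specs, list(syllable_spec("jump", jp[i, "f0"], jp[i, "f1"],
                                         duration = jp[i, "dur"])))
  }
  # 9 harmonic syllables, fundamental sweeps within 50-80 kHz so the
  # 1.5x component stays below 120 kHz and the f2-f1 product lies 25-40 kHz
  hm <- cbind(f0 = c(70, 55, 65, 75, 60, 80, 72, 58, 68) * 1e3,
              f1 = c(55, 70, 56, 58, 76, 62, 55, 72, 56) * 1e3,
              dur = c(50, 40, 60, 45, 55, 50, 40, 60, 45) / 1000)
  for (i in seq_len(nrow(hm))) {
    specs <- c(specs, list(syllable_spec("harmonic", hm[i, "f0"], hm[i, "f1"],
                                         duration = hm[i, "dur"])))
  }
  out <- dplyr::bind_rows(specs)
  out$stimulus_id <- sprintf("%s_%02d", out$kind,
                             stats::ave(seq_len(nrow(out)), out$kind,
                                        FUN = seq_along))
  dplyr::select(out, "stimulus_id", dplyr::everything())
}

#' Write a stimulus suite to WAV files plus a manifest
#'
#' @param suite A tibble of syllable specs (e.g. [usv_suite_default35()]).
#' @param outdir Output directory (created if missing).
#' @param sample_rate Sampling rate in Hz.
#' @return The manifest tibble (stimulus_id, kind, f_start, f_end,
#'   duration, file), invisibly written to `manifest.csv` in `outdir`.
#' @export
write_stimulus_suite <- function(suite, outdir, sample_rate = 400000) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(nrow(suite))
  for (i in seq_len(nrow(suite))) {
    w <- generate_usv(suite[i, ], sample_rate)
    files[i] <- file.path(outdir, paste0(suite$stimulus_id[i], ".wav"))
    write_wav(w, files[i])
  }
  manifest <- dplyr::mutate(
    dplyr::select(suite, "stimulus_id", "kind", "f_start", "f_end", "duration"),
    file = files)
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
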