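# Small waveform fixtures built in code. 400 kHz throughout.

FS <- 400000

tone <- function(freq, dur = 0.02, amp = 1, fs = FS) {
  t <- (seq_len(round(dur * fs)) - 1) / fs
  waveform(amp * sin(2 * pi * freq * t), fs)
}

two_tone <- function(f1, f2, dur = 0.02, fs = FS) {
  t <- (seq_len(round(dur * fs)) - 1) / fs
  waveform(0.5 * sin(2 * pi * f1 * t) + 0.5 * sin(2 * pi * f2 * t), fs)
}

# single-sided amplitude spectrum in dB relative to its own max
spectrum_db <- function(w) {
  n <- length(w$samples)
  a <- Mod(stats::fft(w$samples))[seq_len(n %/% 2)]
  list(frequency = (seq_len(n %/% 2) - 1) * w$sample_rate / n,
       db = 20 * log10(pmax(a, 1e-300) / max(a)))
}

peak_db_near <- function(sp, freq, tol = 300) {
  max(sp$db[abs(sp$frequency - freq) < tol])
}

# deterministic periodic raster: one spike at each time in `times`, all trials
regular_raster <- function(times, n_trials = 20, cycle = 1 / 3) {
  spike_raster(
    tidyr::expand_grid(trial = seq_len(n_trials), time = times),
    cycle_duration = cycle, n_trials = n_trials)
}
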