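# Reverberation comb filter and Boltzmann distortion stage

test_that("reverberate with zero echoes is the identity", {
  w <- tone(60000)
  out <- reverberate(w, reverb_params(n_echoes = 0))
  expect_equal(out$samples, w$samples, tolerance = 1e-12)
})

test_that("reverberate equals direct convolution with the 6-tap kernel", {
  p <- reverb_params()  # 1 ms delay, 2 ms decay, N = 5
  d <- round(p$delay * FS)
  kernel_conv <- function(x) {
    # independent oracle: explicit convolution with taps exp(-n/2) at n*d
    y <- numeric(length(x))
    for (n in 0:p$n_echoes) {
      lag <- n * d
      if (lag < length(x)) {
        y[(lag + 1):length(x)] <- y[(lag + 1):length(x)] +
          exp(-n * p$delay / p$decay) * x[seq_len(length(x) - lag)]
      }
    }
    y
  }
  set.seed(71)
  for (i in 1:25) {
    x <- rnorm(2000 + sample(2000, 1))
    w <- waveform(x, FS)
    got <- reverberate(w, p, normalize = FALSE)$samples
    expect_equal(got, kernel_conv(x), tolerance = 1e-12)
  }
})

test_that("unit impulse expands to six echoes with weights exp(-n/2)", {
  x <- numeric(2401)
  x[1] <- 1
  out <- reverberate(waveform(x, FS), reverb_params())$samples
  got <- out[1 + (0:5) * 400]
  expect_equal(got, exp(-(0:5) / 2), tolerance = 1e-12)  # peak is tap 0 = 1
  expect_equal(sum(out != 0), 6)
})

test_that("pure-tone gain matches the closed-form comb-filter magnitude", {
  # |H(f)| = |sum_n exp(-n/2) exp(-i 2 pi f n dt)|, evaluated independently
  comb_gain <- function(f, dt = 0.001, N = 5) {
    Mod(sum(exp(-(0:N) / 2) * exp(-1i * 2 * pi * f * (0:N) * dt)))
  }
  for (f in c(60000, 60250, 70500)) {
    w <- tone(f, dur = 0.05)
    out <- reverberate(w, normalize = FALSE)
    # steady-state amplitude (skip the 5 ms onset transient)
    sel <- 2001:20000
    amp <- max(abs(out$samples[sel]))
    expect_equal(amp, comb_gain(f), tolerance = 1e-3)
  }
})

test_that("reverberate is linear before normalization", {
  set.seed(5)
  w1 <- waveform(rnorm(3000), FS)
  w2 <- waveform(rnorm(3000), FS)
  a <- 0.7; b <- -1.3
  lhs <- reverberate(waveform(a * w1$samples + b * w2$samples, FS),
                     normalize = FALSE)$samples
  rhs <- a * reverberate(w1, normalize = FALSE)$samples +
    b * reverberate(w2, normalize = FALSE)$samples
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("reverberate preserves length and peak under normalization", {
  w <- generate_usv(syllable_spec("upsweep", 60000, 80000, duration = 0.02))
  out <- reverberate(w)
  expect_length(out$samples, length(w$samples))
  expect_equal(max(abs(out$samples)), max(abs(w$samples)), tolerance = 1e-12)
})

test_that("non-integer sample delay is rejected, not resampled", {
  w <- tone(60000)
  expect_error(reverberate(w, reverb_params(delay = 0.0010007)),
               "whole number of samples")
})

test_that("Boltzmann map is 1/4 at the operating point and saturates correctly", {
  p <- boltzmann_params()
  at <- function(x) boltzmann(waveform(x, FS), p)$samples
  expect_equal(at(-0.2), 0.25, tolerance = 1e-15)
  expect_gt(at(20), 1 - 1e-6)
  expect_lt(at(-20), 1e-6)
  expect_true(all(at(seq(-5, 5, by = 0.01)) > 0 &
                    at(seq(-5, 5, by = 0.01)) < 1))
})

test_that("Boltzmann map is monotone on a million random pairs", {
  set.seed(99)
  x <- runif(1e6, -3, 3)
  y <- runif(1e6, -3, 3)
  p <- boltzmann_params()
  dx <- boltzmann(waveform(x, FS), p)$samples
  dy <- boltzmann(waveform(y, FS), p)$samples
  expect_true(all((dx <= dy) == (x <= y) | x == y))
})

test_that("two-tone input yields f2-f1 and 2f1-f2 distortion products", {
  w <- two_tone(60000, 70000, dur = 0.05)
  out <- boltzmann(w)
  out <- waveform(out$samples - mean(out$samples), FS)
  sp <- spectrum_db(out)
  floor_db <- max(sp$db[sp$frequency > 2000 & sp$frequency < 8000])
  expect_gt(peak_db_near(sp, 10000), floor_db + 40)  # f2 - f1
  expect_gt(peak_db_near(sp, 50000), floor_db + 40)  # 2 f1 - f2
})

test_that("full cochlea filter maps silence to silence", {
  w <- waveform(numeric(4000), FS)
  out <- apply_cochlea_filter(w)
  expect_equal(out$samples, numeric(4000))
})

test_that("full filter introduces sub-50 kHz energy absent from a USV input", {
  w <- generate_usv(syllable_spec("jump", 60000, 80000, duration = 0.05))
  out <- apply_cochlea_filter(w)
  g <- distortion_gain(w, out)
  expect_gt(g$introduced_db, 20)
  expect_gt(g$band_db_out, -75)
  # output is mean-free and level-matched
  expect_lt(abs(mean(out$samples)), 1e-6)
  expect_equal(max(abs(out$samples)), max(abs(w$samples)), tolerance = 1e-9)
})

test_that("two-tone distortion product at 10 kHz survives the 40 kHz lowpass", {
  w <- two_tone(60000, 70000, dur = 0.05)
  out <- lowpass_40k(apply_cochlea_filter(w))
  sp <- spectrum_db(out)
  expect_equal(sp$frequency[which.max(sp$db)], 10000, tolerance = 100)
})

test_that("near-linear drive collapses distortion energy by at least 40 dB", {
  w <- generate_usv(syllable_spec("harmonic", 70000, 55000, duration = 0.05))
  full <- apply_cochlea_filter(w, level = 1)
  tiny <- apply_cochlea_filter(w, level = 1e-3)
  band <- function(p) max(p$power_db[p$frequency >= 10000 & p$frequency <= 35000])
  drop <- band(psd(full)) - band(psd(tiny))
  expect_gt(drop, 40)
})
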