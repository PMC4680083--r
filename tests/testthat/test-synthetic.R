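# Synthetic raster generator and the model fusiform cell

test_that("homogeneous Poisson raster has the expected total count", {
  r <- generate_raster(20, 20, n_trials = 20, cycle = 1 / 3, seed = 10)
  expected <- 20 * 20 / 3
  expect_lt(abs(nrow(r) - expected), 3 * sqrt(expected))
})

test_that("zero rates give an empty raster", {
  r <- generate_raster(0, 0, n_trials = 20, seed = 1)
  expect_equal(nrow(r), 0)
  expect_equal(n_trials(r), 20L)
})

test_that("inside/outside rate ratio approaches lambda2/lambda1", {
  tot_in <- tot_out <- 0
  for (s in 1:100) {
    r <- generate_raster(20, 60, 0.1, 0.1, n_trials = 5, cycle = 1 / 3,
                         seed = 500 + s)
    inside <- r$time >= 0.1 & r$time < 0.2
    tot_in <- tot_in + sum(inside)
    tot_out <- tot_out + sum(!inside)
  }
  # outside window is 1/3 - 0.1 ~ 0.233 s at 20 /s; inside 0.1 s at 60 /s
  ratio <- (tot_in / 0.1) / (tot_out / (1 / 3 - 0.1))
  expect_lt(abs(ratio - 3), 0.3)
})

test_that("gamma renewal matches the mean rate but is more regular", {
  rp <- generate_raster(40, 40, n_trials = 40, cycle = 1 / 3,
                        process = "poisson", seed = 3)
  rg <- generate_raster(40, 40, n_trials = 40, cycle = 1 / 3,
                        process = "gamma", shape = 4, seed = 3)
  expect_lt(abs(nrow(rg) - nrow(rp)) / nrow(rp), 0.15)
  isi_cv <- function(r) {
    isis <- unlist(lapply(raster_trials(r), diff))
    sd(isis) / mean(isis)
  }
  expect_gt(isi_cv(rp), 0.85)   # Poisson: CV ~ 1
  expect_lt(isi_cv(rg), 0.7)    # shape 4: CV ~ 0.5
})

test_that("generators are deterministic given a seed", {
  a <- generate_raster(25, 80, 0.02, 0.05, seed = 123)
  b <- generate_raster(25, 80, 0.02, 0.05, seed = 123)
  expect_identical(a$time, b$time)
  cell <- model_cell_params(20000)
  w <- generate_usv(syllable_spec("jump", 60000, 80000, duration = 0.03))
  r1 <- model_cell_response(cell, w, seed = 9)
  r2 <- model_cell_response(cell, w, seed = 9)
  expect_identical(r1$time, r2$time)
})

test_that("an invalid deflection window is rejected", {
  expect_error(generate_raster(10, 30, 0.3, 0.1, cycle = 1 / 3), "window")
})

test_that("energy in the excitatory band raises the rate above baseline", {
  cell <- model_cell_params(20000, baseline_rate = 15)
  w <- generate_usv(syllable_spec("flat", 20000, duration = 0.05))
  r <- model_cell_response(cell, w, n_trials = 20, seed = 5)
  # rate during the stimulus vs spontaneous expectation
  during <- sum(r$time < 0.05) / (0.05 * 20)
  expect_gt(during, 3 * 15)
})

test_that("silence evokes spontaneous firing only", {
  cell <- model_cell_params(20000, baseline_rate = 20)
  w <- waveform(numeric(8000), 400000)
  sig <- vapply(1:10, function(s) {
    r <- model_cell_response(cell, w, seed = 600 + s)
    detect_response(r, n_iter = 3000, burn_in = 500,
                    seed = 700 + s)$significant
  }, logical(1))
  expect_lt(mean(sig), 0.2)
})

test_that("sweep-direction selectivity emerges from the inhibitory sideband", {
  fx <- direction_selectivity_fixture()
  w <- generate_usv(fx$syllable)
  fwd <- lowpass_40k(apply_cochlea_filter(w))
  rev <- lowpass_40k(apply_cochlea_filter(reverse_waveform(w)))
  r_fwd <- model_cell_response(fx$cell, fwd, seed = 101)
  r_rev <- model_cell_response(fx$cell, rev, seed = 102)
  d_fwd <- detect_response(r_fwd, n_iter = 5000, burn_in = 1000, seed = 103)
  d_rev <- detect_response(r_rev, n_iter = 5000, burn_in = 1000, seed = 104)
  expect_true(d_fwd$significant)
  expect_false(d_rev$significant)
})

test_that("without persistent inhibition the direction preference vanishes", {
  fx <- direction_selectivity_fixture()
  no_inh <- fx$cell
  no_inh$inhibitory_bands <- list()
  w <- generate_usv(fx$syllable)
  rev <- lowpass_40k(apply_cochlea_filter(reverse_waveform(w)))
  r_rev <- model_cell_response(no_inh, rev, seed = 111)
  d_rev <- detect_response(r_rev, n_iter = 5000, burn_in = 1000, seed = 112)
  expect_true(d_rev$significant)  # upsweep now drives the cell too
})

test_that("model-cell population is reproducible and in range", {
  pop1 <- model_cell_population(n = 6, seed = 42)
  pop2 <- model_cell_population(n = 6, seed = 42)
  expect_identical(pop1$cf_khz, pop2$cf_khz)
  expect_true(all(pop1$cf_khz >= 10 & pop1$cf_khz <= 35))
  expect_true(all(vapply(pop1$cell, inherits, logical(1), "model_cell")))
})
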