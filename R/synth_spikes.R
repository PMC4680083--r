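#' Generate a spike raster with a known injected rate deflection
#'
#' Simulates `n_trials` repetitions of a point process whose rate is
#' `lambda1` spikes/s outside the window `[tau1, tau1 + tau2)` and
#' `lambda2` inside it. `process = "poisson"` gives homogeneous Poisson
#' segments; `process = "gamma"` gives a gamma-renewal process (shape
#' `shape`, matched mean rate) emulating the regular, non-Poisson
#' spontaneous firing of many brainstem neurons. Both are simulated by
#' time-rescaling a unit-rate renewal process through the cumulative rate
#' function, with a pre-cycle burn-in so the process is near equilibrium
#' at cycle onset.
#'
#' @param lambda1,lambda2 Rates in spikes/s per trial (>= 0).
#' @param tau1 Deflection onset in seconds (default 0: no offset).
#' @param tau2 Deflection duration in seconds (0 for none).
#' @param n_trials Repetitions (default 20).
#' @param cycle Cycle duration in seconds (default 1/3).
#' @param process `"poisson"` or `"gamma"`.
#' @param shape Gamma-renewal shape parameter (default 4; larger = more
#'   regular firing).
#' @param seed Optional integer seed.
#' @return A [spike_raster()].
#' @export
generate_raster <- function(lambda1, lambda2 = lambda1, tau1 = 0, tau2 = 0,
                            n_trials = 20, cycle = 1 / 3,
                            process = c("poisson", "gamma"), shape = 4,
                            seed = NULL) {
  process <- match.arg(process)
  stopifnot(lambda1 >= 0, lambda2 >= 0, tau1 >= 0, tau2 >= 0, shape > 0)
  if (tau1 + tau2 > cycle + 1e-12) stop("deflection window exceeds cycle", call. = FALSE)
  local_seed(seed)

  # piecewise-linear cumulative rate and its inverse
  knots_t <- c(0, tau1, tau1 + tau2, cycle)
  rates <- c(lambda1, lambda2, lambda1)
  knots_l <- c(0, cumsum(rates * diff(knots_t)))
  total <- knots_l[4]
  inv_cum <- function(u) {
    seg <- findInterval(u, knots_l, rightmost.closed = TRUE)
    seg <- pmin(pmax(seg, 1L), 3L)
    knots_t[seg] + (u - knots_l[seg]) / rates[seg]
  }

  rows <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    if (total <= 0) next
    # unit-rate renewal arrivals on (-burn, total]
    burn <- 10
    draw <- function(n) {
      if (process == "poisson") stats::rexp(n) else stats::rgamma(n, shape, shape)
    }
    arr <- -burn + cumsum(draw(ceiling((burn + total) * 2 + 20)))
    while (length(arr) > 0 && arr[length(arr)] < total) {
      arr <- c(arr, arr[length(arr)] + cumsum(draw(ceiling(total) + 20)))
    }
    arr <- arr[arr > 0 & arr < total]
    if (length(arr) == 0) next
    times <- inv_cum(arr)
    times <- times[times >= 0 & times < cycle]
    if (length(times) > 0) {
      rows[[tr]] <- tibble::tibble(trial = tr, time = sort(times))
    }
  }
  spike_raster(dplyr::bind_rows(rows), cycle_duration = cycle,
               n_trials = n_trials)
}

#' Phenomenological model fusiform cell
#'
#' A rectified-linear spectrogram-energy neuron. `E(t)` is the amplitude
#' envelope in the excitatory band and `I_j(t)` in each inhibitory
#' sideband; inhibitory drive is smoothed with an exponential kernel of
#' time constant `inhibition_decay`, so inhibition persists after its
#' driving energy ends (the mechanism behind FM sweep-direction
#' selectivity). Two rate rules are available:
#' * `"gated"` (default): `r(t) = baseline + max(0, gain * E(t) -
#'   sum_j g_j * smooth(I_j)(t))` -- inhibition gates the
#'   stimulus-evoked drive while spontaneous firing continues, as when
#'   sideband inhibition targets the driven input pathway.
#' * `"subtractive"`: `r(t) = max(0, baseline + gain * E(t) -
#'   sum_j g_j * smooth(I_j)(t))` -- inhibition also suppresses
#'   spontaneous firing (an after-hyperpolarization-like silencing).
#'
#' Either way this is a descriptive stand-in for a V-shaped excitatory
#' tuning curve with inhibitory sidebands, not a biophysical neuron
#' model.
#'
#' @param cf Characteristic frequency in Hz.
#' @param excitatory_band Length-2 Hz range (default `cf * c(0.85, 1.15)`).
#' @param inhibitory_bands List of `list(band = c(lo, hi), gain = g)`
#'   entries; default one sideband below the excitatory band.
#' @param inhibition_decay Persistence time constant in seconds
#'   (default 30 ms).
#' @param baseline_rate Spontaneous rate in spikes/s (default 20).
#' @param gain Excitatory gain, spikes/s per unit band amplitude
#'   (default 30).
#' @param inhibition_mode `"gated"` or `"subtractive"` (see above).
#' @param cf_threshold_db,bbn_threshold_db Metadata thresholds (dB SPL),
#'   carried along for population summaries.
#' @return A `model_cell` list.
#' @export
model_cell_params <- function(cf,
                              excitatory_band = cf * c(0.85, 1.15),
                              inhibitory_bands = list(
                                list(band = cf * c(0.5, 0.82), gain = 60)),
                              inhibition_decay = 0.03,
                              baseline_rate = 20,
                              gain = 30,
                              inhibition_mode = c("gated", "subtractive"),
                              cf_threshold_db = 25,
                              bbn_threshold_db = 36) {
  inhibition_mode <- match.arg(inhibition_mode)
  stopifnot(cf > 0, length(excitatory_band) == 2,
            excitatory_band[1] < excitatory_band[2],
            inhibition_decay >= 0, baseline_rate >= 0, gain >= 0)
  for (ib in inhibitory_bands) {
    stopifnot(length(ib$band) == 2, ib$band[1] < ib$band[2], ib$gain >= 0)
  }
  structure(list(cf = cf, excitatory_band = excitatory_band,
                 inhibitory_bands = inhibitory_bands,
                 inhibition_decay = inhibition_decay,
                 baseline_rate = baseline_rate, gain = gain,
                 inhibition_mode = inhibition_mode,
                 cf_threshold_db = cf_threshold_db,
                 bbn_threshold_db = bbn_threshold_db),
            class = "model_cell")
}

# instantaneous rate profile of a model cell over a full stimulus cycle
model_cell_rate <- function(cell, w, cycle = 1 / 3, window = 0.001,
                            overlap = 0.75) {
  sg <- spectrogram(w, window = window, overlap = overlap)
  dtf <- if (length(sg$times) > 1) diff(sg$times[1:2]) else window
  n_frames <- max(2, ceiling(cycle / dtf))
  pad <- function(x) c(x, numeric(n_frames - length(x)))[seq_len(n_frames)]

  exc <- pad(band_energy(sg, cell$excitatory_band[1], cell$excitatory_band[2]))
  evoked <- cell$gain * exc
  for (ib in cell$inhibitory_bands) {
    inh <- pad(band_energy(sg, ib$band[1], ib$band[2]))
    if (cell$inhibition_decay > 0) {
      a <- exp(-dtf / cell$inhibition_decay)
      inh <- as.numeric(stats::filter(inh, a, method = "recursive")) * (1 - a)
    }
    evoked <- evoked - ib$gain * inh
  }
  rate <- if (cell$inhibition_mode == "gated") {
    cell$baseline_rate + pmax(evoked, 0)
  } else {
    pmax(cell$baseline_rate + evoked, 0)
  }
  list(rate = rate, dt = dtf, times = (seq_len(n_frames) - 1) * dtf)
}

#' Simulate a model cell's spike response to a waveform
#'
#' Computes the cell's instantaneous rate from the stimulus spectrogram
#' (see [model_cell_params()]), extends it with the spontaneous rate (and
#' any decaying inhibition) to the full stimulus cycle, and draws each
#' trial as an inhomogeneous Poisson process (piecewise-constant rate per
#' spectrogram frame).
#'
#' @param cell A `model_cell` from [model_cell_params()].
#' @param w A [waveform()] (must be longer than one spectrogram window).
#' @param n_trials Repetitions (default 20).
#' @param cycle Cycle duration in seconds (default 1/3).
#' @param seed Optional integer seed.
#' @param window,overlap Spectrogram framing (defaults 1 ms, 0.75).
#' @return A [spike_raster()].
#' @export
model_cell_response <- function(cell, w, n_trials = 20, cycle = 1 / 3,
                                seed = NULL, window = 0.001, overlap = 0.75) {
  stopifnot(inherits(cell, "model_cell"), inherits(w, "waveform"))
  local_seed(seed)
  prof <- model_cell_rate(cell, w, cycle = cycle, window = window,
                          overlap = overlap)
  rows <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    counts <- stats::rpois(length(prof$rate), prof$rate * prof$dt)
    if (sum(counts) == 0) next
    times <- rep(prof$times, counts) + stats::runif(sum(counts)) * prof$dt
    times <- times[times < cycle]
    if (length(times) > 0) {
      rows[[tr]] <- tibble::tibble(trial = tr, time = sort(times))
    }
  }
  spike_raster(dplyr::bind_rows(rows), cycle_duration = cycle,
               n_trials = n_trials)
}

#' Generate a population of model cells with low-frequency tuning
#'
#' CFs are spaced log-uniformly across `cf_range` (default 10--35 kHz,
#' the band where cochlear distortion products of ultrasonic
#' vocalizations land); response thresholds are drawn from plausible
#' distributions for selective brainstem neurons.
#'
#' @param n Number of cells (default 8).
#' @param cf_range Length-2 Hz range for characteristic frequencies.
#' @param seed Optional integer seed.
#' @param ... Passed on to [model_cell_params()].
#' @return A tibble with columns `cell_id`, `cf_khz`, `cf_threshold_db`,
#'   `bbn_threshold_db` and a list-column `cell` of `model_cell`s.
#' @export
model_cell_population <- function(n = 8, cf_range = c(10e3, 35e3),
                                  seed = NULL, ...) {
  local_seed(seed)
  cfs <- exp(seq(log(cf_range[1]), log(cf_range[2]), length.out = n))
  cf_thr <- pmin(pmax(stats::rnorm(n, 26, 14), 5), 80)
  bbn_thr <- pmin(pmax(cf_thr + stats::rnorm(n, 11, 5), 5), 85)
  tibble::tibble(
    cell_id = sprintf("cell_%02d", seq_len(n)),
    cf_khz = cfs / 1000,
    cf_threshold_db = cf_thr,
    bbn_threshold_db = bbn_thr,
    cell = purrr::pmap(list(cfs, cf_thr, bbn_thr), function(cf, ct, bt) {
      model_cell_params(cf, cf_threshold_db = ct, bbn_threshold_db = bt, ...)
    })
  )
}

#' The direction-selectivity demonstration: cell and stimulus
#'
#' A fixed model cell and harmonic downsweep syllable chosen so that the
#' syllable's `f2 - f1` cochlear distortion product sweeps downward
#' through the cell's excitatory band (29--36 kHz) and then into its
#' low-frequency inhibitory sideband (18--28.5 kHz, 30 ms persistence).
#' Presented forward, excitation arrives before inhibition and the cell
#' responds; time-reversed, the upsweeping product drives the inhibitory
#' sideband first and the persistent inhibition suppresses the later
#' excitatory drive.
#'
#' @return A list with elements `cell` (a `model_cell`) and `syllable`
#'   (a [syllable_spec()]: harmonic fundamental sweeping 70 to 50 kHz
#'   over 50 ms, difference product 35 to 25 kHz).
#' @export
direction_selectivity_fixture <- function() {
  list(
    cell = model_cell_params(
      cf = 32000,
      excitatory_band = c(29000, 36000),
      inhibitory_bands = list(list(band = c(18000, 28500), gain = 120)),
      inhibition_decay = 0.03,
      baseline_rate = 20,
      gain = 30,
      inhibition_mode = "gated"
    ),
    syllable = syllable_spec("harmonic", 70000, 50000, duration = 0.05)
  )
}
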